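# Summary statistics for the ABC: unfolded SFS, discretized LD-decay and the
# window-diversity transition matrix.

#' Default LD-decay distance breakpoints
#'
#' Physical-distance breakpoints (bp) delimiting the bins over which mean
#' haplotype r-squared is accumulated; site pairs closer than the first or at
#' least the last breakpoint are excluded.
#'
#' @return Numeric vector of nine breakpoints defining eight bins.
#' @export
ld_breakpoints <- function() {
  c(6105, 11379, 21209, 39531, 73680, 137328, 255958, 477066, 889175)
}

#' Unfolded site frequency spectrum
#'
#' Entry `k` counts the sites at which exactly `k` haplotypes carry the
#' derived allele (`k = 1..n-1`); invariant sites are excluded.
#'
#' @param aln a [haplotype_alignment()] with at least two haplotypes.
#' @return Integer vector of length `n_hap - 1`, named `sfs_1..`.
#' @export
unfolded_sfs <- function(aln) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  n <- nrow(aln$geno)
  if (n < 2) stop("need at least two haplotypes", call. = FALSE)
  dac <- colSums(aln$geno)
  out <- tabulate(dac[dac > 0 & dac < n], nbins = n - 1)
  names(out) <- paste0("sfs_", seq_len(n - 1))
  out
}

#' Discretized LD decay
#'
#' Mean haplotype r-squared (`D^2 / (pA (1-pA) pB (1-pB))`) between pairs of
#' segregating sites whose physical distance falls in the half-open bins
#' defined by `breakpoints`. At most `max_snps` sites are used (sampled
#' without replacement) and at most `max_pairs` site pairs are evaluated.
#' Bins without any pair are reported as `NA` with `n = 0`.
#'
#' @param aln a [haplotype_alignment()].
#' @param breakpoints increasing bp distances, see [ld_breakpoints()].
#' @param max_snps maximum number of sites to use.
#' @param max_pairs cap on evaluated site pairs.
#' @param seed optional integer seed for the site subsample.
#' @return A tibble with columns `bin`, `lower`, `upper`, `mean_r2`, `n`.
#' @export
ld_decay <- function(aln, breakpoints = ld_breakpoints(), max_snps = 10000,
                     max_pairs = 200000, seed = NULL) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  if (length(breakpoints) < 2 || is.unsorted(breakpoints, strictly = TRUE))
    stop("breakpoints must be at least two strictly increasing values",
         call. = FALSE)
  S <- ncol(aln$geno)
  nb <- length(breakpoints) - 1
  empty <- tibble::tibble(bin = seq_len(nb),
                          lower = breakpoints[-length(breakpoints)],
                          upper = breakpoints[-1],
                          mean_r2 = NA_real_, n = 0)
  if (S < 2) return(empty)
  .with_seed(seed, {
    sites <- if (S > max_snps) sort(sample.int(S, max_snps)) else seq_len(S)
    res <- cpp_ld_bins(aln$geno, aln$positions, sites - 1L,
                       as.numeric(breakpoints), as.numeric(max_pairs))
    out <- empty
    out$n <- res$counts
    out$mean_r2 <- ifelse(res$counts > 0, res$sums / res$counts, NA_real_)
    out
  })
}

#' Pairwise diversity in non-overlapping windows
#'
#' Counts, for a chosen pair of haplotypes, the number of positions at which
#' they differ within each non-overlapping window of `window_size` bp; a
#' trailing partial window is dropped.
#'
#' @param aln a [haplotype_alignment()].
#' @param pair two 1-based haplotype indices.
#' @param window_size window size in bp (default 10 kb).
#' @return An integer vector of per-window difference counts, with the window
#'   size stored in the `window_size` attribute.
#' @export
window_diversity <- function(aln, pair = c(1, 2), window_size = 10000) {
  stopifnot(inherits(aln, "haplotype_alignment"))
  if (length(pair) != 2 || pair[1] == pair[2])
    stop("pair must be two distinct haplotype indices", call. = FALSE)
  if (window_size < 1) stop("window_size must be >= 1", call. = FALSE)
  n_win <- floor(aln$seq_length / window_size)
  if (n_win < 1)
    stop("window_size exceeds the sequence length", call. = FALSE)
  diff_sites <- aln$positions[aln$geno[pair[1], ] != aln$geno[pair[2], ]]
  win <- diff_sites %/% window_size
  counts <- tabulate(win[win < n_win] + 1L, nbins = n_win)
  attr(counts, "window_size") <- window_size
  counts
}

#' Window-diversity transition matrix (TM_win)
#'
#' Classifies each window's pairwise-difference count into diversity classes
#' by the half-open intervals defined by `class_edges`, then reports the
#' proportion of adjacent window pairs transitioning from class `a` to class
#' `b`, flattened row-major.
#'
#' @param counts per-window counts from [window_diversity()].
#' @param class_edges increasing thresholds; `k` edges define `k + 1`
#'   classes (counts below the first edge are class 1).
#' @return Named numeric vector of length `(k+1)^2` summing to one, names
#'   `tmw_<a>_<b>`.
#' @export
tm_win <- function(counts, class_edges) {
  if (length(counts) < 2)
    stop("need at least two windows", call. = FALSE)
  k <- length(class_edges) + 1L
  cls <- findInterval(counts, class_edges) + 1L
  mat <- matrix(0, k, k)
  from <- cls[-length(cls)]
  to <- cls[-1]
  for (i in seq_along(from)) mat[from[i], to[i]] <- mat[from[i], to[i]] + 1
  mat <- mat / length(from)
  out <- as.vector(t(mat))
  names(out) <- paste0("tmw_", rep(seq_len(k), each = k), "_",
                       rep(seq_len(k), k))
  out
}

.choose_pairs <- function(n, max_pairs = 15) {
  all <- t(utils::combn(n, 2))
  if (nrow(all) > max_pairs) all <- all[sample.int(nrow(all), max_pairs), , drop = FALSE]
  all
}

#' Combined summary-statistic vector
#'
#' Concatenates, in a deterministic order, the components requested by
#' `spec`: the unfolded SFS; per-bin mean LD (missing bins imputed as 0) plus
#' a 0/1 missingness flag per bin; and the TM_win entries averaged over up to
#' `max_tm_pairs` haplotype pairs.
#'
#' @param aln a [haplotype_alignment()].
#' @param spec one of `"sfs_ld"`, `"tmwin"`, `"all"`.
#' @param class_edges diversity-class edges for TM_win (required when the
#'   spec includes TM_win); see [calibrate_class_edges()].
#' @param breakpoints LD distance breakpoints.
#' @param window_size TM_win window size in bp.
#' @param max_snps,max_pairs LD subsampling caps.
#' @param max_tm_pairs cap on haplotype pairs averaged for TM_win.
#' @param seed optional integer seed (LD site subsample and pair choice).
#' @return A named numeric vector.
#' @export
summary_vector <- function(aln, spec = c("all", "sfs_ld", "tmwin"),
                           class_edges = NULL,
                           breakpoints = ld_breakpoints(),
                           window_size = 10000, max_snps = 10000,
                           max_pairs = 200000, max_tm_pairs = 15,
                           seed = NULL) {
  spec <- match.arg(spec)
  stopifnot(inherits(aln, "haplotype_alignment"))
  .with_seed(seed, {
    parts <- list()
    if (spec %in% c("sfs_ld", "all")) {
      parts$sfs <- as.numeric(unfolded_sfs(aln)) |>
        stats::setNames(paste0("sfs_", seq_len(nrow(aln$geno) - 1)))
      ld <- ld_decay(aln, breakpoints, max_snps, max_pairs)
      ldm <- ifelse(is.na(ld$mean_r2), 0, ld$mean_r2)
      miss <- as.numeric(ld$n == 0)
      parts$ld <- stats::setNames(c(ldm, miss),
                                  c(paste0("ld_mean_", ld$bin),
                                    paste0("ld_miss_", ld$bin)))
    }
    if (spec %in% c("tmwin", "all")) {
      if (is.null(class_edges))
        stop("class_edges are required for TM_win statistics", call. = FALSE)
      prs <- .choose_pairs(nrow(aln$geno), max_tm_pairs)
      mats <- apply(prs, 1, function(p)
        tm_win(window_diversity(aln, p, window_size), class_edges))
      parts$tmw <- rowMeans(mats)
    }
    unlist(parts, use.names = TRUE) |>
      stats::setNames(unlist(lapply(parts, names)))
  })
}

#' Average summary vectors across independent loci
#'
#' Multi-locus datasets are summarised per locus and combined by element-wise
#' averaging.
#'
#' @param vectors list of equally named numeric vectors.
#' @return A single named numeric vector.
#' @export
combine_loci <- function(vectors) {
  stopifnot(length(vectors) >= 1)
  m <- do.call(rbind, vectors)
  colMeans(m)
}
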