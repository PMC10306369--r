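# Simulators: pairwise SMC', multi-sample SMC' via the selfing time
# rescaling, and the forward Wright-Fisher oracle.

.with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

.as_pair_segments <- function(mat, seq_length) {
  out <- tibble::as_tibble(mat)
  names(out) <- c("start", "end", "tmrca")
  attr(out, "seq_length") <- seq_length
  class(out) <- c("pair_segments", class(out))
  out
}

#' Construct a T_MRCA-segment series by hand
#'
#' Segments must tile `[0, seq_length)` exactly: contiguous, non-overlapping,
#' in genome order, with positive ages.
#'
#' @param start,end 0-based half-open bp coordinates.
#' @param tmrca ages in generations.
#' @param seq_length chromosome length (defaults to the last `end`).
#' @return A `pair_segments` tibble.
#' @export
pair_segments <- function(start, end, tmrca, seq_length = max(end)) {
  if (length(start) == 0) stop("empty segment series", call. = FALSE)
  if (start[1] != 0 || any(end <= start) ||
      (length(start) > 1 && any(start[-1] != end[-length(end)])) ||
      end[length(end)] != seq_length)
    stop("segments must tile [0, seq_length)", call. = FALSE)
  if (any(tmrca <= 0)) stop("tmrca must be positive", call. = FALSE)
  .as_pair_segments(cbind(start, end, tmrca), seq_length)
}

#' Haplotype alignment
#'
#' A phased alignment of `n_hap` haplotypes over the segregating sites of a
#' chromosome of known length. `geno` is coded 0 = ancestral, 1 = derived;
#' positions are 0-based base-pair coordinates in `[0, seq_length)`.
#'
#' @param geno integer matrix, haplotypes in rows, sites in columns.
#' @param positions integer vector of 0-based site coordinates, strictly
#'   increasing.
#' @param seq_length chromosome length in bp.
#' @param sample_ids optional haplotype labels.
#' @return An object of class `haplotype_alignment`.
#' @export
haplotype_alignment <- function(geno, positions, seq_length,
                                sample_ids = NULL) {
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  positions <- as.integer(positions)
  if (ncol(geno) != length(positions))
    stop("geno and positions disagree on the number of sites", call. = FALSE)
  if (length(positions) && is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing", call. = FALSE)
  if (length(positions) && (min(positions) < 0 || max(positions) >= seq_length))
    stop("positions must lie in [0, seq_length)", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("hap_", seq_len(nrow(geno)))
  structure(list(geno = geno, positions = positions,
                 seq_length = as.numeric(seq_length),
                 sample_ids = sample_ids),
            class = "haplotype_alignment")
}

#' @export
print.haplotype_alignment <- function(x, ...) {
  cat(sprintf("Haplotype alignment: %d haplotypes, %d segregating sites, %s bp\n",
              nrow(x$geno), ncol(x$geno), format(x$seq_length, big.mark = ",")))
  invisible(x)
}

#' @export
print.pair_segments <- function(x, ...) {
  cat(sprintf("T_MRCA-segments over %s bp (%d segments)\n",
              format(attr(x, "seq_length"), big.mark = ","), nrow(x)))
  NextMethod()
}

#' Simulate T_MRCA-segments for a pair of haplotypes (SMC')
#'
#' Sequential simulation for a sample of size two under a piecewise-constant
#' model with selfing. The first coalescence time is drawn from the pairwise
#' coalescent with rate `(1 + F(t)) / (2 N(t))`; along the genome the distance
#' to the next recombination breakpoint is exponential with per-bp hazard
#' `H(s) = integral_0^s 2 r(k) (1 - F(k)) dk` (two branches, each with
#' effective rate `r (1 - F)`). At a breakpoint the detached lineage
#' re-coalesces; back-coalescence onto its own ancestral branch is silent and
#' leaves no segment boundary, so emitted segments are delimited by
#' consequential recombination events only.
#'
#' @param model an [epoch_model()] or [transition_scenario()].
#' @param L chromosome length in bp (`>= 1`).
#' @param seed optional integer seed.
#' @return A `pair_segments` tibble with columns `start`, `end` (0-based
#'   half-open bp) and `tmrca` (generations).
#' @examples
#' m <- epoch_model(0, N = 10000, sigma = 0, rec_rate = 1e-8)
#' simulate_pair(m, L = 1e6, seed = 1)
#' @export
simulate_pair <- function(model, L, seed = NULL) {
  model <- as_epoch_model(model)
  if (L < 1) stop("L must be at least 1 bp", call. = FALSE)
  mat <- .with_seed(seed, cpp_simulate_pair(.model_matrix(model), as.numeric(L)))
  .as_pair_segments(mat, as.numeric(L))
}

#' Overlay infinite-sites mutations on a segment series
#'
#' For a segment of length `l` and age `s` the number of pairwise differences
#' is Poisson with mean `2 s mu l` (total branch length of the pair tree times
#' the mutation rate); each mutation is assigned to one of the two haplotypes
#' at random and placed uniformly. Collisions on the same integer position are
#' dropped.
#'
#' @param segments a `pair_segments` tibble from [simulate_pair()].
#' @param mu per-site per-generation mutation rate.
#' @param seed optional integer seed.
#' @return A two-haplotype [haplotype_alignment()].
#' @export
overlay_mutations <- function(segments, mu, seed = NULL) {
  stopifnot(inherits(segments, "pair_segments"))
  if (mu < 0) stop("mu must be non-negative", call. = FALSE)
  L <- attr(segments, "seq_length")
  .with_seed(seed, {
    len <- segments$end - segments$start
    nm <- stats::rpois(nrow(segments), 2 * segments$tmrca * mu * len)
    tot <- sum(nm)
    if (tot == 0) {
      haplotype_alignment(matrix(integer(0), nrow = 2), integer(0), L)
    } else {
      seg_idx <- rep.int(seq_len(nrow(segments)), nm)
      pos <- floor(segments$start[seg_idx] +
                     stats::runif(tot) * len[seg_idx])
      hap <- stats::rbinom(tot, 1, 0.5)
      ord <- order(pos)
      pos <- pos[ord]; hap <- hap[ord]
      keep <- !duplicated(pos)
      pos <- pos[keep]; hap <- hap[keep]
      geno <- rbind(as.integer(hap == 0), as.integer(hap == 1))
      haplotype_alignment(geno, pos, L)
    }
  })
}

.check_pairs <- function(pairs, n) {
  if (is.null(pairs)) return(matrix(integer(0), ncol = 2))
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2) stop("pairs must have two columns", call. = FALSE)
  if (any(pairs < 1 | pairs > n) || any(pairs[, 1] == pairs[, 2]))
    stop("invalid haplotype pair indices", call. = FALSE)
  storage.mode(pairs) <- "integer"
  pairs
}

#' Simulate polymorphism for a sample of n haplotypes
#'
#' Multi-sample simulator under the coalescent-with-selfing: at time `t` the
#' pairwise coalescence rate is `(1 + F(t)) / (2 N(t))` and the per-bp
#' effective recombination rate per lineage is `r(t) (1 - F(t))`. It is
#' realised through the time change `dtau = (1 - F(t)) dt`: in rescaled time
#' recombination runs at the raw rate `r` while the effective size becomes
#' `N (1 - F) / (1 + F)`; genealogies are generated sequentially along the
#' genome with the SMC' transition and node times are mapped back through the
#' inverse (piecewise-linear) time change, after which mutations fall on
#' branches at rate `mu` per bp per generation.
#'
#' @param model an [epoch_model()] or [transition_scenario()]; all epoch
#'   selfing rates must be `<= 0.999` (use [simulate_pair()] for full
#'   selfing).
#' @param n number of haplotypes (`2..64`).
#' @param L chromosome length in bp.
#' @param mu per-site mutation rate.
#' @param seed optional integer seed.
#' @param pairs optional two-column matrix of 1-based haplotype indices whose
#'   T_MRCA-segment series are returned alongside the alignment.
#' @return A list of class `sample_sim` with elements `alignment`
#'   (a [haplotype_alignment()]), `pair_segments` (list of `pair_segments`)
#'   and `n_trees`.
#' @export
simulate_sample <- function(model, n, L, mu, seed = NULL, pairs = NULL) {
  model <- as_epoch_model(model)
  if (any(model$sigma > 0.999))
    stop("simulate_sample supports sigma <= 0.999; use simulate_pair for ",
         "(nearly) complete selfing", call. = FALSE)
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (L < 1) stop("L must be at least 1 bp", call. = FALSE)
  pr <- .check_pairs(pairs, n)
  res <- .with_seed(seed, cpp_simulate_sample(.model_matrix(model),
                                              as.integer(n), as.numeric(L),
                                              mu, pr - 1L))
  aln <- haplotype_alignment(res$geno, res$positions, L)
  segs <- lapply(res$pair_segments, .as_pair_segments, seq_length = L)
  if (nrow(pr)) names(segs) <- paste0(pr[, 1], "-", pr[, 2])
  structure(list(alignment = aln, pair_segments = segs,
                 n_trees = res$n_trees),
            class = "sample_sim")
}

#' @export
print.sample_sim <- function(x, ...) {
  print(x$alignment)
  cat(sprintf("  %d local genealogies, %d tracked pair(s)\n",
              as.integer(x$n_trees), length(x$pair_segments)))
  invisible(x)
}

#' Forward Wright-Fisher oracle with explicit selfing
#'
#' Small-scale forward simulation used as the fidelity check for the
#' coalescent simulators. Each offspring is produced by self-fertilization of
#' a single parent with probability `sigma(t)`, else by outcrossing between
#' two distinct parents; meioses place crossovers at rate `r(t)` per bp. The
#' pedigree is stored and sampled chromosome pairs are traced back to obtain
#' their T_MRCA-segments; with `mu > 0` mutations are tracked forward so an
#' alignment of the sampled chromosomes is returned as well. Intervals that
#' fail to coalesce within the simulated generations get `NA` ages.
#'
#' @param model an [epoch_model()] or [transition_scenario()]; all epoch
#'   sizes must be `<= 2000` and `L <= 100000` (this is a test-scale oracle).
#' @param n number of chromosomes to sample.
#' @param L chromosome length in bp.
#' @param mu per-site mutation rate (0 skips mutation tracking).
#' @param generations number of forward generations, at least ten times the
#'   largest epoch size.
#' @param seed optional integer seed.
#' @param pair_mode `"between"` samples one chromosome from each of `n`
#'   distinct individuals; `"within"` samples both chromosomes of `n/2`
#'   individuals (the only pairs that can coalesce under complete selfing).
#' @param pairs two-column matrix of 1-based indices into the sampled
#'   chromosomes; defaults to disjoint consecutive pairs.
#' @return A list of class `wf_sim` with `alignment`, `pair_segments` and
#'   `individuals` (the individual of origin of each sampled chromosome).
#' @export
simulate_wf_oracle <- function(model, n, L, mu, generations, seed = NULL,
                               pair_mode = c("between", "within"),
                               pairs = NULL) {
  model <- as_epoch_model(model)
  pair_mode <- match.arg(pair_mode)
  if (max(model$N) > 2000 || L > 1e5)
    stop("the forward oracle is restricted to N <= 2000 and L <= 100 kb",
         call. = FALSE)
  if (generations < 10 * max(model$N))
    stop("generations must be at least 10 * N for burn-in", call. = FALSE)
  if (is.null(pairs)) {
    k <- n %/% 2
    pairs <- cbind(2 * seq_len(k) - 1, 2 * seq_len(k))
  }
  pairs <- .check_pairs(pairs, n)
  res <- .with_seed(seed, cpp_wf_oracle(.model_matrix(model), as.integer(n),
                                        as.numeric(L), mu,
                                        as.integer(generations), pairs - 1L,
                                        pair_mode == "within"))
  aln <- haplotype_alignment(res$geno, res$positions, L)
  segs <- lapply(res$pair_segments, .as_pair_segments, seq_length = L)
  names(segs) <- paste0(pairs[, 1], "-", pairs[, 2])
  structure(list(alignment = aln, pair_segments = segs,
                 individuals = res$individuals),
            class = "wf_sim")
}

#' The T_MRCA at given genomic positions
#'
#' @param segments a `pair_segments` tibble.
#' @param at base-pair positions (0-based).
#' @return Numeric vector of segment ages at the requested positions.
#' @export
tmrca_at <- function(segments, at) {
  stopifnot(inherits(segments, "pair_segments"))
  idx <- findInterval(at, segments$start)
  idx[at < 0 | at >= attr(segments, "seq_length")] <- NA_integer_
  segments$tmrca[idx]
}

#' Write a segment series to a TSV file
#'
#' Three columns (`start`, `end`, `tmrca`), 0-based half-open bp coordinates.
#'
#' @param segments a `pair_segments` tibble.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  stopifnot(inherits(segments, "pair_segments"))
  utils::write.table(as.data.frame(segments)[, c("start", "end", "tmrca")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
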