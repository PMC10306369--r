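# T_MRCA-segment analytics: time discretization, TL-distribution summaries
# and the segment-age transition matrix.

#' Logarithmic time discretization
#'
#' Time bins in the style of multiple-sequential-Markov-coalescent methods:
#' the lower boundary of bin `i` (i = 0..m-1) is `-8 N_ref log(1 - i/m)`
#' (natural logarithm), with an implicit upper boundary at infinity for the
#' last bin. Bin membership uses half-open `[lower, upper)` intervals.
#'
#' @param N_ref reference diploid population size.
#' @param m number of bins (`>= 2`).
#' @return A list of class `time_grid` with elements `m`, `N_ref` and
#'   `boundaries` (length `m`, first element 0).
#' @examples
#' time_grid(40000, 20)
#' @export
time_grid <- function(N_ref, m = 20) {
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  if (N_ref <= 0) stop("N_ref must be positive", call. = FALSE)
  i <- 0:(m - 1)
  structure(list(m = as.integer(m), N_ref = N_ref,
                 boundaries = -8 * N_ref * log(1 - i / m)),
            class = "time_grid")
}

#' @export
print.time_grid <- function(x, ...) {
  cat(sprintf("Time grid: %d bins, N_ref = %g\n", x$m, x$N_ref))
  cat("  lower boundaries:", format(signif(x$boundaries, 4)), "\n")
  invisible(x)
}

#' Assign segment ages to time-grid bins
#'
#' @param grid a [time_grid()].
#' @param age ages in generations (non-negative; 0 maps to bin 1).
#' @return Integer bin indices in `1..m`.
#' @export
grid_bin <- function(grid, age) {
  stopifnot(inherits(grid, "time_grid"))
  pmax(findInterval(age, grid$boundaries), 1L)
}

#' Summaries of the joint age-length (TL) distribution
#'
#' Computes the sample covariance of `(log10 age, log10 length)` over
#' segments, marginal histograms on the time grid, and the per-bin mean
#' log10 segment length. With a single segment the covariance is undefined
#' and reported as `NaN`.
#'
#' @param segments a `pair_segments` tibble (rows from several pairs may be
#'   concatenated with [dplyr::bind_rows()]).
#' @param grid a [time_grid()].
#' @return A list of class `tl_summary`: `covariance`, `n_segments`, and a
#'   tibble `per_bin` with columns `bin`, `lower`, `n`, `mean_log10_length`.
#' @export
tl_summaries <- function(segments, grid) {
  if (nrow(segments) == 0) stop("empty segment series", call. = FALSE)
  la <- log10(segments$tmrca)
  ll <- log10(segments$end - segments$start)
  cv <- if (nrow(segments) < 2) NaN else stats::cov(la, ll)
  bin <- grid_bin(grid, segments$tmrca)
  per_bin <- tibble::tibble(bin = seq_len(grid$m),
                            lower = grid$boundaries) |>
    dplyr::left_join(
      tibble::tibble(bin = bin, ll = ll) |>
        dplyr::group_by(.data$bin) |>
        dplyr::summarise(n = dplyr::n(), mean_log10_length = mean(.data$ll)),
      by = "bin")
  per_bin$n[is.na(per_bin$n)] <- 0L
  structure(list(covariance = cv, n_segments = nrow(segments),
                 per_bin = per_bin,
                 log10_age = la, log10_length = ll),
            class = "tl_summary")
}

#' @export
print.tl_summary <- function(x, ...) {
  cat(sprintf("TL-distribution: %d segments, cov(log10 age, log10 length) = %.4f\n",
              x$n_segments, x$covariance))
  invisible(x)
}

#' Transition matrix of segment ages along the genome
#'
#' Counts, for adjacent T_MRCA-segments scanned left to right, how often a
#' segment in age bin `a` is followed by one in bin `b`; probabilities are
#' row-normalised counts. Rows with no observations are all-zero and listed
#' in the `empty_rows` attribute rather than smoothed.
#'
#' @param segments a `pair_segments` tibble with at least two segments.
#' @param grid a [time_grid()].
#' @return An object of class `tmatrix` with elements `probs`, `counts`
#'   (both `m x m`) and `grid`.
#' @export
tm_true <- function(segments, grid) {
  if (nrow(segments) < 2)
    stop("need at least two segments", call. = FALSE)
  bin <- grid_bin(grid, segments$tmrca)
  m <- grid$m
  counts <- matrix(0L, m, m)
  from <- bin[-length(bin)]
  to <- bin[-1]
  for (i in seq_along(from))
    counts[from[i], to[i]] <- counts[from[i], to[i]] + 1L
  rs <- rowSums(counts)
  probs <- counts / ifelse(rs == 0, 1, rs)
  structure(list(probs = probs, counts = counts, grid = grid,
                 empty_rows = which(rs == 0)),
            class = "tmatrix")
}

#' @export
print.tmatrix <- function(x, ...) {
  cat(sprintf("Segment-age transition matrix (%d x %d), %d transitions\n",
              nrow(x$probs), ncol(x$probs), sum(x$counts)))
  invisible(x)
}

#' Serialize a transition matrix to TSV
#'
#' Writes the probability matrix with a header row naming the grid's lower
#' bin boundaries.
#'
#' @param x a `tmatrix`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tmatrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "tmatrix"))
  pm <- x$probs
  colnames(pm) <- sprintf("ge_%g", x$grid$boundaries)
  utils::write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Lag-one clustering of old segments
#'
#' Autocorrelation at lag one segment of the indicator `tmrca > cutoff`,
#' with a permutation p-value for the null of no spatial clustering of old
#' segments along the chromosome.
#'
#' @param segments a `pair_segments` tibble.
#' @param cutoff age cutoff in generations (e.g. the transition age).
#' @param n_perm number of permutations.
#' @param seed optional integer seed.
#' @return A list with `statistic` (lag-1 autocorrelation) and `p_value`.
#' @export
old_segment_clustering <- function(segments, cutoff, n_perm = 999,
                                   seed = NULL) {
  ind <- as.numeric(segments$tmrca > cutoff)
  if (length(ind) < 3 || stats::var(ind) == 0)
    return(list(statistic = NA_real_, p_value = NA_real_))
  lag1 <- function(v) stats::cor(v[-length(v)], v[-1])
  obs <- lag1(ind)
  .with_seed(seed, {
    perm <- replicate(n_perm, lag1(sample(ind)))
    list(statistic = obs,
         p_value = (1 + sum(perm >= obs)) / (n_perm + 1))
  })
}
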