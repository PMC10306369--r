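#' Population-genetic rescalings under partial self-fertilization
#'
#' A population of `N` diploids in which a fraction `sigma` of offspring are
#' produced by self-fertilization has, at equilibrium, inbreeding coefficient
#' `F = sigma / (2 - sigma)`. Selfing shrinks the effective population size to
#' `N / (1 + F)` and the effective recombination rate to `r (1 - F)`, so the
#' population-scaled rates become `rho_sigma = 4 N r (1 - F) / (1 + F)` and
#' `theta_sigma = 4 N mu / (1 + F)`.
#'
#' @param N census diploid population size (positive).
#' @param r per-site per-generation recombination rate.
#' @param mu per-site per-generation mutation rate.
#' @param sigma selfing rate in `[0, 1]`.
#' @return A one-row tibble with columns `F`, `N_sigma`, `r_sigma`,
#'   `rho_sigma`, `theta_sigma`.
#' @examples
#' selfing_rescalings(N = 50000, r = 3.6e-9, mu = 6.95e-9, sigma = 0.95)
#' @export
selfing_rescalings <- function(N, r = 0, mu = 0, sigma = 0) {
  if (any(N <= 0)) stop("N must be positive", call. = FALSE)
  if (any(sigma < 0 | sigma > 1)) stop("sigma must lie in [0, 1]", call. = FALSE)
  if (any(r < 0) || any(mu < 0)) stop("rates must be non-negative", call. = FALSE)
  F <- sigma / (2 - sigma)
  tibble::tibble(
    F = F,
    N_sigma = N / (1 + F),
    r_sigma = r * (1 - F),
    rho_sigma = 4 * N * r * (1 - F) / (1 + F),
    theta_sigma = 4 * N * mu / (1 + F)
  )
}

#' Piecewise-constant demographic model with time-varying selfing
#'
#' An epoch model is a tibble of epochs ordered by `start_time` (generations
#' before present, first epoch starting at 0). Within an epoch the census size
#' `N`, selfing rate `sigma` and per-site recombination rate `rec_rate` are
#' constant; epochs are half-open intervals `[start_time, next_start)` and the
#' last epoch extends to infinity.
#'
#' @param start_time numeric vector of epoch start times, strictly
#'   increasing, first element 0.
#' @param N census diploid sizes per epoch.
#' @param sigma selfing rates per epoch, each in `[0, 1]`.
#' @param rec_rate per-site recombination rates per epoch (recycled).
#' @return A tibble of class `epoch_model`.
#' @examples
#' epoch_model(start_time = c(0, 2e5), N = 50000, sigma = c(0.95, 0),
#'             rec_rate = 3.6e-9)
#' @export
epoch_model <- function(start_time, N, sigma, rec_rate) {
  df <- tibble::tibble(start_time = start_time, N = N, sigma = sigma,
                       rec_rate = rec_rate)
  if (nrow(df) == 0) stop("at least one epoch required", call. = FALSE)
  if (df$start_time[1] != 0) stop("first epoch must start at 0", call. = FALSE)
  if (is.unsorted(df$start_time, strictly = TRUE))
    stop("epoch start times must be strictly increasing", call. = FALSE)
  if (any(df$N <= 0)) stop("N must be positive", call. = FALSE)
  if (any(df$sigma < 0 | df$sigma > 1))
    stop("sigma must lie in [0, 1]", call. = FALSE)
  if (any(df$rec_rate < 0))
    stop("rec_rate must be non-negative", call. = FALSE)
  df$F <- df$sigma / (2 - df$sigma)
  class(df) <- c("epoch_model", class(df))
  df
}

#' Look up epoch parameters at given times
#'
#' @param model an [epoch_model()].
#' @param t times in generations before present (non-negative).
#' @return A tibble with one row per element of `t` giving the epoch
#'   parameters in force at that time.
#' @export
model_at <- function(model, t) {
  stopifnot(inherits(model, "epoch_model"))
  if (any(t < 0)) stop("t must be non-negative", call. = FALSE)
  idx <- findInterval(t, model$start_time)
  out <- tibble::as_tibble(model)[idx, , drop = FALSE]
  out$t <- t
  dplyr::relocate(out, "t")
}

#' Single-transition scenario
#'
#' The canonical two-change scenario: the selfing rate jumps from `sigma_anc`
#' to `sigma_pres` at `t_sigma` generations before present, and the census
#' size from `N_anc` to `N_pres` at `t_N`. Converts losslessly to an
#' [epoch_model()] with at most three epochs.
#'
#' @param N_pres,N_anc present and ancestral census sizes.
#' @param t_N age of the size change in generations (`>= 0`).
#' @param sigma_pres,sigma_anc present and ancestral selfing rates.
#' @param t_sigma age of the selfing transition in generations (`>= 0`).
#' @param rec_rate per-site recombination rate.
#' @param mut_rate per-site mutation rate.
#' @return A list of class `transition_scenario`.
#' @examples
#' sc <- transition_scenario(N_pres = 40000, N_anc = 40000, t_N = 0,
#'                           sigma_pres = 0.99, sigma_anc = 0.1,
#'                           t_sigma = 40000, rec_rate = 1e-8, mut_rate = 1e-8)
#' as_epoch_model(sc)
#' @export
transition_scenario <- function(N_pres, N_anc = N_pres, t_N = 0,
                                sigma_pres = 0, sigma_anc = sigma_pres,
                                t_sigma = 0, rec_rate = 1e-8,
                                mut_rate = 1e-8) {
  if (t_N < 0 || t_sigma < 0)
    stop("t_N and t_sigma must be non-negative", call. = FALSE)
  if (N_pres <= 0 || N_anc <= 0) stop("sizes must be positive", call. = FALSE)
  for (s in c(sigma_pres, sigma_anc))
    if (s < 0 || s > 1) stop("sigma must lie in [0, 1]", call. = FALSE)
  structure(list(N_pres = N_pres, N_anc = N_anc, t_N = t_N,
                 sigma_pres = sigma_pres, sigma_anc = sigma_anc,
                 t_sigma = t_sigma, rec_rate = rec_rate,
                 mut_rate = mut_rate),
            class = "transition_scenario")
}

#' @export
print.transition_scenario <- function(x, ...) {
  cat("Transition scenario:\n")
  cat(sprintf("  N: %g -> %g at t_N = %g generations\n",
              x$N_anc, x$N_pres, x$t_N))
  cat(sprintf("  sigma: %g -> %g at t_sigma = %g generations\n",
              x$sigma_anc, x$sigma_pres, x$t_sigma))
  cat(sprintf("  r = %g, mu = %g per site per generation\n",
              x$rec_rate, x$mut_rate))
  invisible(x)
}

#' Convert an object to an epoch model
#'
#' @param x object to convert.
#' @param ... passed to methods.
#' @export
as_epoch_model <- function(x, ...) UseMethod("as_epoch_model")

#' @export
as_epoch_model.epoch_model <- function(x, ...) x

#' @rdname as_epoch_model
#' @export
as_epoch_model.transition_scenario <- function(x, ...) {
  breaks <- sort(unique(c(0, x$t_N, x$t_sigma)))
  N <- ifelse(breaks < x$t_N, x$N_pres, x$N_anc)
  sg <- ifelse(breaks < x$t_sigma, x$sigma_pres, x$sigma_anc)
  # a change at time 0 means the ancestral value applies from the present on
  epoch_model(start_time = breaks, N = N, sigma = sg, rec_rate = x$rec_rate)
}

#' Probability of an effective recombination event given the coalescence time
#'
#' For a sample of size two whose current coalescence time is `s`, the
#' probability that at least one effective recombination event falls on the
#' genealogy is `1 - exp(-I(s))` with
#' `I(s) = integral_0^s 2 (1 - sigma_k) (2 - sigma_k)^-2 r_k dk`, evaluated in
#' closed form over the epochs intersecting `[0, s]`. Under full selfing the
#' integrand vanishes and the probability is zero.
#'
#' @param model an [epoch_model()].
#' @param s coalescence times in generations (vectorised, `>= 0`).
#' @return Numeric vector of probabilities in `[0, 1)`.
#' @export
recomb_prob_given_tmrca <- function(model, s) {
  stopifnot(inherits(model, "epoch_model"))
  if (any(s < 0)) stop("s must be non-negative", call. = FALSE)
  dens <- 2 * (1 - model$sigma) * (2 - model$sigma)^-2 * model$rec_rate
  cum <- c(0, cumsum(dens[-length(dens)] * diff(model$start_time)))
  idx <- findInterval(s, model$start_time)
  integral <- cum[idx] + dens[idx] * (s - model$start_time[idx])
  1 - exp(-integral)
}

# internal: epoch model as the plain matrix the C++ cores consume
.model_matrix <- function(model) {
  stopifnot(inherits(model, "epoch_model"))
  as.matrix(tibble::as_tibble(model)[, c("start_time", "N", "sigma", "rec_rate")])
}
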