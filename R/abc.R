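# Rejection ABC with PLS dimension reduction: priors, reference tables,
# model choice via Bayes factors, posterior summaries and the validation
# experiment.

#' Prior specifications for the two competing demographies
#'
#' Model 1 is a constant-size population with a single transition in selfing
#' rate (parameters `N`, `sigma_anc`, `sigma_pres`, `t_sigma`); model 2 has a
#' constant selfing rate and a single size change (`N_pres`, `N_anc`,
#' `sigma`, `t_N`). Distributions are independent uniforms or log-uniforms.
#'
#' @param param,dist,lower,upper vectors describing one distribution per
#'   parameter (`dist` is `"unif"` or `"logunif"`).
#' @return A tibble of class `prior_spec`.
#' @export
prior_spec <- function(param, dist, lower, upper) {
  df <- tibble::tibble(param = param, dist = dist, lower = lower,
                       upper = upper)
  if (!all(df$dist %in% c("unif", "logunif")))
    stop("dist must be 'unif' or 'logunif'", call. = FALSE)
  if (any(!is.finite(df$lower)) || any(!is.finite(df$upper)) ||
      any(df$lower > df$upper))
    stop("prior bounds must be finite with lower <= upper", call. = FALSE)
  if (any(df$dist == "logunif" & df$lower <= 0))
    stop("log-uniform bounds must be positive", call. = FALSE)
  class(df) <- c("prior_spec", class(df))
  df
}

#' @rdname prior_spec
#' @export
model1_prior <- function() {
  prior_spec(param = c("N", "sigma_anc", "sigma_pres", "t_sigma"),
             dist = c("logunif", "unif", "unif", "logunif"),
             lower = c(1e3, 0, 0.8, 1e2),
             upper = c(1e6, 0.2, 0.999, 1e6))
}

#' @rdname prior_spec
#' @export
model2_prior <- function() {
  prior_spec(param = c("N_pres", "N_anc", "sigma", "t_N"),
             dist = c("logunif", "logunif", "unif", "logunif"),
             lower = c(1e3, 1e3, 0, 1e2),
             upper = c(1e6, 1e6, 0.999, 1e6))
}

#' Draw parameter vectors from a prior
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional integer seed.
#' @return A tibble with one column per parameter and `n` rows.
#' @export
sample_prior <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"))
  .with_seed(seed, {
    cols <- lapply(seq_len(nrow(spec)), function(i) {
      if (spec$dist[i] == "unif") {
        stats::runif(n, spec$lower[i], spec$upper[i])
      } else {
        10^stats::runif(n, log10(spec$lower[i]), log10(spec$upper[i]))
      }
    })
    names(cols) <- spec$param
    tibble::as_tibble(cols)
  })
}

.weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord]) / sum(w)
  sapply(probs, function(p) x[which(cw >= p)[1]])
}

# transform used on the supervision side of the PLS and for posterior
# densities: log-uniform parameters are handled on log10 scale
.param_transform <- function(spec, values, param) {
  d <- spec$dist[spec$param == param]
  if (length(d) && d == "logunif") log10(values) else values
}

.param_backtransform <- function(spec, values, param) {
  d <- spec$dist[spec$param == param]
  if (length(d) && d == "logunif") 10^values else values
}

#' Simulation dimensions for a reference table
#'
#' @param n_hap haplotypes per locus.
#' @param L locus length in bp.
#' @param n_loci number of independent loci (statistics are averaged across
#'   loci).
#' @param mut_rate,rec_rate per-site rates.
#' @param window_size TM_win window size in bp.
#' @return A list of class `sim_dims`.
#' @export
sim_dims <- function(n_hap = 8, L = 5e5, n_loci = 2, mut_rate = 1e-8,
                     rec_rate = 1e-8, window_size = 10000) {
  structure(list(n_hap = n_hap, L = L, n_loci = n_loci,
                 mut_rate = mut_rate, rec_rate = rec_rate,
                 window_size = window_size),
            class = "sim_dims")
}

#' Turn a drawn parameter vector into a transition scenario
#'
#' @param model_id 1 (selfing transition, constant size) or 2 (size change,
#'   constant selfing).
#' @param params a one-row data frame or named list of parameter values.
#' @param dims a [sim_dims()] providing the mutation and recombination rates.
#' @return A [transition_scenario()].
#' @export
params_to_scenario <- function(model_id, params, dims) {
  p <- as.list(params)
  if (model_id == 1) {
    transition_scenario(N_pres = p$N, N_anc = p$N, t_N = 0,
                        sigma_pres = p$sigma_pres, sigma_anc = p$sigma_anc,
                        t_sigma = p$t_sigma,
                        rec_rate = dims$rec_rate, mut_rate = dims$mut_rate)
  } else if (model_id == 2) {
    transition_scenario(N_pres = p$N_pres, N_anc = p$N_anc, t_N = p$t_N,
                        sigma_pres = p$sigma, sigma_anc = p$sigma,
                        t_sigma = 0,
                        rec_rate = dims$rec_rate, mut_rate = dims$mut_rate)
  } else stop("model_id must be 1 or 2", call. = FALSE)
}

#' Simulate a multi-locus dataset under a scenario
#'
#' @param scenario a [transition_scenario()] (or epoch model).
#' @param dims a [sim_dims()].
#' @param seed optional integer seed.
#' @return List of [haplotype_alignment()]s, one per locus.
#' @export
simulate_dataset <- function(scenario, dims, seed = NULL) {
  .with_seed(seed, {
    lapply(seq_len(dims$n_loci), function(i)
      simulate_sample(scenario, n = dims$n_hap, L = dims$L,
                      mu = dims$mut_rate)$alignment)
  })
}

#' Summarise a multi-locus dataset
#'
#' Per-locus summary vectors combined by element-wise averaging.
#'
#' @param alns list of [haplotype_alignment()]s.
#' @param spec,class_edges,... passed to [summary_vector()].
#' @return Named numeric vector.
#' @export
dataset_summary <- function(alns, spec = "all", class_edges = NULL, ...) {
  combine_loci(lapply(alns, summary_vector, spec = spec,
                      class_edges = class_edges, ...))
}

#' Calibrate diversity-class edges for TM_win
#'
#' The class edges are set at evenly spaced percentiles (12.5, 25, ...,
#' 87.5 by default, giving eight classes) of per-window pairwise-difference
#' counts pooled over a pilot batch of prior-predictive simulations, and are
#' then frozen alongside the reference table so that observed and simulated
#' data are discretized identically. The pilot uses the pairwise simulator,
#' since only two-haplotype window counts are needed.
#'
#' @param prior a [prior_spec()] for model 1.
#' @param dims a [sim_dims()].
#' @param n_pilot number of pilot simulations.
#' @param k number of diversity classes.
#' @param seed optional integer seed.
#' @return Numeric vector of `k - 1` strictly increasing edges (possibly
#'   fewer after deduplication of tied integer quantiles).
#' @export
calibrate_class_edges <- function(prior, dims, n_pilot = 1000, k = 8,
                                  seed = NULL) {
  .with_seed(seed, {
    draws <- sample_prior(prior, n_pilot)
    counts <- unlist(lapply(seq_len(n_pilot), function(i) {
      sc <- params_to_scenario(1, draws[i, ], dims)
      segs <- simulate_pair(sc, dims$L)
      aln <- overlay_mutations(segs, dims$mut_rate)
      window_diversity(aln, c(1, 2), dims$window_size)
    }))
    probs <- seq_len(k - 1) / k
    edges <- unique(ceiling(stats::quantile(counts, probs, names = FALSE)))
    edges[edges > 0]
  })
}

#' Build an ABC reference table
#'
#' Draws `n_sims` parameter vectors from the prior, simulates a multi-locus
#' dataset for each, computes its summary vector with the frozen diversity
#' classes, and fits the per-column normaliser (columns with zero variance
#' are dropped and recorded).
#'
#' @param model_id 1 or 2.
#' @param prior a [prior_spec()] (defaults to the model's standard prior).
#' @param dims a [sim_dims()].
#' @param n_sims number of simulations (`>= 100`).
#' @param class_edges frozen diversity-class edges from
#'   [calibrate_class_edges()].
#' @param spec summary set: `"all"`, `"sfs_ld"` or `"tmwin"`.
#' @param seed optional integer seed.
#' @param progress print a progress line every 500 simulations.
#' @return An object of class `reference_table`.
#' @export
build_reference_table <- function(model_id, prior = NULL, dims = sim_dims(),
                                  n_sims = 1000, class_edges = NULL,
                                  spec = "all", seed = NULL,
                                  progress = FALSE) {
  if (n_sims < 100) stop("n_sims must be at least 100", call. = FALSE)
  if (is.null(prior))
    prior <- if (model_id == 1) model1_prior() else model2_prior()
  if (spec %in% c("all", "tmwin") && is.null(class_edges))
    stop("class_edges must be supplied for TM_win statistics", call. = FALSE)
  .with_seed(seed, {
    params <- sample_prior(prior, n_sims)
    rows <- vector("list", n_sims)
    for (i in seq_len(n_sims)) {
      sc <- params_to_scenario(model_id, params[i, ], dims)
      alns <- simulate_dataset(sc, dims)
      rows[[i]] <- dataset_summary(alns, spec = spec,
                                   class_edges = class_edges,
                                   window_size = dims$window_size)
      if (progress && i %% 500 == 0)
        message(sprintf("  model %d: %d / %d simulations", model_id, i, n_sims))
    }
    stats_mat <- do.call(rbind, rows)
    ctr <- colMeans(stats_mat)
    scl <- apply(stats_mat, 2, stats::sd)
    keep <- is.finite(scl) & scl > 0
    structure(list(model_id = model_id, prior = prior, dims = dims,
                   params = params, stats = stats_mat,
                   center = ctr, scale = scl, keep = keep,
                   class_edges = class_edges, spec = spec,
                   pls = NULL, n_comp = NULL),
              class = "reference_table")
  })
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("ABC reference table (model %d): %d simulations, %d statistics (%d retained)\n",
              x$model_id, nrow(x$stats), ncol(x$stats), sum(x$keep)))
  if (!is.null(x$pls))
    cat(sprintf("  PLS: %d components\n", x$n_comp))
  invisible(x)
}

.normalize_stats <- function(table, stats_mat) {
  if (is.null(dim(stats_mat))) stats_mat <- matrix(stats_mat, nrow = 1,
                                                   dimnames = list(NULL, names(stats_mat)))
  if (ncol(stats_mat) != length(table$center))
    stop("summary-vector dimensions do not match the reference table",
         call. = FALSE)
  out <- sweep(stats_mat, 2, table$center, "-")
  out <- sweep(out, 2, ifelse(table$keep, table$scale, 1), "/")
  out[, table$keep, drop = FALSE]
}

#' Fit a partial-least-squares map on a reference table
#'
#' Supervised linear dimension reduction: PLS regression of the (transformed)
#' model parameters on the centred and scaled summary statistics. Distances
#' in [abc_reject()] are computed on the first `n_comp` PLS scores once this
#' map is fitted.
#'
#' @param table a [build_reference_table()] result.
#' @param n_comp number of components (default 20, truncated to the number of
#'   retained statistics columns).
#' @return The table with the fitted PLS map attached.
#' @export
fit_pls <- function(table, n_comp = 20) {
  stopifnot(inherits(table, "reference_table"))
  p <- sum(table$keep)
  if (n_comp < 1) stop("n_comp must be at least 1", call. = FALSE)
  if (n_comp > p) n_comp <- p
  X <- .normalize_stats(table, table$stats)
  Y <- sapply(table$prior$param, function(pm)
    .param_transform(table$prior, table$params[[pm]], pm))
  fit <- mixOmics::pls(X, Y, ncomp = n_comp, mode = "regression",
                       scale = FALSE)
  table$pls <- fit
  table$n_comp <- n_comp
  table
}

#' Project summary vectors into the table's comparison space
#'
#' @param table a `reference_table`.
#' @param stats_mat matrix (rows = datasets) or single named vector of raw
#'   summary statistics.
#' @return Matrix of normalised statistics or PLS scores.
#' @export
project_stats <- function(table, stats_mat) {
  X <- .normalize_stats(table, stats_mat)
  if (is.null(table$pls)) return(X)
  stats::predict(table$pls, X)$variates
}

#' Rejection ABC
#'
#' Euclidean distances between the observed and simulated summary vectors in
#' the table's comparison space (PLS scores when fitted, else normalised
#' statistics); the closest `tolerance` fraction of rows is accepted, ties at
#' the cutoff broken by row order.
#'
#' Optionally, `adjust = "loclinear"` applies the classical local-linear
#' regression correction: within the acceptance window, each (transformed)
#' parameter is regressed on the projected statistics with Epanechnikov
#' weights in distance, and the accepted values are shifted to the fitted
#' value at the observation plus their residuals (log10 scale for
#' log-uniform parameters, clipped to the prior support). The kernel weights
#' are retained and honoured by [posterior_summary()].
#'
#' @param obs observed summary vector (same construction and frozen class
#'   edges as the table).
#' @param table a `reference_table`.
#' @param tolerance accepted fraction in `(0, 1]`.
#' @param adjust `"none"` for plain rejection or `"loclinear"` for the
#'   regression-adjusted posterior.
#' @return An object of class `posterior_sample` with the accepted parameter
#'   draws, their kernel weights, distances and row indices.
#' @export
abc_reject <- function(obs, table, tolerance = 0.01,
                       adjust = c("none", "loclinear")) {
  stopifnot(inherits(table, "reference_table"))
  adjust <- match.arg(adjust)
  if (tolerance <= 0 || tolerance > 1)
    stop("tolerance must be in (0, 1]", call. = FALSE)
  ref <- project_stats(table, table$stats)
  po <- project_stats(table, obs)
  d <- sqrt(rowSums(sweep(ref, 2, as.numeric(po), "-")^2))
  n_acc <- max(1L, round(tolerance * nrow(ref)))
  idx <- order(d)[seq_len(n_acc)]
  acc <- table$params[idx, , drop = FALSE]
  w <- rep(1, n_acc)
  if (adjust == "loclinear" && n_acc > ncol(ref) + 2) {
    dmax <- max(d[idx])
    w <- if (dmax > 0) 1 - (d[idx] / dmax)^2 else rep(1, n_acc)
    w[w <= 0] <- min(w[w > 0]) / 2
    Z <- sweep(ref[idx, , drop = FALSE], 2, as.numeric(po))
    for (pm in table$prior$param) {
      y <- .param_transform(table$prior, acc[[pm]], pm)
      fit <- stats::lm.wfit(cbind(1, Z), y, w)
      adj <- fit$coefficients[1] + fit$residuals
      lo <- .param_transform(table$prior,
                             table$prior$lower[table$prior$param == pm], pm)
      hi <- .param_transform(table$prior,
                             table$prior$upper[table$prior$param == pm], pm)
      acc[[pm]] <- .param_backtransform(table$prior, pmin(pmax(adj, lo), hi),
                                        pm)
    }
  }
  structure(list(accepted = acc, weights = w,
                 distances = d[idx], indices = idx, adjust = adjust,
                 tolerance = tolerance, prior = table$prior,
                 n_sims = nrow(ref)),
            class = "posterior_sample")
}

#' @export
print.posterior_sample <- function(x, ...) {
  cat(sprintf("ABC posterior sample: %d accepted of %d (tolerance %g)\n",
              nrow(x$accepted), x$n_sims, x$tolerance))
  invisible(x)
}

#' ABC model choice via Bayes factors
#'
#' Pools the two reference tables (which must share dimensions, summary set
#' and class edges), normalises the pooled statistics jointly, accepts the
#' closest `tolerance` fraction of rows and reports the posterior probability
#' of model 1 and the Bayes factor `BF = P(m1|obs) / P(m2|obs)`. When one
#' model has no accepted rows the BF is capped at `n_accepted + 1` and
#' flagged. The decision rule "transition detected" uses `BF >= sqrt(10)`.
#'
#' As on the parameter-estimation side, distances are computed on a
#' supervised partial-least-squares projection: a PLS-DA map of the pooled
#' normalised statistics against the model label, with `n_comp` components
#' (set `n_comp = 0` to use the raw normalised statistics). Two estimators of
#' `P(m1 | obs)` are available. `"logistic"` (the default) fits a local
#' logistic regression of the model label on the projected statistics over
#' the `window` fraction of rows closest to the observation, weighted by an
#' Epanechnikov kernel in distance, and evaluates it at the observation;
#' `"rejection"` is the plain accepted-row count. The plain count is noisy
#' when the two prior predictive distributions overlap, which flattens the
#' detection curve; the local regression recovers the posterior probability
#' far more efficiently from the same reference tables.
#'
#' @param obs observed summary vector.
#' @param table1,table2 reference tables for models 1 and 2.
#' @param tolerance accepted fraction of the pooled table (rejection
#'   estimator, and reported acceptance counts).
#' @param threshold detection threshold on the Bayes factor.
#' @param method posterior-probability estimator, `"logistic"` or
#'   `"rejection"`.
#' @param n_comp number of PLS-DA components for the model-choice
#'   projection (truncated to the number of retained columns; 0 disables).
#' @param window fraction of rows used by the local logistic regression.
#' @return An object of class `model_choice_result`.
#' @export
model_choice <- function(obs, table1, table2, tolerance = 0.01,
                         threshold = sqrt(10),
                         method = c("logistic", "rejection"),
                         n_comp = 20, window = 0.1) {
  method <- match.arg(method)
  stopifnot(inherits(table1, "reference_table"),
            inherits(table2, "reference_table"))
  if (!identical(colnames(table1$stats), colnames(table2$stats)) ||
      !identical(table1$class_edges, table2$class_edges) ||
      !identical(unclass(table1$dims), unclass(table2$dims)))
    stop("reference tables were not built under identical settings",
         call. = FALSE)
  pooled <- rbind(table1$stats, table2$stats)
  lab <- rep(c(1L, 2L), c(nrow(table1$stats), nrow(table2$stats)))
  ctr <- colMeans(pooled)
  scl <- apply(pooled, 2, stats::sd)
  keep <- is.finite(scl) & scl > 0
  X <- sweep(pooled, 2, ctr, "-")
  X <- sweep(X, 2, ifelse(keep, scl, 1), "/")[, keep, drop = FALSE]
  ov <- matrix((as.numeric(obs) - ctr)[keep] / scl[keep], nrow = 1,
               dimnames = list(NULL, colnames(X)))
  if (n_comp > 0) {
    n_comp <- min(n_comp, ncol(X))
    da <- mixOmics::plsda(X, factor(lab), ncomp = n_comp, scale = FALSE)
    X <- da$variates$X
    ov <- stats::predict(da, ov)$variates
  }
  d <- sqrt(colSums((t(X) - as.numeric(ov))^2))
  n_acc <- max(1L, round(tolerance * nrow(X)))
  idx <- order(d)[seq_len(n_acc)]
  n1 <- sum(lab[idx] == 1L)
  n2 <- n_acc - n1
  if (method == "rejection") {
    capped <- n1 == 0 || n2 == 0
    bf <- if (capped) n_acc + 1 else n1 / n2
    if (capped && n1 == 0) bf <- 1 / (n_acc + 1)
    p1 <- n1 / n_acc
  } else {
    n_win <- max(max(50L, 2L * ncol(X)), round(window * nrow(X)))
    widx <- order(d)[seq_len(min(n_win, nrow(X)))]
    wts <- 1 - (d[widx] / max(d[widx]))^2
    Z <- sweep(X[widx, , drop = FALSE], 2, as.numeric(ov))
    y <- as.integer(lab[widx] == 1L)
    fit <- suppressWarnings(stats::glm(y ~ Z, family = stats::binomial,
                                       weights = wts))
    p1 <- as.numeric(stats::plogis(stats::coef(fit)[1]))
    cap <- length(widx) + 1
    capped <- !is.finite(p1) || p1 >= cap / (cap + 1) || p1 <= 1 / (cap + 1)
    bf <- if (!is.finite(p1)) NA_real_ else p1 / (1 - p1)
    if (capped) bf <- if (isTRUE(p1 > 0.5)) cap else 1 / cap
  }
  structure(list(p_model1 = p1, bayes_factor = bf,
                 accepted = c(model1 = n1, model2 = n2),
                 method = method, capped = capped, threshold = threshold,
                 detected = bf >= threshold, tolerance = tolerance),
            class = "model_choice_result")
}

#' @export
print.model_choice_result <- function(x, ...) {
  cat(sprintf("Model choice: P(transition model) = %.3f, BF = %.3g%s\n",
              x$p_model1, x$bayes_factor, if (x$capped) " (capped)" else ""))
  cat(sprintf("  transition %s at BF >= %.3g\n",
              if (x$detected) "DETECTED" else "not detected", x$threshold))
  invisible(x)
}

#' Posterior mode and credibility interval
#'
#' Per replicate, a Gaussian kernel density (bandwidth by the standard
#' reference rule) of the accepted values is evaluated on a fixed grid
#' spanning the prior support (on log10 scale for log-uniform parameters);
#' the densities are averaged across replicates and the mode is the grid
#' argmax. The credibility interval is formed from quantiles of the pooled
#' accepted values.
#'
#' @param samples a `posterior_sample` or list of them (replicates).
#' @param parameter parameter name.
#' @param level credibility level (default 0.95).
#' @param grid_n grid resolution.
#' @return A one-row tibble: `parameter`, `mode`, `lower`, `upper`, `level`,
#'   `n_accepted`.
#' @export
posterior_summary <- function(samples, parameter, level = 0.95,
                              grid_n = 512) {
  if (inherits(samples, "posterior_sample")) samples <- list(samples)
  if (!length(samples)) stop("no posterior samples given", call. = FALSE)
  prior <- samples[[1]]$prior
  if (!parameter %in% prior$param)
    stop("unknown parameter: ", parameter, call. = FALSE)
  lo <- .param_transform(prior, prior$lower[prior$param == parameter], parameter)
  hi <- .param_transform(prior, prior$upper[prior$param == parameter], parameter)
  grid <- seq(lo, hi, length.out = grid_n)
  dens <- rep(0, grid_n)
  pooled <- numeric(0)
  pooled_w <- numeric(0)
  for (s in samples) {
    v <- .param_transform(prior, s$accepted[[parameter]], parameter)
    if (!length(v)) stop("empty acceptance set", call. = FALSE)
    w <- s$weights
    if (is.null(w)) w <- rep(1, length(v))
    pooled <- c(pooled, s$accepted[[parameter]])
    pooled_w <- c(pooled_w, w / sum(w))
    if (length(unique(v)) == 1) {
      dens[which.min(abs(grid - v[1]))] <- dens[which.min(abs(grid - v[1]))] + 1
    } else {
      kd <- suppressWarnings(stats::density(v, weights = w / sum(w),
                                            from = lo, to = hi, n = grid_n))
      dens <- dens + kd$y
    }
  }
  mode_t <- grid[which.max(dens)]
  a <- (1 - level) / 2
  qs <- .weighted_quantile(pooled, pooled_w, c(a, 1 - a))
  tibble::tibble(parameter = parameter,
                 mode = .param_backtransform(prior, mode_t, parameter),
                 lower = qs[1], upper = qs[2], level = level,
                 n_accepted = length(pooled))
}

#' Model-choice and recovery performance across transition ages
#'
#' For each transition age on the grid, simulates `n_reps` pseudo-observed
#' datasets under the transition model (constant size `N`, selfing jumping
#' from `sigma_anc` to `sigma_pres`), runs the model choice against the two
#' reference tables and the rejection step against the transition-model
#' table, and reports the fraction of datasets with `BF >= threshold`
#' together with posterior quantiles for the transition age.
#'
#' @param t_sigma_grid transition ages (generations) to scan.
#' @param n_reps datasets per grid point.
#' @param table1,table2 reference tables (model 1 and model 2).
#' @param dims a [sim_dims()] (should match the tables).
#' @param N,sigma_anc,sigma_pres data-generating values.
#' @param tolerance acceptance fraction.
#' @param threshold Bayes-factor detection threshold.
#' @param method model-choice estimator, see [model_choice()].
#' @param seed optional integer seed.
#' @return A tibble with one row per grid point.
#' @export
validate_performance <- function(t_sigma_grid, n_reps, table1, table2,
                                 dims = table1$dims, N = 40000,
                                 sigma_anc = 0.1, sigma_pres = 0.99,
                                 tolerance = 0.01, threshold = sqrt(10),
                                 method = "logistic", seed = NULL) {
  .with_seed(seed, {
    out <- lapply(t_sigma_grid, function(ts) {
      det <- logical(n_reps)
      modes <- q25 <- q75 <- numeric(n_reps)
      for (r in seq_len(n_reps)) {
        sc <- transition_scenario(N_pres = N, N_anc = N, t_N = 0,
                                  sigma_pres = sigma_pres,
                                  sigma_anc = sigma_anc, t_sigma = ts,
                                  rec_rate = dims$rec_rate,
                                  mut_rate = dims$mut_rate)
        obs <- dataset_summary(simulate_dataset(sc, dims),
                               spec = table1$spec,
                               class_edges = table1$class_edges,
                               window_size = dims$window_size)
        mc <- model_choice(obs, table1, table2, tolerance, threshold,
                           method = method)
        det[r] <- mc$detected
        post <- abc_reject(obs, table1, tolerance)
        ts_acc <- post$accepted$t_sigma
        modes[r] <- posterior_summary(post, "t_sigma")$mode
        q25[r] <- stats::quantile(ts_acc, 0.25)
        q75[r] <- stats::quantile(ts_acc, 0.75)
      }
      tibble::tibble(t_sigma = ts, n_reps = n_reps,
                     frac_detected = mean(det),
                     mode_median = stats::median(modes),
                     q25_median = stats::median(q25),
                     q75_median = stats::median(q75))
    })
    dplyr::bind_rows(out)
  })
}

#' Persist a reference table as plain-text files
#'
#' Writes `params.tsv`, `stats.tsv` and a JSON sidecar with the normaliser,
#' class edges, prior, dimensions and PLS component count. The PLS map is
#' refitted deterministically on load.
#'
#' @param table a `reference_table`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_reference_table <- function(table, dir) {
  stopifnot(inherits(table, "reference_table"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(as.data.frame(table$params), file.path(dir, "params.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(as.data.frame(table$stats), file.path(dir, "stats.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  side <- list(model_id = table$model_id,
               prior = as.data.frame(table$prior),
               dims = unclass(table$dims),
               center = as.list(table$center), scale = as.list(table$scale),
               keep = as.list(table$keep),
               class_edges = table$class_edges, spec = table$spec,
               n_comp = table$n_comp)
  jsonlite::write_json(side, file.path(dir, "table.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_reference_table
#' @param dir directory written by [save_reference_table()].
#' @export
load_reference_table <- function(dir) {
  side <- jsonlite::read_json(file.path(dir, "table.json"),
                              simplifyVector = TRUE)
  params <- tibble::as_tibble(utils::read.table(
    file.path(dir, "params.tsv"), header = TRUE, sep = "\t"))
  stats_mat <- as.matrix(utils::read.table(
    file.path(dir, "stats.tsv"), header = TRUE, sep = "\t",
    check.names = FALSE))
  tab <- structure(list(
    model_id = side$model_id,
    prior = prior_spec(side$prior$param, side$prior$dist, side$prior$lower,
                       side$prior$upper),
    dims = do.call(sim_dims, side$dims),
    params = params, stats = stats_mat,
    center = unlist(side$center), scale = unlist(side$scale),
    keep = unlist(side$keep),
    class_edges = side$class_edges, spec = side$spec,
    pls = NULL, n_comp = NULL), class = "reference_table")
  if (length(side$n_comp)) tab <- fit_pls(tab, side$n_comp)
  tab
}
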