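# Shared small fixtures, all built in code.

const_model <- function(N = 10000, sigma = 0, r = 1e-8) {
  epoch_model(start_time = 0, N = N, sigma = sigma, rec_rate = r)
}

# random piecewise models for property-style checks
random_model <- function(max_epochs = 4) {
  k <- sample(1:max_epochs, 1)
  epoch_model(start_time = c(0, sort(stats::runif(k - 1, 1, 1e6))),
              N = stats::runif(k, 1e3, 1e5),
              sigma = stats::runif(k, 0, 1),
              rec_rate = stats::runif(k, 0, 5e-8))
}

# numerical quadrature oracle for the effective-recombination probability,
# integrating the printed integrand epoch by epoch
recomb_prob_quadrature <- function(model, s) {
  f <- function(t) {
    idx <- findInterval(t, model$start_time)
    2 * (1 - model$sigma[idx]) * (2 - model$sigma[idx])^-2 * model$rec_rate[idx]
  }
  cuts <- unique(c(0, model$start_time[model$start_time < s], s))
  total <- 0
  for (i in seq_len(length(cuts) - 1)) {
    total <- total + stats::integrate(f, cuts[i], cuts[i + 1],
                                      rel.tol = 1e-13, abs.tol = 1e-15)$value
  }
  1 - exp(-total)
}

# tiny deterministic alignment: 4 haplotypes, derived counts {1, 1, 2}
toy_alignment <- function() {
  geno <- rbind(c(1, 0, 1),
                c(0, 0, 1),
                c(0, 1, 0),
                c(0, 0, 0))
  haplotype_alignment(geno, positions = c(100, 5000, 12000),
                      seq_length = 30000)
}

# minimal hand-written reference table for estimator contract tests
fake_table <- function(stats_vals, params, model_id = 1,
                       prior = model1_prior()) {
  stats_mat <- as.matrix(stats_vals)
  colnames(stats_mat) <- paste0("s", seq_len(ncol(stats_mat)))
  ctr <- colMeans(stats_mat)
  scl <- apply(stats_mat, 2, stats::sd)
  keep <- is.finite(scl) & scl > 0
  structure(list(model_id = model_id, prior = prior, dims = sim_dims(),
                 params = tibble::as_tibble(params), stats = stats_mat,
                 center = ctr, scale = scl, keep = keep,
                 class_edges = c(1, 2), spec = "all",
                 pls = NULL, n_comp = NULL),
            class = "reference_table")
}
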