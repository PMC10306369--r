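test_that("prior draws honour their declared distributions", {
  ps <- prior_spec(param = c("a", "b"), dist = c("unif", "logunif"),
                   lower = c(0, 1e2), upper = c(1, 1e6))
  d <- sample_prior(ps, 10000, seed = 1)
  expect_gt(stats::ks.test(d$a, "punif")$p.value, 0.01)
  expect_gt(stats::ks.test(log10(d$b), "punif", 2, 6)$p.value, 0.01)
  expect_identical(d, sample_prior(ps, 10000, seed = 1))

  degen <- prior_spec("c", "unif", 0.7, 0.7)
  expect_true(all(sample_prior(degen, 50, seed = 2)$c == 0.7))
  expect_error(prior_spec("x", "unif", 2, 1), "lower <= upper")
  expect_error(prior_spec("x", "norm", 0, 1), "unif")
})

test_that("reference tables are reproducible and correctly normalised", {
  dims <- sim_dims(n_hap = 4, L = 1e5, n_loci = 1)
  tab <- build_reference_table(1, dims = dims, n_sims = 120,
                               class_edges = c(1, 3, 7), seed = 7)
  tab_b <- build_reference_table(1, dims = dims, n_sims = 120,
                                 class_edges = c(1, 3, 7), seed = 7)
  expect_identical(tab$stats, tab_b$stats)
  expect_identical(tab$params, tab_b$params)
  Z <- sweep(sweep(tab$stats, 2, tab$center), 2,
             ifelse(tab$keep, tab$scale, 1), "/")[, tab$keep]
  expect_equal(unname(colMeans(Z)), rep(0, ncol(Z)), tolerance = 1e-10)
  expect_equal(unname(apply(Z, 2, stats::sd)), rep(1, ncol(Z)),
               tolerance = 1e-10)
  expect_error(build_reference_table(1, dims = dims, n_sims = 50,
                                     class_edges = c(1)), "at least 100")
})

test_that("PLS recovers a synthetic linear parameter map", {
  withr::with_seed(11, {
    n <- 400
    params <- tibble::tibble(N = 10^stats::runif(n, 3, 6),
                             sigma_anc = stats::runif(n, 0, 0.2),
                             sigma_pres = stats::runif(n, 0.8, 0.999),
                             t_sigma = 10^stats::runif(n, 2, 6))
    Y <- scale(cbind(log10(params$N), params$sigma_anc,
                     log10(params$t_sigma)))
    A <- matrix(stats::rnorm(3 * 12), 3, 12)
    stats_vals <- Y %*% A + matrix(stats::rnorm(n * 12, sd = 0.05), n, 12)
    tab <- fake_table(stats_vals, params)
    tab <- fit_pls(tab, 3)
    sc <- project_stats(tab, tab$stats)
    for (j in 1:3) {
      r2 <- summary(stats::lm(Y[, j] ~ sc))$r.squared
      expect_gt(r2, 0.95)
    }
    expect_identical(sc, project_stats(tab, tab$stats))
    expect_error(fit_pls(tab, 0), "at least 1")
  })
})

test_that("rejection honours the tolerance and recovers planted rows", {
  withr::with_seed(12, {
    n <- 200
    params <- tibble::tibble(N = 10^stats::runif(n, 3, 6),
                             sigma_anc = stats::runif(n, 0, 0.2),
                             sigma_pres = stats::runif(n, 0.8, 0.999),
                             t_sigma = 10^stats::runif(n, 2, 6))
    stats_vals <- matrix(stats::rnorm(n * 5), n, 5)
    tab <- fake_table(stats_vals, params)
    # tolerance 1 returns the prior
    post <- abc_reject(stats_vals[1, ], tab, tolerance = 1)
    expect_equal(nrow(post$accepted), n)
    expect_equal(tibble::as_tibble(post$accepted[order(post$indices), ]),
                 params[order(seq_len(n)), ], ignore_attr = TRUE)
    # observation equal to a table row with minimal tolerance
    post1 <- abc_reject(stats_vals[42, ], tab, tolerance = 1 / n)
    expect_equal(post1$indices, 42L)
    expect_equal(nrow(post1$accepted), 1)
    expect_error(abc_reject(stats_vals[1, ], tab, tolerance = 0), "tolerance")
    expect_error(abc_reject(stats_vals[1, 1:3], tab, 0.1), "dimensions")
  })
})

test_that("model choice counting, Bayes factors and caps follow the contract", {
  n <- 100
  mkp <- function(n) tibble::tibble(N = rep(1e4, n), sigma_anc = 0.1,
                                    sigma_pres = 0.9, t_sigma = 1e3)
  t1 <- fake_table(matrix(seq(1, 2 * n - 1, by = 2), ncol = 1), mkp(n))
  t2 <- fake_table(matrix(seq(2, 2 * n, by = 2), ncol = 1), mkp(n),
                   model_id = 2)
  # interleaved distances from obs = 0: accepted split evenly
  mc <- model_choice(0, t1, t2, tolerance = 0.1, method = "rejection",
                     n_comp = 0)
  expect_equal(mc$p_model1, 0.5)
  expect_equal(mc$bayes_factor, 1)
  expect_false(mc$capped)
  expect_false(mc$detected)
  # all accepted rows from model 1: capped BF
  t2far <- fake_table(matrix(seq(2, 2 * n, by = 2) + 1e4, ncol = 1), mkp(n),
                      model_id = 2)
  mc2 <- model_choice(0, t1, t2far, tolerance = 0.1, method = "rejection",
                      n_comp = 0)
  expect_true(mc2$capped)
  expect_equal(mc2$bayes_factor, sum(mc2$accepted) + 1)
  expect_true(mc2$detected)
  # BF * P(m2) = P(m1) away from the cap
  mc3 <- model_choice(50, t1, t2, tolerance = 0.2, method = "rejection",
                      n_comp = 0)
  expect_equal(mc3$bayes_factor * (1 - mc3$p_model1), mc3$p_model1)
  # mismatched tables are refused
  t2bad <- t2; t2bad$class_edges <- c(1, 5)
  expect_error(model_choice(0, t1, t2bad, 0.1), "identical settings")
})

test_that("the local logistic estimator separates planted clusters", {
  withr::with_seed(13, {
    n <- 300
    mkp <- function(n) tibble::tibble(N = rep(1e4, n), sigma_anc = 0.1,
                                      sigma_pres = 0.9, t_sigma = 1e3)
    s1 <- matrix(stats::rnorm(n * 3, mean = 0), n, 3)
    s2 <- matrix(stats::rnorm(n * 3, mean = 2), n, 3)
    t1 <- fake_table(s1, mkp(n)); t2 <- fake_table(s2, mkp(n), model_id = 2)
    mc <- model_choice(c(0, 0, 0), t1, t2, method = "logistic", n_comp = 2)
    expect_gt(mc$p_model1, 0.9)
    mcr <- model_choice(c(2, 2, 2), t1, t2, method = "logistic", n_comp = 2)
    expect_lt(mcr$p_model1, 0.1)
  })
})

test_that("the regression adjustment shifts draws within the prior support", {
  withr::with_seed(21, {
    n <- 500
    params <- tibble::tibble(N = 10^stats::runif(n, 3, 6),
                             sigma_anc = stats::runif(n, 0, 0.2),
                             sigma_pres = stats::runif(n, 0.8, 0.999),
                             t_sigma = 10^stats::runif(n, 2, 6))
    # stats linear in log10(t_sigma) with noise: the local regression should
    # pull the accepted cloud toward the observation's fitted value
    sv <- cbind(log10(params$t_sigma) + stats::rnorm(n, sd = 0.4),
                stats::rnorm(n))
    tab <- fake_table(sv, params)
    obs <- c(4, 0)
    plain <- abc_reject(obs, tab, tolerance = 0.2)
    adj <- abc_reject(obs, tab, tolerance = 0.2, adjust = "loclinear")
    expect_identical(adj$indices, plain$indices)
    spread <- function(p) stats::sd(log10(p$accepted$t_sigma))
    expect_lt(spread(adj), spread(plain))
    expect_true(all(adj$accepted$t_sigma >= 1e2 & adj$accepted$t_sigma <= 1e6))
    expect_true(all(adj$weights > 0 & adj$weights <= 1))
    expect_equal(plain$weights, rep(1, nrow(plain$accepted)))
  })
})

test_that("posterior summaries report modes and credibility intervals", {
  prior <- model1_prior()
  mk_post <- function(vals) {
    structure(list(accepted = tibble::tibble(t_sigma = vals),
                   distances = rep(0, length(vals)),
                   indices = seq_along(vals), tolerance = 0.01,
                   prior = prior, n_sims = 1000),
              class = "posterior_sample")
  }
  degen <- posterior_summary(mk_post(rep(5000, 20)), "t_sigma")
  expect_equal(degen$mode, 5000, tolerance = 1e-2)
  expect_equal(c(degen$lower, degen$upper), c(5000, 5000))

  withr::with_seed(14, {
    tight <- mk_post(10^stats::rnorm(200, mean = 3, sd = 0.05))
    wide <- mk_post(10^stats::rnorm(200, mean = 5, sd = 0.5))
    avg <- posterior_summary(list(tight, wide), "t_sigma")
    expect_lt(abs(log10(avg$mode) - 3), 0.2)
  })
  expect_error(posterior_summary(mk_post(1), "bogus"), "unknown parameter")
})

test_that("the posterior concentrates around a planted transition age", {
  dims <- sim_dims(n_hap = 4, L = 2e5, n_loci = 1)
  edges <- c(1, 2, 4, 8, 16, 40)
  tab <- withr::with_seed(15,
    fit_pls(build_reference_table(1, dims = dims, n_sims = 800,
                                  class_edges = edges), 10))
  prior_iqr <- 2  # log10 IQR of the log-uniform prior on [1e2, 1e6]
  withr::with_seed(16, {
    hits <- replicate(5, {
      sc <- transition_scenario(N_pres = 4e4, N_anc = 4e4, t_N = 0,
                                sigma_pres = 0.99, sigma_anc = 0.1,
                                t_sigma = 4e4, rec_rate = 1e-8,
                                mut_rate = 1e-8)
      obs <- dataset_summary(simulate_dataset(sc, dims), class_edges = edges)
      post <- abc_reject(obs, tab, tolerance = 0.01)
      diff(stats::quantile(log10(post$accepted$t_sigma),
                           c(0.25, 0.75))) < prior_iqr
    })
    expect_gte(sum(hits), 4)
  })
})

test_that("validation runs are reproducible end to end", {
  dims <- sim_dims(n_hap = 4, L = 1e5, n_loci = 1)
  edges <- c(1, 3, 7)
  t1 <- withr::with_seed(17, build_reference_table(1, dims = dims,
                                                   n_sims = 120,
                                                   class_edges = edges))
  t2 <- withr::with_seed(18, build_reference_table(2, dims = dims,
                                                   n_sims = 120,
                                                   class_edges = edges))
  v1 <- validate_performance(5000, n_reps = 2, t1, t2, tolerance = 0.05,
                             seed = 19)
  v2 <- validate_performance(5000, n_reps = 2, t1, t2, tolerance = 0.05,
                             seed = 19)
  expect_identical(v1, v2)
  expect_true(all(v1$frac_detected >= 0 & v1$frac_detected <= 1))
})

test_that("reference tables round-trip through their plain-text form", {
  dims <- sim_dims(n_hap = 4, L = 1e5, n_loci = 1)
  tab <- fit_pls(build_reference_table(1, dims = dims, n_sims = 120,
                                       class_edges = c(1, 3, 7), seed = 20),
                 5)
  dir <- withr::local_tempdir()
  save_reference_table(tab, dir)
  back <- load_reference_table(dir)
  expect_equal(back$stats, tab$stats, tolerance = 1e-9)
  expect_equal(back$center, tab$center, tolerance = 1e-12)
  expect_equal(back$class_edges, tab$class_edges)
  expect_equal(back$n_comp, tab$n_comp)
  obs <- tab$stats[3, ]
  expect_equal(abc_reject(obs, back, 0.05)$indices,
               abc_reject(obs, tab, 0.05)$indices)
})
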