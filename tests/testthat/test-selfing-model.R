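test_that("selfing rescalings reproduce the closed forms", {
  r <- selfing_rescalings(N = 50000, r = 3.6e-9, mu = 6.95e-9, sigma = 0.95)
  expect_equal(r$N_sigma, 26250)
  expect_equal(r$F, 0.95 / 1.05)
  # rho_sigma via the identity (1 - F) / (1 + F) = 1 - sigma
  expect_equal(r$rho_sigma, 4 * 50000 * 3.6e-9 * 0.05)

  out <- selfing_rescalings(N = 12345, r = 2e-8, mu = 7e-9, sigma = 0)
  expect_equal(out$F, 0)
  expect_equal(out$N_sigma, 12345)
  expect_equal(out$rho_sigma, 4 * 12345 * 2e-8)
  expect_equal(out$theta_sigma, 4 * 12345 * 7e-9)

  expect_error(selfing_rescalings(N = -1, sigma = 0.5), "positive")
  expect_error(selfing_rescalings(N = 100, sigma = 1.2), "sigma")
})

test_that("the selfing algebra holds on a dense sigma grid", {
  sg <- seq(0, 1, length.out = 501)
  F <- sg / (2 - sg)
  expect_true(all(F >= 0 & F <= 1))
  expect_equal((1 - F) / (1 + F), 1 - sg, tolerance = 1e-14)
  r <- selfing_rescalings(N = 1e4, r = 1e-8, mu = 1e-8, sigma = sg[-length(sg)])
  # theta / rho = mu / (r (1 - F))
  expect_equal(r$theta_sigma / r$rho_sigma, 1e-8 / (1e-8 * (1 - r$F)),
               tolerance = 1e-12)
})

test_that("epoch models validate their invariants and support lookup", {
  m <- epoch_model(start_time = c(0, 5e4, 2e5), N = c(4e4, 4e4, 5e4),
                   sigma = c(0.99, 0.99, 0.1), rec_rate = 1e-8)
  expect_s3_class(m, "epoch_model")
  at <- model_at(m, c(0, 49999, 5e4, 1e6))
  expect_equal(at$N, c(4e4, 4e4, 4e4, 5e4))
  expect_equal(at$sigma, c(0.99, 0.99, 0.99, 0.1))
  expect_error(epoch_model(c(1, 2), 1e4, 0, 1e-8), "start at 0")
  expect_error(epoch_model(c(0, 0), 1e4, 0, 1e-8), "strictly increasing")
  expect_error(epoch_model(0, -5, 0, 1e-8), "positive")
  expect_error(model_at(m, -1), "non-negative")
})

test_that("transition scenarios convert losslessly to epoch models", {
  sc <- transition_scenario(N_pres = 4e4, N_anc = 4e4, t_N = 1e4,
                            sigma_pres = 0.9, sigma_anc = 0.1,
                            t_sigma = 1e4, rec_rate = 1e-8, mut_rate = 1e-8)
  expect_equal(nrow(as_epoch_model(sc)), 2)

  sc2 <- transition_scenario(N_pres = 3e4, N_anc = 5e4, t_N = 5e4,
                             sigma_pres = 0.95, sigma_anc = 0,
                             t_sigma = 2e5, rec_rate = 1e-8, mut_rate = 1e-8)
  m2 <- as_epoch_model(sc2)
  expect_equal(m2$start_time, c(0, 5e4, 2e5))

  sc3 <- transition_scenario(N_pres = 4e4, N_anc = 4e4, t_N = 0,
                             sigma_pres = 0.99, sigma_anc = 0.1,
                             t_sigma = 7e4, rec_rate = 1e-8, mut_rate = 1e-8)
  grid <- c(0, 1e4, 69999, 7e4, 70001, 1e6)
  expect_equal(model_at(as_epoch_model(sc3), grid)$sigma,
               ifelse(grid < 7e4, 0.99, 0.1))
  expect_error(transition_scenario(N_pres = 1e4, t_sigma = -5), "non-negative")
})

test_that("recombination probability follows the printed closed form", {
  m_self <- const_model(N = 1e4, sigma = 1, r = 1e-8)
  expect_equal(recomb_prob_given_tmrca(m_self, c(0, 1e3, 1e7)), c(0, 0, 0))

  m <- const_model(N = 1e4, sigma = 0, r = 1e-8)
  expect_equal(recomb_prob_given_tmrca(m, 0), 0)
  expect_equal(recomb_prob_given_tmrca(m, 1e6), 1 - exp(-0.5 * 1e-8 * 1e6),
               tolerance = 1e-12)
  expect_error(recomb_prob_given_tmrca(m, -1), "non-negative")
})

test_that("closed-form probability matches quadrature on random piecewise models", {
  withr::with_seed(42, {
    for (i in 1:25) {
      m <- random_model()
      s <- stats::runif(1, 0, 2e6)
      expect_equal(recomb_prob_given_tmrca(m, s),
                   recomb_prob_quadrature(m, s), tolerance = 1e-10)
    }
  })
})

test_that("recombination probability is non-decreasing and bounded", {
  withr::with_seed(7, {
    for (i in 1:10) {
      m <- random_model()
      p <- recomb_prob_given_tmrca(m, seq(0, 3e6, length.out = 200))
      expect_true(all(diff(p) >= -1e-15))
      expect_true(all(p >= 0 & p < 1))
    }
  })
})
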