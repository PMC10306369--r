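test_that("full selfing yields a single segment spanning the chromosome", {
  m <- const_model(N = 1000, sigma = 1, r = 1e-8)
  s <- simulate_pair(m, 1e6, seed = 1)
  expect_equal(nrow(s), 1)
  expect_equal(c(s$start, s$end), c(0, 1e6))
  expect_gt(s$tmrca, 0)
})

test_that("segment series tile the sequence and are deterministic by seed", {
  m <- const_model()
  s1 <- simulate_pair(m, 2e6, seed = 99)
  s2 <- simulate_pair(m, 2e6, seed = 99)
  expect_identical(s1, s2)
  expect_equal(s1$start[1], 0)
  expect_equal(s1$end[nrow(s1)], 2e6)
  expect_equal(s1$start[-1], s1$end[-nrow(s1)])
  expect_true(all(s1$tmrca > 0))
  # merged silent events: adjacent segments always change age
  expect_true(all(diff(s1$tmrca) != 0))
})

test_that("pairwise T_MRCA marginals follow the rescaled coalescent", {
  m <- const_model(N = 10000, sigma = 0)
  withr::with_seed(11, {
    lw <- replicate(20, {
      s <- simulate_pair(m, 5e6)
      stats::weighted.mean(s$tmrca, s$end - s$start)
    })
    expect_lt(abs(mean(lw) - 20000), 3 * stats::sd(lw) / sqrt(20))
    ts <- replicate(300, tmrca_at(simulate_pair(m, 1e4), 5e3))
    expect_gt(stats::ks.test(ts, "pexp", 1 / 20000)$p.value, 0.01)
  })
  # with selfing the marginal rate is (1 + F) / (2N)
  ms <- const_model(N = 10000, sigma = 0.9)
  withr::with_seed(12, {
    ts <- replicate(300, tmrca_at(simulate_pair(ms, 1e3), 500))
    F <- 0.9 / 1.1
    expect_gt(stats::ks.test(ts, "pexp", (1 + F) / 20000)$p.value, 0.01)
  })
})

test_that("mutation overlay is Poisson with rate 2 s mu per bp", {
  segs <- pair_segments(0, 1e6, tmrca = 10000)
  expect_equal(ncol(overlay_mutations(segs, 0, seed = 1)$geno), 0)
  withr::with_seed(3, {
    counts <- replicate(100, ncol(overlay_mutations(segs, 1e-8)$geno))
    expect_lt(abs(mean(counts) - 200), 3 * stats::sd(counts) / sqrt(100))
  })
  a1 <- overlay_mutations(segs, 1e-7, seed = 5)
  a2 <- overlay_mutations(segs, 1e-7, seed = 5)
  expect_identical(a1, a2)
  expect_true(all(colSums(a1$geno) == 1))
})

test_that("multi-sample simulator matches the neutral coalescent at sigma 0", {
  m <- const_model(N = 10000, sigma = 0)
  withr::with_seed(21, {
    ts <- replicate(300,
      tmrca_at(simulate_sample(m, 2, 1e4, 0, pairs = rbind(c(1, 2)))$pair_segments[[1]], 5e3))
    expect_gt(stats::ks.test(ts, "pexp", 1 / 20000)$p.value, 0.01)
  })
})

test_that("multi-sample diversity calibrates to theta_sigma", {
  m <- const_model(N = 10000, sigma = 0.9)
  withr::with_seed(22, {
    pis <- replicate(60, {
      a <- simulate_sample(m, 4, 2e5, 1e-8)$alignment
      sum(a$geno[1, ] != a$geno[2, ]) / 2e5
    })
    F <- 0.9 / 1.1
    expect_lt(abs(mean(pis) - 4e4 * 1e-8 / (1 + F)),
              3 * stats::sd(pis) / sqrt(60))
  })
})

test_that("n = 2 sample simulation agrees with the pairwise simulator", {
  sc <- transition_scenario(N_pres = 2e4, N_anc = 2e4, t_N = 0,
                            sigma_pres = 0.95, sigma_anc = 0.05,
                            t_sigma = 3e4, rec_rate = 1e-8, mut_rate = 1e-8)
  withr::with_seed(23, {
    tA <- replicate(300,
      tmrca_at(simulate_sample(sc, 2, 1e4, 0, pairs = rbind(c(1, 2)))$pair_segments[[1]], 5e3))
    tB <- replicate(300, tmrca_at(simulate_pair(sc, 1e4), 5e3))
    expect_gt(stats::ks.test(tA, tB)$p.value, 0.01)
    # segment lengths over longer chromosomes
    sA <- simulate_sample(sc, 2, 5e6, 0, pairs = rbind(c(1, 2)))$pair_segments[[1]]
    sB <- simulate_pair(sc, 5e6)
    expect_gt(suppressWarnings(
      stats::ks.test(sA$end - sA$start, sB$end - sB$start)$p.value), 0.01)
  })
})

test_that("sample simulator output is deterministic and rejects high selfing", {
  m <- const_model(N = 5000, sigma = 0.5)
  r1 <- simulate_sample(m, 5, 1e5, 1e-8, seed = 31)
  r2 <- simulate_sample(m, 5, 1e5, 1e-8, seed = 31)
  expect_identical(r1$alignment, r2$alignment)
  expect_error(simulate_sample(const_model(sigma = 0.9995), 4, 1e5, 1e-8),
               "simulate_pair")
  # every emitted site is segregating
  expect_true(all(colSums(r1$alignment$geno) > 0))
  expect_true(all(colSums(r1$alignment$geno) < 5))
  expect_true(!is.unsorted(r1$alignment$positions, strictly = TRUE))
})

test_that("scale invariance: doubling N while halving mu and r preserves window diversity", {
  m1 <- const_model(N = 5000, sigma = 0.3, r = 2e-8)
  m2 <- const_model(N = 10000, sigma = 0.3, r = 1e-8)
  withr::with_seed(41, {
    w1 <- unlist(replicate(40, window_diversity(
      simulate_sample(m1, 2, 1e5, 2e-8)$alignment, c(1, 2), 2e4), simplify = FALSE))
    w2 <- unlist(replicate(40, window_diversity(
      simulate_sample(m2, 2, 1e5, 1e-8)$alignment, c(1, 2), 2e4), simplify = FALSE))
    expect_gt(suppressWarnings(stats::ks.test(w1, w2)$p.value), 0.01)
  })
})

test_that("the forward oracle recovers neutral pairwise expectations", {
  mw <- const_model(N = 200, sigma = 0, r = 1e-8)
  withr::with_seed(51, {
    mns <- replicate(15, {
      w <- simulate_wf_oracle(mw, n = 30, L = 5e4, mu = 0, generations = 2200)
      mean(sapply(w$pair_segments, function(s) tmrca_at(s, 2.5e4)), na.rm = TRUE)
    })
    expect_lt(abs(mean(mns) - 400), 3.5 * stats::sd(mns) / sqrt(15))
  })
  expect_error(simulate_wf_oracle(const_model(N = 5000), 10, 1e4, 0, 5e4),
               "restricted")
  expect_error(simulate_wf_oracle(mw, 10, 1e4, 0, generations = 100),
               "burn-in")
})

test_that("full selfing in the forward oracle gives single within-lineage segments", {
  mw <- const_model(N = 50, sigma = 1, r = 1e-8)
  w <- simulate_wf_oracle(mw, n = 10, L = 1e4, mu = 0, generations = 600,
                          seed = 52, pair_mode = "within")
  nseg <- sapply(w$pair_segments, nrow)
  expect_true(all(nseg == 1))
  expect_true(all(sapply(w$pair_segments, function(s) all(!is.na(s$tmrca)))))
})

test_that("forward-oracle mutations give a valid alignment", {
  mw <- const_model(N = 100, sigma = 0.5, r = 1e-8)
  w <- simulate_wf_oracle(mw, n = 12, L = 2e4, mu = 5e-7, generations = 1100,
                          seed = 53)
  a <- w$alignment
  expect_equal(nrow(a$geno), 12)
  expect_true(all(colSums(a$geno) > 0 & colSums(a$geno) < 12))
  expect_true(!is.unsorted(a$positions, strictly = TRUE))
})
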