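test_that("the unfolded SFS counts derived alleles", {
  expect_equal(unname(unfolded_sfs(toy_alignment())), c(2, 1, 0))
  empty <- haplotype_alignment(matrix(integer(0), nrow = 4), integer(0), 100)
  expect_equal(unname(unfolded_sfs(empty)), c(0, 0, 0))
  withr::with_seed(1, {
    g <- matrix(rbinom(10 * 50, 1, 0.3), nrow = 10)
    seg <- colSums(g) > 0 & colSums(g) < 10
    a <- haplotype_alignment(g[, seg], sort(sample.int(1e4, sum(seg))), 1e4)
    expect_equal(sum(unfolded_sfs(a)), ncol(a$geno))
  })
})

test_that("LD is exact for constructed site pairs", {
  # two sites with identical derived patterns, 7 kb apart: first bin, r2 = 1
  g <- rbind(c(1, 1), c(1, 1), c(0, 0), c(0, 0))
  a <- haplotype_alignment(g, c(0, 7000), 2e4)
  ld <- ld_decay(a)
  expect_equal(ld$mean_r2[1], 1)
  expect_equal(ld$n[1], 1)
  expect_true(all(ld$n[-1] == 0))
  expect_true(all(is.na(ld$mean_r2[-1])))

  # patterns 1100 and 1010: D = 0.25 - 0.25 = 0, r2 = 0
  g2 <- cbind(c(1, 1, 0, 0), c(1, 0, 1, 0))
  a2 <- haplotype_alignment(g2, c(0, 7000), 2e4)
  expect_equal(ld_decay(a2)$mean_r2[1], 0)

  # pairs closer than the first breakpoint are excluded
  a3 <- haplotype_alignment(g, c(0, 500), 2e4)
  expect_true(all(ld_decay(a3)$n == 0))
})

test_that("mean r2 under independence matches the 1/(n-1) permutation expectation", {
  n <- 20
  withr::with_seed(5, {
    means <- replicate(30, {
      repeat {
        g <- matrix(rbinom(n * 120, 1, 0.35), nrow = n)
        seg <- colSums(g) > 0 & colSums(g) < n
        if (sum(seg) > 50) break
      }
      a <- haplotype_alignment(g[, seg], 6105 + seq_len(sum(seg)) * 6105, 1e7)
      ld <- ld_decay(a)
      stats::weighted.mean(ld$mean_r2, ld$n, na.rm = TRUE)
    })
    expect_lt(abs(mean(means) - 1 / (n - 1)), 3 * stats::sd(means) / sqrt(30))
  })
})

test_that("r2 stays within [0, 1] on simulated data", {
  a <- simulate_sample(const_model(N = 2e4, sigma = 0.8), 8, 5e5, 1e-8,
                       seed = 8)$alignment
  ld <- ld_decay(a, seed = 1)
  ok <- !is.na(ld$mean_r2)
  expect_true(any(ok))
  expect_true(all(ld$mean_r2[ok] >= 0 & ld$mean_r2[ok] <= 1))
})

test_that("window diversity places differences in the right windows", {
  g <- rbind(c(1), c(0))
  a <- haplotype_alignment(g, 15000, 30000)
  expect_equal(as.integer(window_diversity(a, c(1, 2), 1e4)), c(0, 1, 0))
  same <- haplotype_alignment(rbind(c(1, 1), c(1, 1)), c(5, 25000), 30000)
  expect_equal(as.integer(window_diversity(same, c(1, 2), 1e4)), c(0, 0, 0))
  expect_error(window_diversity(a, c(1, 2), 40000), "exceeds")
  expect_error(window_diversity(a, c(1, 1), 1e4), "distinct")
})

test_that("window counts calibrate to theta_sigma per window", {
  m <- const_model(N = 10000, sigma = 0.9)
  withr::with_seed(9, {
    w <- unlist(replicate(50, window_diversity(
      overlay_mutations(simulate_pair(m, 1e5), 1e-8), c(1, 2), 1e4),
      simplify = FALSE))
    F <- 0.9 / 1.1
    expect_lt(abs(mean(w) - 4e4 * 1e-8 / (1 + F) * 1e4),
              3 * stats::sd(w) / sqrt(length(w)))
  })
})

test_that("the window transition matrix counts adjacent class pairs", {
  counts <- c(0, 0, 5, 5)  # classes A A B B with edge at 3
  tw <- tm_win(counts, class_edges = 3)
  expect_equal(unname(tw[c("tmw_1_1", "tmw_1_2", "tmw_2_2")]),
               c(1, 1, 1) / 3)
  expect_equal(sum(tw), 1)
  expect_equal(unname(tm_win(c(2, 2, 2), class_edges = 3)["tmw_1_1"]), 1)
  # a single class is trivially the matrix [1]
  expect_equal(unname(tm_win(c(0, 7, 3), class_edges = numeric(0))), 1)
  expect_error(tm_win(c(1), 3), "at least two")
})

test_that("permuting windows destroys diagonal clustering", {
  sc <- transition_scenario(N_pres = 5e4, N_anc = 5e4, t_N = 0,
                            sigma_pres = 0.95, sigma_anc = 0, t_sigma = 2e5,
                            rec_rate = 3.6e-9, mut_rate = 1e-8)
  withr::with_seed(10, {
    w <- window_diversity(overlay_mutations(simulate_pair(sc, 2e6), 1e-8),
                          c(1, 2), 1e4)
    edges <- unique(stats::quantile(w, c(0.25, 0.5, 0.75), names = FALSE))
    diag_mass <- function(x) {
      k <- length(edges) + 1
      sum(tm_win(x, edges)[paste0("tmw_", 1:k, "_", 1:k)])
    }
    obs <- diag_mass(w)
    perm <- replicate(50, diag_mass(sample(w)))
    expect_gt(obs, mean(perm))
  })
})

test_that("summary vectors compose deterministically in declared order", {
  a <- toy_alignment()
  sv <- summary_vector(a, spec = "all", class_edges = c(1, 2), seed = 3)
  sfs <- unfolded_sfs(a)
  expect_equal(unname(sv[1:3]), as.numeric(sfs))
  expect_true(all(startsWith(names(sv)[1:3], "sfs_")))
  ld_i <- grep("^ld_", names(sv))
  tm_i <- grep("^tmw_", names(sv))
  expect_true(max(ld_i) < min(tm_i))
  expect_equal(length(tm_i), 9)
  sv2 <- summary_vector(a, spec = "all", class_edges = c(1, 2), seed = 3)
  expect_identical(sv, sv2)
  # TM_win components require frozen edges
  expect_error(summary_vector(a, spec = "tmwin"), "class_edges")
  # multi-locus averaging is element-wise
  expect_equal(combine_loci(list(sv, sv * 3)), sv * 2)
})
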