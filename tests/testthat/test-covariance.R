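test_that("theoretical null covariance follows rho * ns / sqrt(n1 n2)", {
  expect_equal(theoretical_sigma_r(1e4, 1e4, 1e4, 0.5), 0.5)  # full overlap
  expect_equal(theoretical_sigma_r(1e4, 2e4, 0, 0.9), 0)       # disjoint
  expect_equal(theoretical_sigma_r(40000, 10000, 10000, 0.4), 0.2)
  expect_error(theoretical_sigma_r(1e4, 1e4, 2e4, 0.5), "ns")

  # bilinear in rho and ns, symmetric in (n1, n2)
  expect_equal(theoretical_sigma_r(3e4, 1e4, 5e3, 0.6),
               3 * theoretical_sigma_r(3e4, 1e4, 5e3, 0.2))
  expect_equal(theoretical_sigma_r(3e4, 1e4, 6e3, 0.2),
               2 * theoretical_sigma_r(3e4, 1e4, 3e3, 0.2))
  expect_equal(theoretical_sigma_r(3e4, 1e4, 5e3, 0.6),
               theoretical_sigma_r(1e4, 3e4, 5e3, 0.6))
})

test_that("naive estimator recovers the null covariance; estimators agree", {
  S <- random_correlation(4, seed = 31)
  Z <- simulate_null_panel(S, 40000, seed = 32)
  est <- empirical_sigma_r(Z, "naive")
  expect_lt(max(abs(est$sigma_r - S)), 0.02)

  # on pure-null data, naive / pruned / trimmed agree within MC error
  prn <- empirical_sigma_r(Z, "pruned", subset_size = 20000, seed = 33)
  trm <- empirical_sigma_r(Z, "trimmed")
  expect_lt(max(abs(prn$sigma_r - est$sigma_r)), 0.03)
  expect_lt(max(abs(trm$sigma_r - est$sigma_r)), 0.01)

  expect_error(empirical_sigma_r(Z[1:50, ], "naive"), "pairwise-complete")
})

test_that("causal contamination inflates the naive estimator; trimming helps", {
  # 10% causal SNPs with positive genetic covariance
  sim <- simulate_ldsc_panel(60000, n = c(3e4, 3e4), ns = 1.5e4, rho_p = 0.4,
                             h2 = 0.5, rho_g = 0.8, causal_fraction = 0.1,
                             seed = 34)
  truth <- sim$sigma_r[1, 2]
  naive <- empirical_sigma_r(sim$Z, "naive")$sigma_r[1, 2]
  trimmed <- empirical_sigma_r(sim$Z, "trimmed", trim_p = 5e-8)$sigma_r[1, 2]
  expect_gt(naive, truth)                        # biased upward
  expect_lt(abs(trimmed - truth), abs(naive - truth))
})

test_that("LDSC regression separates overlap intercept from genetic slope", {
  # complete overlap, known rho, no genetic effects: intercept ~= rho
  sim0 <- simulate_ldsc_panel(50000, n = c(2e4, 2e4), ns = 2e4, rho_p = 0.6,
                              h2 = 0, seed = 35)
  cv0 <- ldsc_sigma(sim0$Z, sim0$ld_scores, m_snps = sim0$m_snps, n = sim0$n)
  expect_lt(abs(cv0$sigma_r[1, 2] - 0.6), 2 * cv0$se_r[1, 2])

  # polygenic signal: slope-derived genetic covariance within 15% of truth
  sim1 <- simulate_ldsc_panel(100000, n = c(3e4, 3e4), ns = 0, rho_p = 0,
                              h2 = 0.4, rho_g = 0.6, seed = 36)
  cv1 <- ldsc_sigma(sim1$Z, sim1$ld_scores, m_snps = sim1$m_snps, n = sim1$n)
  expect_lt(abs(cv1$sigma_g[1, 2] / sim1$sigma_g[1, 2] - 1), 0.15)
  expect_lt(abs(cv1$sigma_g[1, 1] / 0.4 - 1), 0.15)

  # intercept stays put when the genetic signal scales up at fixed overlap
  sim2 <- simulate_ldsc_panel(100000, n = c(3e4, 3e4), ns = 1.5e4,
                              rho_p = 0.4, h2 = 0.4, rho_g = 0.6, seed = 37)
  cv2 <- ldsc_sigma(sim2$Z, sim2$ld_scores, m_snps = sim2$m_snps, n = sim2$n)
  expect_lt(abs(cv2$sigma_r[1, 2] - sim2$sigma_r[1, 2]), 3 * cv2$se_r[1, 2])

  # degenerate design: constant LD scores
  expect_error(ldsc_sigma(sim0$Z, rep(2, nrow(sim0$Z)), n = sim0$n),
               "rank-deficient")
})

test_that("pseudo-inverse strategies honor their contracts", {
  # identity is its own inverse under every strategy (ridge approximately)
  for (s in c("truncate", "floor")) {
    pi5 <- pseudo_inverse(diag(5), s)
    expect_equal(pi5$inv, diag(5))
    expect_equal(pi5$df, 5L)
  }
  expect_equal(pseudo_inverse(diag(5), "ridge", 1e-8)$inv, diag(5),
               tolerance = 1e-6)

  # rank-deficient: truncate keeps K' and satisfies the Moore-Penrose identity
  set.seed(41)
  A <- matrix(rnorm(8 * 4), 8, 4)
  S <- tcrossprod(A %*% t(A)) / 64        # rank 4, size 8
  S <- (S + t(S)) / 2
  pt <- pseudo_inverse(S, "truncate", 1e-6)
  expect_equal(pt$df, 4L)
  expect_lt(max(abs(S %*% pt$inv %*% S - S)), 1e-8)

  # all eigenvalues below epsilon -> singularity error
  expect_error(pseudo_inverse(diag(1e-9, 3), "truncate", 1e-6), "singular")

  # floor/ridge keep full df
  expect_equal(pseudo_inverse(S, "floor", 1e-6)$df, 8L)
  expect_equal(pseudo_inverse(S, "ridge", 1e-6)$df, 8L)
})

test_that("rank-deficient covariance with truncation keeps the omnibus calibrated", {
  set.seed(42)
  K <- 12; K_true <- 6
  V <- qr.Q(qr(matrix(rnorm(K * K), K)))[, 1:K_true]
  lam <- seq(2, 0.5, length.out = K_true)
  S <- V %*% (t(V) * lam)
  S <- (S + t(S)) / 2
  Z <- simulate_null_panel(S, 20000, seed = 43)
  res <- multitrait_scan(Z, null_covariance(S), tests = "omnibus")
  expect_equal(res$df_omnibus[1], K_true)
  expect_lt(abs(lambda_gc(res$stat_omnibus, K_true) - 1), 0.05)
  # uniform p-values at both tails
  expect_lt(abs(mean(res$p_omnibus < 0.05) - 0.05),
            3 * sqrt(0.05 * 0.95 / 20000))
})

test_that("misspecified (downscaled) covariance inflates the omnibus", {
  S <- random_correlation(6, seed = 44)
  Z <- simulate_null_panel(S, 20000, seed = 45)
  good <- multitrait_scan(Z, null_covariance(S), tests = "omnibus")
  bad <- multitrait_scan(Z, null_covariance(S * 0.8), tests = "omnibus")
  expect_gt(lambda_gc(bad$stat_omnibus, 6), 1.05)
  expect_true(abs(lambda_gc(good$stat_omnibus, 6) - 1) <= 0.05)
})
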