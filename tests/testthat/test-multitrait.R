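test_that("omnibus and sumZ reproduce the closed-form micro cases", {
  r <- omnibus_test(c(3, 4), diag(2))
  expect_equal(r$statistic, 25)
  expect_equal(r$df, 2L)
  expect_equal(r$pvalue, pchisq(25, 2, lower.tail = FALSE))

  z0 <- omnibus_test(c(0, 0, 0), diag(3))
  expect_equal(z0$statistic, 0)
  expect_equal(z0$pvalue, 1)

  s <- sumz_test(c(2, 2), c(1, 1), diag(2))
  expect_equal(s$statistic, 8)
  expect_equal(s$df, 1L)

  # unit basis weight reduces to the univariate chi-square
  e1 <- sumz_test(c(1.7, -0.3), c(1, 0), diag(2))
  expect_equal(e1$statistic, 1.7^2)

  # scale invariance of the sumZ ratio
  S <- random_correlation(5, seed = 51)
  z <- rnorm(5); w <- rnorm(5)
  expect_equal(sumz_test(z, w, S)$statistic,
               sumz_test(z, -3.7 * w, S)$statistic)

  # degenerate weights rejected
  expect_error(sumz_test(c(1, 1), c(0, 0), diag(2)), "degenerate")
})

test_that("omnibus equals the sum of per-eigenvector sumZ statistics", {
  # closed form at the identity
  d <- omnibus_eigen_identity(c(3, 4), null_covariance(diag(2)))
  expect_equal(sort(d$components), c(9, 16))
  expect_equal(d$total, 25)

  # fuzzed identity over random full-rank covariances
  set.seed(52)
  for (i in 1:200) {
    K <- sample(2:10, 1)
    S <- random_correlation(K)
    z <- as.numeric(rmvnorm_rows_test(1, S))
    t_omni <- omnibus_test(z, S)$statistic
    dec <- omnibus_eigen_identity(z, null_covariance(S))
    expect_lt(abs(dec$total - t_omni), 1e-8 * max(1, t_omni))
  }

  # rank-deficient: only K' components under truncation
  V <- qr.Q(qr(matrix(rnorm(16), 4)))[, 1:2]
  S2 <- V %*% t(V)
  S2 <- (S2 + t(S2)) / 2
  dec2 <- omnibus_eigen_identity(rnorm(4), S2, "truncate", 1e-6)
  expect_equal(length(dec2$components), 2)
})

test_that("omnibus is invariant under simultaneous orthonormal rotation", {
  set.seed(53)
  K <- 6
  S <- random_correlation(K)
  z <- rnorm(K)
  Q <- qr.Q(qr(matrix(rnorm(K * K), K)))
  t1 <- omnibus_test(z, S)$statistic
  t2 <- omnibus_test(drop(Q %*% z), Q %*% S %*% t(Q))$statistic
  expect_equal(t1, t2, tolerance = 1e-10)
})

test_that("weight schemes deliver the advertised directions", {
  S <- random_correlation(4, seed = 54)
  cov <- null_covariance(S)
  expect_equal(make_weights(cov, scheme = "unit")$w, rep(1, 4))

  # pheno_pc1 maximizes w'Sw among unit vectors (eigen characterization)
  w_r <- make_weights(cov, scheme = "pheno_pc1")$w
  set.seed(55)
  for (i in 1:50) {
    u <- rnorm(4); u <- u / sqrt(sum(u^2))
    expect_gte(drop(t(w_r) %*% S %*% w_r) + 1e-10, drop(t(u) %*% S %*% u))
  }

  # isotropic sigma_r: degenerate leading axis, canonical fallback + warning
  expect_warning(w_i <- make_weights(null_covariance(diag(3)),
                                     scheme = "pheno_pc1"),
                 "degenerate")
  expect_equal(w_i$w, c(1, 0, 0))

  # gene_pc1 concentrates loadings on the dominant trait pair
  Sg <- diag(0.05, 4)
  Sg[1, 2] <- Sg[2, 1] <- 0.5
  Sg[1, 1] <- Sg[2, 2] <- 0.55
  covg <- null_covariance(S, sigma_g = Sg)
  w_g <- make_weights(covg, scheme = "gene_pc1")$w
  expect_true(all(abs(w_g[1:2]) > abs(w_g[3:4])))
  expect_error(make_weights(cov, scheme = "gene_pc1"), "sigma_g")

  # largest-magnitude loading is positive (sign canonicalization)
  expect_gt(w_g[which.max(abs(w_g))], 0)
})

test_that("ICA weight selection works and refuses too-missing panels", {
  set.seed(56)
  # two independent non-Gaussian sources mixed into 3 traits
  S0 <- cbind(runif(3000, -2, 2), rexp(3000) - 1)
  M <- matrix(c(1, 0.6, 0.2, 0.1, 0.8, 1), 3, 2)
  Z <- S0 %*% t(M) + 0.05 * matrix(rnorm(9000), 3000, 3)
  cov <- null_covariance(cov(Z))
  w <- make_weights(cov, panel = Z, scheme = "ica", seed = 57)
  expect_s3_class(w, "WeightVector")
  expect_equal(length(w$w), 3)
  expect_true(is.finite(sumz_test(Z[1, ], w, cov)$statistic))

  Zm <- Z
  Zm[sample(length(Zm), 0.4 * length(Zm))] <- NA
  expect_error(make_weights(cov, panel = Zm, scheme = "ica"), "missing")
})

test_that("missing-data handling: subset mode matches manual sub-restriction", {
  S <- random_correlation(5, seed = 58)
  z <- c(1.2, NA, -0.7, 2.1, NA)
  obs <- !is.na(z)
  r <- omnibus_test(z, S, na_action = "subset")
  r_manual <- omnibus_test(z[obs], S[obs, obs])
  expect_equal(r$statistic, r_manual$statistic)
  expect_equal(r$df, 3L)
  expect_error(omnibus_test(z, S), "missing")

  w <- rep(1, 5)
  s <- sumz_test(z, w, S, na_action = "subset")
  expect_equal(s$statistic, sumz_test(z[obs], w[obs], S[obs, obs])$statistic)
})

test_that("panel scan agrees with per-SNP calls and handles patterns", {
  S <- random_correlation(4, seed = 59)
  Z <- simulate_null_panel(S, 300, seed = 60)
  Z[sample(length(Z), 100)] <- NA
  Z <- Z[rowSums(!is.na(Z)) > 0, ]
  cov <- null_covariance(S)
  res <- multitrait_scan(Z, cov, tests = c("omnibus", "sumz_1", "univ_min"))
  for (i in c(1, 7, 50)) {
    z <- Z[i, ]
    expect_equal(res$stat_omnibus[i],
                 omnibus_test(z, cov, na_action = "subset")$statistic,
                 tolerance = 1e-12)
    expect_equal(res$stat_sumz_1[i],
                 sumz_test(z, rep(1, 4), cov, na_action = "subset")$statistic,
                 tolerance = 1e-12)
    expect_equal(res$p_univ_min[i], min(2 * pnorm(-abs(z)), na.rm = TRUE))
  }
})

test_that("omnibus matches MANOVA on complete-overlap individual-level data", {
  sim <- simulate_individual_level(1500, 400, 4, n_causal = 40,
                                   beta_sd = 0.08, seed = 61)
  sc <- gwas_scan(sim$G, sim$Y)
  p_manova <- manova_scan(sim$G, sim$Y)
  cov <- null_covariance(cor(sim$Y))
  res <- multitrait_scan(sc$z, cov, tests = "omnibus")
  cc <- cor(-log10(res$p_omnibus), -log10(p_manova))
  expect_gt(cc, 0.99)
})

test_that("closed-form MANOVA matches stats::manova", {
  sim <- simulate_individual_level(400, 25, 3, n_causal = 5, beta_sd = 0.15,
                                   seed = 62)
  p_fast <- manova_scan(sim$G, sim$Y)
  p_ref <- vapply(seq_len(25), function(s) {
    g <- sim$G[, s]
    summary(manova(sim$Y ~ g))$stats[1, "Pr(>F)"]
  }, 0)
  expect_equal(p_fast, p_ref, tolerance = 1e-10)
})
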