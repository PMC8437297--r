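test_that("overlap correction: no-overlap case reduces to the plain mean", {
  set.seed(101)
  b1 <- rnorm(50, 0, 0.01); b2 <- rnorm(50, 0, 0.01)
  res <- cluster_genetic_covariance(b1, b2, 1e4, 1e4, ns = 0, rho_y = 0.5)
  expect_equal(res$covariance, mean(b1 * b2))
  expect_equal(res$m, 50)
  # symmetric in the two traits
  res_sw <- cluster_genetic_covariance(b2, b1, 1e4, 1e4, ns = 0, rho_y = 0.5)
  expect_equal(res_sw$covariance, res$covariance)
  expect_equal(res_sw$pvalue, res$pvalue)
  expect_error(cluster_genetic_covariance(b1[1:4], b2[1:4], 1e4, 1e4),
               "at least 5")
})

test_that("corrected estimator beats the naive one under sample overlap", {
  # full overlap, correlated phenotypes: bhat cross-products are biased by
  # ns * rho / (n1 n2); the correction removes it
  n <- 2e4; ns <- 2e4; rho <- 0.4; M <- 150
  sigma_g <- 2e-4                       # true per-SNP covariance
  set.seed(102)
  reps <- 300
  naive <- corrected <- numeric(reps)
  for (r in seq_len(reps)) {
    b <- rmvnorm_rows_test(M, matrix(c(1, .8, .8, 1) * sigma_g, 2))
    E <- rmvnorm_rows_test(M, matrix(c(1, rho, rho, 1) / n, 2))
    bh1 <- b[, 1] + E[, 1]; bh2 <- b[, 2] + E[, 2]
    naive[r] <- mean(bh1 * bh2)
    corrected[r] <- cluster_genetic_covariance(bh1, bh2, n, n, ns,
                                               rho)$covariance
  }
  truth <- 0.8 * sigma_g
  expect_lt(abs(mean(corrected) - truth), abs(mean(naive) - truth))
  expect_lt(abs(mean(corrected) - truth), 2 * sd(corrected) / sqrt(reps))
})

test_that("null-cluster t-test is calibrated under full overlap", {
  n <- 2e4; ns <- 2e4; rho <- 0.4; M <- 80
  set.seed(103)
  reps <- 1000
  p <- vapply(seq_len(reps), function(r) {
    E <- rmvnorm_rows_test(M, matrix(c(1, rho, rho, 1) / n, 2))
    cluster_genetic_covariance(E[, 1], E[, 2], n, n, ns, rho)$pvalue
  }, 0)
  err <- mean(p < 0.05)
  expect_lt(abs(err - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("pairwise table applies Bonferroni across clusters and pairs", {
  set.seed(104)
  B <- rmvnorm_rows_test(60, diag(3)) * 0.01
  B[1:30, 1] <- B[1:30, 2] + rnorm(30, 0, 1e-3)    # strong pair in cluster 1
  tab <- cluster_correlation_table(B, rep(1:2, each = 30), n = rep(1e4, 3))
  expect_equal(nrow(tab), 6)                        # 2 clusters x 3 pairs
  expect_true(tab$significant[tab$cluster == 1 & tab$trait1 == "trait1" &
                                tab$trait2 == "trait2"])
  expect_true(all(abs(na.omit(tab$correlation)) <= 1 + 1e-8))
})

test_that("shuffle-averaged PC1 recovers the profile direction", {
  # exact rank-1 matrix: PC1 explains everything, loadings align
  d <- c(0.6, 0.64, 0.48)
  Z1 <- outer(c(1, -2, 1.5, 3, -1), d)
  pc <- cluster_pc1(Z1, n_shuffles = 5, seed = 1)
  expect_equal(pc$var_explained, 1, tolerance = 1e-10)
  dn <- d / sqrt(sum(d^2))
  expect_equal(abs(sum(pc$loadings * dn)), 1, tolerance = 1e-10)

  # known direction + isotropic noise: averaged loadings within 5 degrees
  set.seed(105)
  w <- d / sqrt(sum(d^2))
  Z2 <- outer(rnorm(400, 0, 3), w) + matrix(rnorm(1200, 0, 0.3), 400, 3)
  pc2 <- cluster_pc1(Z2, n_shuffles = 20, seed = 2)
  angle <- acos(min(abs(sum(pc2$loadings * w)), 1)) * 180 / pi
  expect_lt(angle, 5)

  # sign-flipping rows leaves the uncentered second moment unchanged
  flip <- sample(c(-1, 1), 400, TRUE)
  expect_equal(crossprod(Z2 * flip), crossprod(Z2), tolerance = 1e-10)

  expect_error(cluster_pc1(matrix(0, 5, 3)), "degenerate")
  expect_error(cluster_pc1(Z2[1:2, ]), "at least as many SNPs")
})

test_that("allele alignment to PC1 is a sign normalization", {
  pc1 <- c(0.6, 0.8)
  expect_equal(as.numeric(align_alleles_to_pc1(-pc1, pc1)), pc1)
  expect_equal(as.numeric(align_alleles_to_pc1(pc1, pc1)), pc1)
  orth <- c(-0.8, 0.6)
  al <- align_alleles_to_pc1(orth, pc1)
  expect_equal(as.numeric(al), orth)                 # orthogonal: unflipped
  expect_false(attr(al, "flipped"))
  # applying it twice equals applying it once
  once <- align_alleles_to_pc1(c(-1, -2), pc1)
  twice <- align_alleles_to_pc1(as.numeric(once), pc1)
  expect_equal(as.numeric(twice), as.numeric(once))
})

test_that("sign test matches the exact binomial and is calibrated", {
  res <- disease_sign_test(rep(2.5, 10))
  expect_equal(res$pvalue, 2 * 0.5^10)
  expect_equal(res$direction, "positive")

  bal <- disease_sign_test(c(rep(1, 5), rep(-1, 5)))
  expect_equal(bal$pvalue, 1)
  expect_equal(bal$direction, "balanced")

  expect_error(disease_sign_test(c(1, -1, 0, 0, 0)), "at least 5")

  # global flip of profiles together with pc1 leaves p unchanged
  set.seed(106)
  z <- rnorm(20)
  expect_equal(disease_sign_test(z)$pvalue, disease_sign_test(-z)$pvalue)

  # i.i.d. fair signs: rejection rate at 0.05 within 3 binomial SDs
  reps <- 800
  p <- vapply(seq_len(reps), function(r)
    disease_sign_test(sample(c(-1, 1), 25, TRUE))$pvalue, 0)
  expect_lte(mean(p < 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("variance-explained shares normalize per trait", {
  Z <- rbind(c(2, 1), c(2, 1), c(2, 3), c(0, 1), c(4, 1))
  N <- matrix(1e4, 5, 2)
  out <- variance_explained_matrix(Z, N, c(1, 1, 2, 2, 3))
  expect_equal(colSums(out$shares), c(1, 1), ignore_attr = TRUE)
  # hand computation: contributions z^2 per trait (n constant)
  z2 <- Z^2
  expect_equal(unname(out$shares[1, 1]), sum(z2[1:2, 1]) / sum(z2[, 1]))
  expect_equal(unname(out$shares[3, 2]), z2[5, 2] / sum(z2[, 2]))
  # one cluster holding everything -> share 1; equal split -> 0.5/0.5
  out1 <- variance_explained_matrix(Z, N, rep(1, 5))
  expect_true(all(out1$shares == 1))
  Zeq <- rbind(c(1, 1), c(1, 1))
  oeq <- variance_explained_matrix(Zeq, matrix(1e4, 2, 2), c(1, 2))
  expect_true(all(oeq$shares == 0.5))
})
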