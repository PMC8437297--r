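make_tab <- function(...) {
  base <- data.frame(snp_id = paste0("rs", 1:3), chrom = "1", pos = 1:3 * 100L,
                     coded_allele = "A", other_allele = "G",
                     stringsAsFactors = FALSE)
  sumstats_table(cbind(base, data.frame(...)))
}

test_that("z derivation matches the normal quantile and its conventions", {
  tab <- make_tab(beta = c(1, -1, 2), pvalue = c(0.05, 0.05, 1))
  out <- derive_z(tab)
  expect_equal(out$z[1], qnorm(0.975), tolerance = 1e-12)
  expect_equal(out$z[2], -qnorm(0.975), tolerance = 1e-12)  # sign symmetry
  expect_equal(out$z[3], 0)                                  # p = 1 -> z = 0

  # p = 0 is clamped to the floor with a warning
  tab0 <- make_tab(beta = 1, pvalue = c(0, 0.5, 0.5))
  expect_warning(out0 <- derive_z(tab0), "clamped")
  expect_equal(out0$z[1], qnorm(1e-300 / 2, lower.tail = FALSE))

  # no sign source -> z stays missing
  tabn <- make_tab(pvalue = c(0.01, 0.5, 1))
  outn <- derive_z(tabn)
  expect_true(all(is.na(outn$z[1:2])))
  expect_equal(outn$z[3], 0)

  # existing z preserved unless overwrite; p-derived wins on conflict
  tabz <- make_tab(z = c(5, NA, NA), beta = c(1, 1, 1),
                   se = c(1, 1, 1), pvalue = c(0.05, 0.05, 0.05))
  expect_warning(outz <- derive_z(tabz), "disagrees")
  expect_equal(outz$z[1], qnorm(0.975), tolerance = 1e-12)
})

test_that("derive_z round-trips with the two-sided p for p > 1e-12", {
  set.seed(11)
  p <- 10^runif(200, -11.5, -0.01)
  tab <- sumstats_table(data.frame(
    snp_id = paste0("rs", seq_along(p)), chrom = "1",
    pos = seq_along(p) * 10L, coded_allele = "A", other_allele = "G",
    beta = sample(c(-1, 1), length(p), TRUE), pvalue = p))
  z <- derive_z(tab)$z
  expect_lt(max(abs(2 * pnorm(-abs(z)) - p) / p), 1e-10)
})

test_that("sample-size inference follows 1/(se^2 * 2f(1-f))", {
  tab <- make_tab(se = c(0.01, 0.02, 0.01), freq = c(0.5, 0.5, NA),
                  n = c(NA, NA, NA))
  out <- infer_sample_size(tab)
  expect_equal(out$n[1], 1 / (1e-4 * 0.5))          # = 20,000
  expect_equal(out$n[2], out$n[1] / 4)               # se doubled -> n/4
  expect_true(is.na(out$n[3]))                       # no frequency
  expect_equal(out$n_inferred, c(TRUE, TRUE, FALSE))

  # observed n untouched; external frequency source honored
  tab2 <- make_tab(se = 0.01, freq = NA, n = c(500, NA, NA))
  out2 <- infer_sample_size(tab2, freq_source = c(rs1 = 0.5, rs2 = 0.5,
                                                  rs3 = 1.2))
  expect_equal(out2$n[1], 500)
  expect_equal(out2$n[2], 20000)
  expect_true(is.na(out2$n[3]))                      # f outside (0,1)
})

test_that("inferred n targets the true N for a standardized linear GWAS", {
  sim <- simulate_individual_level(5000, 300, 2, seed = 21)
  sc <- gwas_scan(sim$G, sim$Y)
  # genotypes standardized: var_G = 1, so n_hat = 1/se^2 targets N (sigma_e^2
  # = 1 here); the estimator consumes the raw-genotype se and frequency
  se_raw <- sc$se[, 1] / apply(sim$G_raw, 2, sd)
  tab <- sumstats_table(data.frame(
    snp_id = sprintf("s%03d", 1:300), chrom = "1", pos = 1:300 * 10L,
    coded_allele = "A", other_allele = "G",
    se = se_raw, freq = colMeans(sim$G_raw) / 2))
  nhat <- infer_sample_size(tab)$n
  expect_true(abs(median(nhat) / 5000 - 1) < 0.05)
})

test_that("low-sample-size filter masks entries below the fraction", {
  ld <- toy_ld_panel()
  ref <- ld$snp_info
  t1 <- sumstats_table(toy_sumstats_df(ref, 1, n = 1e5))
  t2 <- sumstats_table(toy_sumstats_df(ref, 1, n = 1e5))
  panel <- harmonize_panel(list(a = t1, b = t2), ref)
  panel$N[1, 1] <- 5e4                               # 0.5 < 0.7 of max
  before <- sum(!is.na(panel$Z))
  out <- filter_low_n(panel, fraction = 0.70, robust = FALSE)
  expect_true(is.na(out$Z[1, 1]))
  expect_equal(sum(!is.na(out$Z)), before - 1)

  # equal n -> nothing masked; invalid fraction -> error
  out2 <- filter_low_n(harmonize_panel(list(a = t1, b = t2), ref),
                       robust = FALSE)
  expect_equal(sum(is.na(out2$Z)), 0)
  expect_error(filter_low_n(panel, fraction = 1.5), "fraction")
  # never increases the number of observed entries
  expect_lte(sum(!is.na(out$Z)), before)
})

test_that("the 70% filter removes the heterogeneous-sample-size inflation", {
  # 25% of SNPs were assayed at half the sample size on trait 1, so their
  # true cross-trait overlap (and Z covariance) is lower than the
  # genome-wide value used in the test
  ld <- toy_ld_panel(n_regions = 1, block_size = 2)   # ids only
  n_snp <- 20000; n_hi <- 1e5; n_lo <- 5e4; rho <- 0.6
  lo <- seq_len(n_snp) <= n_snp * 0.25
  s_hi <- theoretical_sigma_r(n_hi, n_hi, n_hi, rho)      # 0.6
  s_lo <- theoretical_sigma_r(n_lo, n_hi, n_lo, rho)      # 0.42
  set.seed(23)
  Z <- rbind(
    rmvnorm_rows_test(sum(lo), matrix(c(1, s_lo, s_lo, 1), 2)),
    rmvnorm_rows_test(sum(!lo), matrix(c(1, s_hi, s_hi, 1), 2)))
  snps <- data.frame(snp_id = sprintf("s%05d", seq_len(n_snp)), chrom = "1",
                     pos = seq_len(n_snp), coded_allele = "A",
                     other_allele = "G")
  N <- cbind(ifelse(lo, n_lo, n_hi), rep(n_hi, n_snp))
  colnames(Z) <- colnames(N) <- c("a", "b")
  panel <- sumstats_panel(snps, Z, N)
  cov_global <- null_covariance(matrix(c(1, s_hi, s_hi, 1), 2))

  before <- multitrait_scan(panel, cov_global, tests = "omnibus")
  expect_gt(lambda_gc(before$stat_omnibus[lo], 2), 1.05)

  filtered <- filter_low_n(panel, fraction = 0.70, robust = FALSE)
  keep <- rowSums(is.na(filtered$Z)) == 0
  after <- multitrait_scan(filtered$Z[keep, ], cov_global, tests = "omnibus")
  expect_true(abs(lambda_gc(after$stat_omnibus, 2) - 1) <= 0.05)
})

test_that("logit-link n proxy is proportional to N p (1 - p)", {
  fracs <- c(0.2, 0.35, 0.5)
  slopes <- vapply(fracs, function(cf) {
    gw <- simulate_logistic_gwas(4000, 40, cf, seed = round(cf * 100))
    tab <- sumstats_table(cbind(
      data.frame(snp_id = gw$snp_id, chrom = "1",
                 pos = seq_len(nrow(gw)) * 10L,
                 coded_allele = "A", other_allele = "G"),
      gw[c("beta", "se", "freq")]))
    median(infer_sample_size(tab)$n) / (4000 * cf * (1 - cf))
  }, 0)
  expect_lt(sd(slopes) / mean(slopes), 0.05)
})
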