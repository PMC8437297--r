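# Built-in verification engine: each verify_* function re-runs one of the
# simulation studies the methods rest on — null calibration, the eigen
# identity, MANOVA equivalence, covariance misspecification, estimator
# contamination, power ordering, imputation fidelity, mixture recovery,
# cluster-covariance correction and the sample-size proxy — and returns the
# measured quantities. The acceptance tests assert on these; the acceptance
# script reports them.

#' Null calibration of the omnibus and sumZ tests
#'
#' Simulates a complete-null Z panel (`z ~ N(0, Sigma_r)` with a random
#' correlation), runs the omnibus test and all four sumZ weightings, and
#' measures empirical type-I error at each `alpha`. The genetic covariance
#' driving the `sumz_g` weights is an independently drawn random correlation
#' (under the null any fixed weighting must be calibrated).
#'
#' @param K number of traits.
#' @param n_snps panel size (default 1e5).
#' @param alphas type-I error levels examined.
#' @param seed RNG seed.
#' @return list with `errors` (data.frame: test, alpha, error, bound3sd) and
#'   `lambda_gc` of the omnibus.
#' @export
verify_null_calibration <- function(K = 5, n_snps = 1e5,
                                    alphas = c(0.05, 1e-3), seed = 1) {
  sigma_r <- random_correlation(K, seed = seed)
  sigma_g <- random_correlation(K, seed = seed + 1)
  Z <- simulate_null_panel(sigma_r, n_snps, seed = seed + 2)
  cov <- null_covariance(sigma_r, sigma_g = sigma_g, method = "theoretical")
  res <- multitrait_scan(Z, cov,
                         tests = c("omnibus", "sumz_1", "sumz_r", "sumz_g",
                                   "sumz_ica"),
                         seed = seed + 3)
  tests <- c("omnibus", "sumz_1", "sumz_r", "sumz_g", "sumz_ica")
  grid <- expand.grid(test = tests, alpha = alphas, stringsAsFactors = FALSE)
  grid$error <- mapply(function(tn, a) mean(res[[paste0("p_", tn)]] < a),
                       grid$test, grid$alpha)
  grid$bound3sd <- 3 * sqrt(grid$alpha * (1 - grid$alpha) / n_snps)
  list(errors = grid, lambda_gc = lambda_gc(res$stat_omnibus, K))
}

#' Eigen-decomposition identity of the omnibus statistic
#'
#' Fuzzes random (z, Sigma_r) pairs and measures the worst relative error
#' between the omnibus statistic and the sum of its per-eigenvector sumZ
#' components.
#'
#' @param n_pairs fuzzed pairs (default 1e4).
#' @param k_max largest trait count drawn.
#' @param seed RNG seed.
#' @return list with `max_rel_err` and `n_pairs`.
#' @export
verify_eigen_identity <- function(n_pairs = 1e4, k_max = 10, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  worst <- 0
  for (i in seq_len(n_pairs)) {
    K <- sample(2:k_max, 1)
    S <- random_correlation(K)
    z <- drop(rmvnorm_rows(1, S))
    t_omni <- omnibus_test(z, S)$statistic
    dec <- omnibus_eigen_identity(z, null_covariance(S))
    worst <- max(worst, abs(dec$total - t_omni) / max(1, abs(t_omni)))
  }
  list(max_rel_err = worst, n_pairs = n_pairs)
}

#' Equivalence of the summary-statistic omnibus test and MANOVA
#'
#' Simulates individual-level genotypes and correlated phenotypes under
#' complete sample overlap, computes per-trait univariate Z-scores, runs the
#' omnibus test with the phenotypic-correlation covariance, and correlates
#' its -log10 p with the exact MANOVA p-values on the same data.
#'
#' @param n_ind individuals (default 5000).
#' @param n_snps SNPs (default 2000).
#' @param K traits (default 5).
#' @param transform apply the mixed uniform/Laplace/exponential margins.
#' @param seed RNG seed.
#' @return list with `cor_loglog` (Pearson on -log10 p) and sizes.
#' @export
verify_manova_equivalence <- function(n_ind = 5000, n_snps = 2000, K = 5,
                                      transform = FALSE, seed = 1) {
  sim <- simulate_individual_level(n_ind, n_snps, K,
                                   n_causal = round(n_snps * 0.1),
                                   beta_sd = 0.05, transform = transform,
                                   seed = seed)
  sc <- gwas_scan(sim$G, sim$Y)
  p_manova <- manova_scan(sim$G, sim$Y)
  cov <- null_covariance(stats::cor(sim$Y))
  res <- multitrait_scan(sc$z, cov, tests = "omnibus")
  list(cor_loglog = stats::cor(-log10(res$p_omnibus), -log10(p_manova)),
       n_ind = n_ind, n_snps = n_snps)
}

#' Inflation under a misspecified null covariance
#'
#' Measures the genomic inflation factor of the omnibus test on null data
#' when the covariance is correct versus uniformly downscaled.
#'
#' @param K traits (default 10).
#' @param n_snps SNPs (default 5e4).
#' @param downscale misspecification factor applied to `Sigma_r`
#'   (default 0.8).
#' @param seed RNG seed.
#' @return list with `lambda_true` and `lambda_downscaled`.
#' @export
verify_covariance_misspecification <- function(K = 10, n_snps = 5e4,
                                               downscale = 0.8, seed = 1) {
  S <- random_correlation(K, seed = seed)
  Z <- simulate_null_panel(S, n_snps, seed = seed + 1)
  good <- multitrait_scan(Z, null_covariance(S), tests = "omnibus")
  bad <- multitrait_scan(Z, null_covariance(S * downscale), tests = "omnibus")
  list(lambda_true = lambda_gc(good$stat_omnibus, K),
       lambda_downscaled = lambda_gc(bad$stat_omnibus, K))
}

#' Contamination of empirical covariance estimators by causal SNPs
#'
#' Simulates a two-trait panel with overlap-induced null covariance plus a
#' polygenic signal concentrated on 10% causal SNPs, then compares the
#' naive, trimmed and LD-score-regression estimates of the null covariance
#' against the design value.
#'
#' @param n_snps SNPs (default 1e5).
#' @param seed RNG seed.
#' @return list: `truth`, `naive`, `trimmed`, `ldsc_intercept`,
#'   `ldsc_se`, `bias_naive`, `bias_trimmed`, `ldsc_covered` (truth inside
#'   the ~95% jackknife CI).
#' @export
verify_sigma_estimators <- function(n_snps = 1e5, seed = 1) {
  sim <- simulate_ldsc_panel(n_snps, n = c(3e4, 3e4), ns = 1.5e4,
                             rho_p = 0.4, h2 = 0.5, rho_g = 0.8,
                             causal_fraction = 0.1, seed = seed)
  truth <- sim$sigma_r[1, 2]
  naive <- empirical_sigma_r(sim$Z, "naive")$sigma_r[1, 2]
  trimmed <- empirical_sigma_r(sim$Z, "trimmed",
                               trim_p = 5e-8)$sigma_r[1, 2]
  cv <- ldsc_sigma(sim$Z, sim$ld_scores, m_snps = sim$m_snps, n = sim$n)
  list(truth = truth, naive = naive, trimmed = trimmed,
       ldsc_intercept = cv$sigma_r[1, 2], ldsc_se = cv$se_r[1, 2],
       bias_naive = naive - truth, bias_trimmed = trimmed - truth,
       ldsc_covered = abs(cv$sigma_r[1, 2] - truth) < 1.96 * cv$se_r[1, 2])
}

# analytic genetic covariance of the scenario's Z_g component
scenario_sigma_g <- function(spec, rho_g) {
  K <- spec$K
  switch(spec$scenario,
         random_eff = diag(12, K),                 # Var of Uniform(-6, 6)
         corG = spec$zg_scale^2 * rho_g,
         highH = diag(spec$zg_scale^2, K),
         hetH = diag(c(spec$zg_scale^2, rep(0, K - 1))),
         diag(1, K))
}

#' Power ordering of the omnibus and sumZ_g tests across effect scenarios
#'
#' Replicates the power study: per replicate, draws a fresh residual
#' correlation and 10-trait causal Z-scores under a scenario, and measures
#' the power of the omnibus test and of the sumZ test weighted by the first
#' eigenvector of the scenario's genetic covariance.
#'
#' @param scenarios scenario tags to run.
#' @param K traits (default 10).
#' @param n_causal causal SNPs per replicate (default 500).
#' @param n_reps replicates (default 50).
#' @param alpha rejection threshold (default 1e-8, the genome-wide joint
#'   threshold).
#' @param seed RNG seed.
#' @return data.frame per scenario: mean power of both tests, the mean
#'   paired difference and its standard error.
#' @export
verify_power_ordering <- function(scenarios = c("random_eff", "highH",
                                                "hetH"),
                                  K = 10, n_causal = 500, n_reps = 50,
                                  alpha = 1e-8, seed = 1) {
  out <- lapply(scenarios, function(sc) {
    p_omni <- p_sumzg <- numeric(n_reps)
    for (r in seq_len(n_reps)) {
      spec <- scenario_spec(sc, K = K, n_causal = n_causal,
                            overlap = 0.5, seed = seed + 1000 * r)
      sim <- simulate_power_panel(spec)
      cov <- null_covariance(sim$sigma_r,
                             sigma_g = scenario_sigma_g(spec, sim$rho_g))
      res <- multitrait_scan(sim$Z, cov, tests = c("omnibus", "sumz_g"))
      p_omni[r] <- mean(res$p_omnibus < alpha)
      p_sumzg[r] <- mean(res$p_sumz_g < alpha)
    }
    d <- p_omni - p_sumzg
    data.frame(scenario = sc, power_omnibus = mean(p_omni),
               power_sumz_g = mean(p_sumzg), diff = mean(d),
               se_diff = stats::sd(d) / sqrt(n_reps))
  })
  do.call(rbind, out)
}

#' Imputation fidelity: closed form at lambda = 0 and null-distribution drift
#'
#' Checks that ridge-free imputation equals the Gaussian conditional
#' expectation on one LD block, then masks entries of a large blockwise-LD
#' null panel, imputes them, and measures the Kolmogorov-Smirnov distance
#' between the omnibus p-value distributions before and after imputation.
#'
#' @param n_blocks LD blocks (default 200).
#' @param block_size SNPs per block (default 100).
#' @param rho AR(1) LD decay within a block (default 0.7).
#' @param trait_cor cross-trait null correlation (default 0.3).
#' @param missing_rate fraction of trait-1 entries masked (default 0.3).
#' @param seed RNG seed.
#' @return list: `max_closed_form_err`, `ks_distance`, `n_snps`,
#'   `frac_imputed`.
#' @export
verify_imputation <- function(n_blocks = 200, block_size = 100, rho = 0.7,
                              trait_cor = 0.3, missing_rate = 0.3, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  R0 <- rho^abs(outer(seq_len(block_size), seq_len(block_size), `-`))
  S <- matrix(c(1, trait_cor, trait_cor, 1), 2)
  ids_all <- sprintf("s%06d", seq_len(n_blocks * block_size))
  mats <- vector("list", n_blocks)
  Z <- matrix(0, n_blocks * block_size, 2)
  chS <- t(chol(S))
  for (b in seq_len(n_blocks)) {
    rows <- (b - 1) * block_size + seq_len(block_size)
    R <- R0
    dimnames(R) <- list(ids_all[rows], ids_all[rows])
    mats[[b]] <- R
    Z[rows, ] <- t(chS %*% rmvnorm_rows(2, R0))
  }
  regions <- region_set(rep("1", n_blocks),
                        (seq_len(n_blocks) - 1) * block_size * 1000 + 1,
                        seq_len(n_blocks) * block_size * 1000)
  ld <- ld_panel(regions, mats)
  colnames(Z) <- c("a", "b")

  # closed-form check on the first block, trait 1, lambda = 0
  z1 <- Z[seq_len(block_size), 1]
  names(z1) <- ids_all[seq_len(block_size)]
  obs <- seq_len(block_size) %% 3 != 0
  imp <- impute_region(z1[obs], mats[[1]], lambda = 0,
                       quality_threshold = 0)
  W <- R0[!obs, obs] %*% solve(R0[obs, obs])
  max_err <- max(abs(imp$z_imp - drop(W %*% z1[obs])))

  # mask, impute, compare omnibus p-value distributions
  snps <- data.frame(snp_id = ids_all, chrom = "1",
                     pos = as.integer(seq_along(ids_all) * 1000 - 500),
                     coded_allele = "A", other_allele = "G")
  N <- matrix(5e4, nrow(Z), 2, dimnames = list(NULL, colnames(Z)))
  panel <- sumstats_panel(snps, Z, N)
  miss <- sample(nrow(Z), round(missing_rate * nrow(Z)))
  panel$Z[miss, 1] <- NA
  panel <- impute_panel(panel, ld, lambda = 0.1, quality_threshold = 0.6)
  cov <- null_covariance(S)
  p_pre <- multitrait_scan(Z, cov, tests = "omnibus")$p_omnibus
  p_post <- multitrait_scan(panel, cov, tests = "omnibus",
                            na_action = "subset")$p_omnibus
  ks <- suppressWarnings(stats::ks.test(p_pre, p_post)$statistic)
  list(max_closed_form_err = max_err, ks_distance = unname(ks),
       n_snps = nrow(Z), frac_imputed = mean(panel$imputed[, 1]))
}

#' Recovery of a well-separated mixture under missing data
#'
#' On a 3-component fixture whose means are 10 within-cluster standard
#' deviations apart in every coordinate, with MCAR missingness: runs the
#' bootstrap model selection and the EM fit across seeds, measuring how
#' often k = 3 is selected, the mean absolute error of the recovered means,
#' the assignment accuracy and log-likelihood monotonicity.
#'
#' @param n_seeds seeds examined (default 20).
#' @param n SNPs per fixture (default 2000).
#' @param K traits (default 4).
#' @param missing_rate MCAR rate (default 0.2).
#' @param k_range candidate k for selection (default 2:5).
#' @param n_boot bootstrap replicates per k (default 5).
#' @param seed base RNG seed.
#' @return list: `prop_k_correct`, `k_selected`, `mean_mu_err`,
#'   `min_accuracy`, `mean_accuracy`, `loglik_monotone`.
#' @export
verify_mgmm_recovery <- function(n_seeds = 20, n = 2000, K = 4,
                                 missing_rate = 0.2, k_range = 2:5,
                                 n_boot = 5, seed = 1) {
  mu_true <- rbind(rep(-10, K), rep(0, K), rep(10, K))
  k_sel <- integer(n_seeds)
  mu_err <- acc <- numeric(n_seeds)
  mono <- logical(n_seeds)
  for (i in seq_len(n_seeds)) {
    s <- seed + 37 * i
    sim <- simulate_cluster_panel(c(0.3, 0.4, 0.3), mu_true, diag(K), n,
                                  missing_rate = missing_rate, seed = s)
    ks <- select_k(sim$Z, k_range = k_range, n_boot = n_boot,
                   subsample = 0.8, seed = s, n_init = 2, max_iter = 80)
    k_sel[i] <- ks$k
    fit <- fit_mgmm(sim$Z, 3, seed = s)
    mu_err[i] <- mean(abs(fit$mu - mu_true))
    acc[i] <- mean(fit$assignment == sim$labels)
    mono[i] <- all(diff(fit$loglik_trace) > -1e-8 * abs(fit$loglik))
  }
  list(prop_k_correct = mean(k_sel == 3), k_selected = k_sel,
       mean_mu_err = mean(mu_err), min_accuracy = min(acc),
       mean_accuracy = mean(acc), loglik_monotone = all(mono))
}

#' Bias correction of the per-cluster genetic covariance under overlap
#'
#' Simulates clusters of standardized effects for two fully overlapping
#' GWAS with phenotypic correlation, compares the naive and
#' overlap-corrected covariance estimators against the design value, and
#' measures the type-I error of the per-cluster t-test on null clusters.
#'
#' @param n_snps_cluster SNPs per cluster (default 150).
#' @param n_reps estimation replicates (default 300).
#' @param n_null_reps calibration replicates (default 1000).
#' @param n sample size of both GWAS (full overlap; default 2e4).
#' @param rho phenotypic correlation (default 0.4).
#' @param sigma_g true per-SNP genetic covariance (default 1.6e-4).
#' @param seed RNG seed.
#' @return list: `truth`, `mean_naive`, `mean_corrected`, `bias_naive`,
#'   `bias_corrected`, `mc_se`, `within_2se`, `type1_error`, `type1_bound`.
#' @export
verify_cluster_covariance <- function(n_snps_cluster = 150, n_reps = 300,
                                      n_null_reps = 1000, n = 2e4,
                                      rho = 0.4, sigma_g = 1.6e-4, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  M <- n_snps_cluster
  Sg <- matrix(c(2, 1, 1, 2), 2) * sigma_g   # gcov = sigma_g, var 2x
  Se <- matrix(c(1, rho, rho, 1) / n, 2)
  naive <- corrected <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    b <- rmvnorm_rows(M, Sg)
    bh <- b + rmvnorm_rows(M, Se)
    naive[r] <- mean(bh[, 1] * bh[, 2])
    corrected[r] <- cluster_genetic_covariance(bh[, 1], bh[, 2], n, n,
                                               ns = n, rho_y = rho)$covariance
  }
  p_null <- vapply(seq_len(n_null_reps), function(r) {
    e <- rmvnorm_rows(M, Se)
    cluster_genetic_covariance(e[, 1], e[, 2], n, n, ns = n,
                               rho_y = rho)$pvalue
  }, 0)
  mc_se <- stats::sd(corrected) / sqrt(n_reps)
  list(truth = sigma_g, mean_naive = mean(naive),
       mean_corrected = mean(corrected),
       bias_naive = mean(naive) - sigma_g,
       bias_corrected = mean(corrected) - sigma_g,
       mc_se = mc_se,
       within_2se = abs(mean(corrected) - sigma_g) < 2 * mc_se,
       type1_error = mean(p_null < 0.05),
       type1_bound = 0.05 + 3 * sqrt(0.05 * 0.95 / n_null_reps))
}

#' Sample-size proxy: linear-model recovery and logistic proportionality
#'
#' Runs a null linear GWAS on a standardized outcome at N individuals and
#' measures the median of the inferred-to-true sample-size ratio; then runs
#' null logistic GWAS across a case-fraction grid and measures the
#' coefficient of variation of `median(n_hat) / (N p (1 - p))`.
#'
#' @param n_ind_linear individuals in the linear study (default 2e4).
#' @param n_snps_linear SNPs in the linear study (default 300).
#' @param n_ind_logit individuals per logistic study (default 4000).
#' @param n_snps_logit SNPs per logistic study (default 40).
#' @param case_fractions case-fraction grid (default 0.1 .. 0.5).
#' @param seed RNG seed.
#' @return list: `median_ratio_linear`, `slope_cv_logit`, `slopes`.
#' @export
verify_sample_size_proxy <- function(n_ind_linear = 2e4, n_snps_linear = 300,
                                     n_ind_logit = 4000, n_snps_logit = 40,
                                     case_fractions = c(0.1, 0.2, 0.35, 0.5),
                                     seed = 1) {
  sim <- simulate_individual_level(n_ind_linear, n_snps_linear, 2,
                                   seed = seed)
  sc <- gwas_scan(sim$G, sim$Y)
  se_raw <- sc$se[, 1] / apply(sim$G_raw, 2, stats::sd)
  tab <- sumstats_table(data.frame(
    snp_id = sprintf("s%04d", seq_len(n_snps_linear)), chrom = "1",
    pos = seq_len(n_snps_linear) * 10L, coded_allele = "A",
    other_allele = "G", se = se_raw, freq = colMeans(sim$G_raw) / 2))
  median_ratio <- stats::median(infer_sample_size(tab)$n) / n_ind_linear

  slopes <- vapply(seq_along(case_fractions), function(i) {
    cf <- case_fractions[i]
    gw <- simulate_logistic_gwas(n_ind_logit, n_snps_logit, cf,
                                 seed = seed + i)
    tb <- sumstats_table(cbind(
      data.frame(snp_id = gw$snp_id, chrom = "1",
                 pos = seq_len(nrow(gw)) * 10L, coded_allele = "A",
                 other_allele = "G"),
      gw[c("beta", "se", "freq")]))
    stats::median(infer_sample_size(tb)$n) / (n_ind_logit * cf * (1 - cf))
  }, 0)
  list(median_ratio_linear = median_ratio,
       slope_cv_logit = stats::sd(slopes) / mean(slopes), slopes = slopes)
}

#' Deterministic micro-oracles of the core statistics
#'
#' Collects the hand-checkable values: the omnibus statistic at
#' `z = (3, 4)` with identity covariance, the unit-weight sumZ at
#' `z = (2, 2)`, the entropy of an even split, the sign-test p for 10
#' concordant signs, and the lead count of a fully linked clump toy.
#'
#' @return named list of the computed values.
#' @export
verify_micro_oracles <- function() {
  ids <- c("a", "b", "c")
  R <- matrix(0.95, 3, 3); diag(R) <- 1
  dimnames(R) <- list(ids, ids)
  ld <- ld_panel(region_set("1", 1, 4000), list(R))
  cl <- clump(data.frame(snp_id = ids, chrom = "1", pos = c(100, 200, 300),
                         p = c(1e-9, 1e-10, 1e-9)),
              ld, p1 = 1e-8, r2 = 0.2)
  list(omnibus_3_4 = omnibus_test(c(3, 4), diag(2))$statistic,
       sumz_2_2 = sumz_test(c(2, 2), c(1, 1), diag(2))$statistic,
       entropy_even = entropy(c(0.5, 0.5)),
       sign_test_10_of_10 = disease_sign_test(rep(1, 10))$pvalue,
       clump_leads_linked_toy = nrow(cl))
}
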