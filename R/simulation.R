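# Simulation engine: generators with the statistical structure the methods
# assume. These are first-class, tested code: they define the study
# conditions under which calibration, power and recovery are verified.

#' Random correlation matrix (uniform over the elliptope)
#'
#' Onion-method sampler (LKJ with eta = 1): grows the matrix one dimension
#' at a time, drawing the new correlation vector uniformly inside the
#' ellipsoid that keeps the matrix positive semi-definite.
#'
#' @param K dimension (>= 2).
#' @param seed optional RNG seed.
#' @return a K x K correlation matrix.
#' @export
random_correlation <- function(K, seed = NULL) {
  stopifnot(K >= 2)
  if (!is.null(seed)) { old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old)); set.seed(seed) }
  R <- diag(1, K)
  beta <- 1 + (K - 2) / 2
  R[1, 2] <- R[2, 1] <- 2 * stats::rbeta(1, beta, beta) - 1
  if (K == 2) return(R)
  for (k in 2:(K - 1)) {
    beta <- beta - 0.5
    y <- stats::rbeta(1, k / 2, beta)
    u <- stats::rnorm(k)
    u <- u / sqrt(sum(u^2))
    w <- sqrt(y) * u
    q <- drop(t(chol(R[1:k, 1:k])) %*% w)
    R[1:k, k + 1] <- R[k + 1, 1:k] <- q
  }
  R
}

#' Simulate a null multitrait Z-score panel
#'
#' Rows i.i.d. `N(0, sigma_r)`: the complete-null setting in which every
#' multitrait test must be calibrated.
#'
#' @param sigma_r K x K null Z-score covariance.
#' @param n_snps number of SNPs (rows).
#' @param seed optional RNG seed.
#' @return an `n_snps` x K matrix.
#' @export
simulate_null_panel <- function(sigma_r, n_snps, seed = NULL) {
  if (!is.null(seed)) { old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old)); set.seed(seed) }
  Z <- rmvnorm_rows(n_snps, sigma_r)
  colnames(Z) <- colnames(sigma_r) %||% paste0("trait", seq_len(ncol(sigma_r)))
  Z
}

#' Power-study scenario specification
#'
#' @param scenario one of `"random_eff"` (genetic Z uniform on \[-6, 6\] per
#'   trait), `"corG"` (multivariate normal with a random genetic
#'   correlation), `"wG"` (effects along one direction plus isotropic
#'   noise), `"highH"` (independent traits, all with strong effects),
#'   `"hetH"` (only trait 1 with strong effects), `"null"` (no effects).
#' @param K number of traits (default 10).
#' @param n_causal causal SNP count (default 5000).
#' @param n_null additional null SNP count (default 0).
#' @param overlap sample-overlap fraction in \[0, 1\]; with equal per-trait
#'   sample size n and shared count ns = overlap * n, the null covariance is
#'   `rho * overlap`.
#' @param residual_mode `"random"` (residual correlation drawn at random) or
#'   `"aligned"` (`rho_r = 0.4 * rho_g + 0.6 * E`, E random, projected back
#'   to a correlation matrix).
#' @param zg_scale standard deviation of the strong genetic effects
#'   (default 4; the scale of "high heritability").
#' @param seed RNG seed.
#' @return a `ScenarioSpec` list.
#' @export
scenario_spec <- function(scenario = c("random_eff", "corG", "wG", "highH",
                                       "hetH", "null"),
                          K = 10, n_causal = 5000, n_null = 0, overlap = 1,
                          residual_mode = c("random", "aligned"),
                          zg_scale = 4, seed = 1) {
  stopifnot(overlap >= 0, overlap <= 1, K >= 2)
  structure(list(scenario = match.arg(scenario), K = K, n_causal = n_causal,
                 n_null = n_null, overlap = overlap,
                 residual_mode = match.arg(residual_mode),
                 zg_scale = zg_scale, seed = seed),
            class = "ScenarioSpec")
}

# Project a symmetric matrix to the nearest correlation matrix (clip
# eigenvalues, renormalize the diagonal).
nearest_correlation <- function(m) {
  eg <- eigen(symmetrize(m), symmetric = TRUE)
  vals <- pmax(eg$values, 1e-8)
  s <- symmetrize(eg$vectors %*% (t(eg$vectors) * vals))
  d <- sqrt(diag(s))
  s / tcrossprod(d)
}

#' Simulate causal multitrait Z-scores: Z = Z_genetic + Z_residual
#'
#' Each causal SNP's Z vector is the sum of a scenario-specific genetic
#' component and a residual component drawn from `N(0, sigma_r)` with the
#' overlap-induced covariance `rho * overlap` (unit diagonal). Optional null
#' SNPs carry the residual component only.
#'
#' @param spec a [scenario_spec()].
#' @return list: `Z` (matrix), `causal` (logical), `sigma_r`, `rho_g`
#'   (genetic correlation used, when any), `spec`.
#' @export
simulate_power_panel <- function(spec) {
  stopifnot(inherits(spec, "ScenarioSpec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  K <- spec$K
  rho_g <- random_correlation(K)
  E <- random_correlation(K)
  rho_r <- if (spec$residual_mode == "aligned")
    nearest_correlation(0.4 * rho_g + 0.6 * E) else E
  sigma_r <- diag(1 - spec$overlap, K) + spec$overlap * rho_r

  n <- spec$n_causal
  Zg <- switch(spec$scenario,
    random_eff = matrix(stats::runif(n * K, -6, 6), n, K),
    corG = rmvnorm_rows(n, spec$zg_scale^2 * rho_g),
    wG = {
      d <- canonical_sign(eigen(rho_g, symmetric = TRUE)$vectors[, 1])
      tcrossprod(stats::rnorm(n, 0, spec$zg_scale), d) +
        matrix(stats::rnorm(n * K), n, K)
    },
    highH = matrix(stats::rnorm(n * K, 0, spec$zg_scale), n, K),
    hetH = cbind(stats::rnorm(n, 0, spec$zg_scale),
                 matrix(0, n, K - 1)),
    null = matrix(0, n, K))
  Z <- Zg + rmvnorm_rows(n, sigma_r)
  causal <- rep(spec$scenario != "null", n)
  if (spec$n_null > 0) {
    Z <- rbind(Z, rmvnorm_rows(spec$n_null, sigma_r))
    causal <- c(causal, rep(FALSE, spec$n_null))
  }
  colnames(Z) <- paste0("trait", seq_len(K))
  list(Z = Z, causal = causal, sigma_r = sigma_r, rho_g = rho_g, spec = spec)
}

#' Simulate individual-level genotypes and correlated phenotypes
#'
#' Genotypes are Binomial(2, f) with per-SNP frequency f uniform in
#' `freq_range`, standardized; phenotypes are `Y = G_std B + E` with
#' residuals multivariate normal under the given trait correlation and unit
#' total variance target. Optionally the traits are quantile-transformed in
#' thirds to uniform / Laplace / exponential margins (a non-normality
#' stress).
#'
#' @param n_ind individuals (<= 5e4; desk-scale).
#' @param n_snps SNPs.
#' @param K traits.
#' @param n_causal causal SNP count (effects on every trait).
#' @param beta_sd per-trait effect SD of causal standardized genotypes.
#' @param trait_cor K x K residual correlation (default from
#'   [random_correlation()]).
#' @param transform apply the non-normal margins.
#' @param freq_range allele-frequency bounds (default `c(0.01, 0.99)`).
#' @param seed RNG seed.
#' @return list: `G` (standardized genotypes), `G_raw`, `Y`, `freq`,
#'   `causal`, `trait_cor`.
#' @export
simulate_individual_level <- function(n_ind, n_snps, K, n_causal = 0,
                                      beta_sd = 0.05, trait_cor = NULL,
                                      transform = FALSE,
                                      freq_range = c(0.01, 0.99), seed = 1) {
  stopifnot(n_ind <= 5e4, n_snps <= 1e4)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- stats::runif(n_snps, freq_range[1], freq_range[2])
  G_raw <- matrix(stats::rbinom(n_ind * n_snps, 2, rep(f, each = n_ind)),
                  n_ind, n_snps)
  G <- scale(G_raw)
  G[is.na(G)] <- 0
  if (is.null(trait_cor)) trait_cor <- random_correlation(K)
  Y <- rmvnorm_rows(n_ind, trait_cor)
  causal <- rep(FALSE, n_snps)
  if (n_causal > 0) {
    causal[sample.int(n_snps, n_causal)] <- TRUE
    B <- matrix(stats::rnorm(n_causal * K, 0, beta_sd), n_causal, K)
    Y <- Y + G[, causal, drop = FALSE] %*% B
  }
  if (transform) {
    thirds <- cut(seq_len(K), 3, labels = FALSE)
    qlaplace <- function(p) ifelse(p < 0.5, log(2 * p), -log(2 * (1 - p)))
    for (j in seq_len(K)) {
      u <- rank(Y[, j]) / (n_ind + 1)
      Y[, j] <- switch(thirds[j], u, qlaplace(u), stats::qexp(u))
    }
  }
  list(G = G, G_raw = G_raw, Y = Y, freq = f, causal = causal,
       trait_cor = trait_cor)
}

#' Per-trait univariate GWAS on simulated individual-level data
#'
#' Simple linear regression of each trait on each standardized genotype
#' (with intercept), vectorized over SNPs.
#'
#' @param G standardized genotype matrix (individuals x SNPs).
#' @param Y phenotype matrix (individuals x traits).
#' @return list of SNP x trait matrices: `beta`, `se`, `z`.
#' @export
gwas_scan <- function(G, Y) {
  n <- nrow(G)
  Gc <- scale(G, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  ss <- colSums(Gc^2)
  B <- crossprod(Gc, Yc) / ss                    # n_snps x K
  yty <- colSums(Yc^2)
  rss <- sweep(-B^2 * ss, 2, yty, `+`)           # yty - b^2 * ss per snp x trait
  se <- sqrt(rss / (n - 2) / ss)
  list(beta = B, se = se, z = B / se)
}

#' Closed-form one-predictor MANOVA p-values
#'
#' For a single predictor the four classical MANOVA statistics coincide;
#' with `a = h' T^{-1} h` (h the scaled cross-covariance between genotype
#' and the centered traits, T the total SSCP), the single nonzero eigenvalue
#' of `H E^{-1}` is `a / (1 - a)` and the exact F statistic is
#' `lambda * (n - K - 1) / K` on `(K, n - K - 1)` df. Vectorized over SNPs.
#'
#' @param G standardized genotype matrix (individuals x SNPs).
#' @param Y phenotype matrix (individuals x traits).
#' @return per-SNP MANOVA p-values.
#' @export
manova_scan <- function(G, Y) {
  n <- nrow(G); K <- ncol(Y)
  Gc <- scale(G, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Tm <- crossprod(Yc)
  H <- crossprod(Yc, Gc)
  H <- sweep(H, 2, sqrt(colSums(Gc^2)), `/`)     # columns h_s
  a <- colSums(H * solve(Tm, H))
  lambda <- a / (1 - a)
  Fstat <- lambda * (n - K - 1) / K
  stats::pf(Fstat, K, n - K - 1, lower.tail = FALSE)
}

#' Simulate a mixture-distributed multitrait Z panel with MCAR missingness
#'
#' Test bed for the missing-data Gaussian-mixture clustering: labels are
#' multinomial, rows component-wise multivariate normal, missing entries
#' completely at random.
#'
#' @param pi mixture weights (length k).
#' @param mu k x K component means.
#' @param sigmas list of k covariance matrices (a single matrix is
#'   recycled).
#' @param n_snps rows to draw.
#' @param missing_rate MCAR missingness in \[0, 0.6\]; rows losing all
#'   coordinates are redrawn to keep one observed.
#' @param seed RNG seed.
#' @return list: `Z` (with `NA`s), `labels`.
#' @export
simulate_cluster_panel <- function(pi, mu, sigmas, n_snps,
                                   missing_rate = 0, seed = 1) {
  stopifnot(abs(sum(pi) - 1) < 1e-8, missing_rate >= 0, missing_rate <= 0.6)
  k <- length(pi); K <- ncol(mu)
  if (is.matrix(sigmas)) sigmas <- rep(list(sigmas), k)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  labels <- sample.int(k, n_snps, replace = TRUE, prob = pi)
  Z <- matrix(0, n_snps, K)
  for (j in seq_len(k)) {
    rows <- which(labels == j)
    if (length(rows))
      Z[rows, ] <- sweep(rmvnorm_rows(length(rows), sigmas[[j]]), 2,
                         mu[j, ], `+`)
  }
  if (missing_rate > 0) {
    mask <- matrix(stats::runif(n_snps * K) < missing_rate, n_snps, K)
    all_gone <- rowSums(!mask) == 0
    if (any(all_gone)) {           # keep at least one observed coordinate
      keep_col <- sample.int(K, sum(all_gone), replace = TRUE)
      mask[cbind(which(all_gone), keep_col)] <- FALSE
    }
    Z[mask] <- NA_real_
  }
  rownames(Z) <- sprintf("snp%06d", seq_len(n_snps))
  colnames(Z) <- paste0("trait", seq_len(K))
  list(Z = Z, labels = labels)
}

#' Simulate Z-scores under a polygenic LD-score model
#'
#' Per SNP j with LD score `l_j`, the Z vector is
#' `N(0, Sigma_r + (l_j * s_j / M) * Gmat)` where `Sigma_r` is the
#' overlap-induced null covariance (unit diagonal, off-diagonal
#' `rho * ns / sqrt(n1 n2)`), `Gmat_ab = sqrt(n_a n_b) * Cg_ab` with `Cg`
#' the per-SNP-scale genetic covariance of standardized effects, and `s_j`
#' concentrates the genetic variance on a causal fraction
#' (`s_j = 1/causal_fraction` for causal SNPs, 0 otherwise; genome-wide
#' average 1).
#'
#' @param n_snps SNPs.
#' @param n per-trait sample sizes (length K).
#' @param ns K x K overlap counts (scalar recycled).
#' @param rho_p K x K phenotypic correlations among overlapping samples
#'   (scalar recycled; diagonal forced to 1).
#' @param h2 per-trait heritabilities.
#' @param rho_g K x K genetic correlations (scalar recycled).
#' @param causal_fraction fraction of causal SNPs (default 1 = infinitesimal).
#' @param ld_scores optional per-SNP LD scores (default Gamma-distributed,
#'   mean ~ 90).
#' @param m_snps M behind the LD scores (defaults to `n_snps`).
#' @param seed RNG seed.
#' @return list: `Z`, `ld_scores`, `causal`, `sigma_r`, `sigma_g`
#'   (`= Cg`, the standardized genetic covariance), `n`, `m_snps`.
#' @export
simulate_ldsc_panel <- function(n_snps, n, ns = 0, rho_p = 0, h2 = 0,
                                rho_g = 0, causal_fraction = 1,
                                ld_scores = NULL, m_snps = NULL, seed = 1) {
  K <- length(n)
  if (length(ns) == 1) ns <- matrix(ns, K, K)
  if (length(rho_p) == 1) rho_p <- matrix(rho_p, K, K)
  if (length(rho_g) == 1) rho_g <- matrix(rho_g, K, K)
  diag(rho_p) <- 1; diag(rho_g) <- 1
  if (length(h2) == 1) h2 <- rep(h2, K)
  if (any(ns > outer(n, n, pmin))) stop("ns cannot exceed min(n_a, n_b)",
                                        call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  m_snps <- m_snps %||% n_snps
  if (is.null(ld_scores)) ld_scores <- 1 + stats::rgamma(n_snps, 3, scale = 30)
  sigma_r <- rho_p * ns / sqrt(outer(n, n))
  diag(sigma_r) <- 1
  Cg <- rho_g * sqrt(outer(h2, h2))                 # standardized scale
  Gmat <- sqrt(outer(n, n)) * Cg
  causal <- stats::runif(n_snps) < causal_fraction
  s <- ifelse(causal, 1 / causal_fraction, 0)
  Z <- rmvnorm_rows(n_snps, sigma_r)
  if (any(Gmat != 0)) {
    Zg <- rmvnorm_rows(n_snps, Gmat)
    Z <- Z + Zg * sqrt(ld_scores * s / m_snps)
  }
  colnames(Z) <- paste0("trait", seq_len(K))
  list(Z = Z, ld_scores = ld_scores, causal = causal, sigma_r = sigma_r,
       sigma_g = Cg, n = n, m_snps = m_snps)
}

#' Simulate a null panel with per-SNP heterogeneous sample overlap
#'
#' Each SNP draws its own overlap fraction `o_i`; its null covariance is
#' `o_i * C + (1 - o_i) * I` with `C` the trait correlation. Testing such a
#' panel against a single genome-wide covariance (the mean-overlap one)
#' reproduces the inflation that motivates the low-sample-size filter.
#'
#' @param C K x K trait correlation matrix.
#' @param n_snps SNPs.
#' @param overlaps per-SNP overlap fractions (recycled).
#' @param seed RNG seed.
#' @return list: `Z`, `overlaps`, `sigma_r_mean` (covariance at the mean
#'   overlap).
#' @export
simulate_hetn_panel <- function(C, n_snps, overlaps, seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  o <- rep_len(overlaps, n_snps)
  A <- rmvnorm_rows(n_snps, C)
  B <- matrix(stats::rnorm(n_snps * ncol(C)), n_snps, ncol(C))
  Z <- A * sqrt(o) + B * sqrt(1 - o)
  om <- mean(o)
  list(Z = Z, overlaps = o,
       sigma_r_mean = om * C + (1 - om) * diag(ncol(C)))
}

#' Null case-control GWAS for sample-size-proxy checks
#'
#' Simulates a binary outcome with case fraction `p` independent of
#' genotype, runs per-SNP logistic regressions, and returns the summary
#' statistics (`beta`, `se`, `freq`) the sample-size-proxy estimator
#' consumes.
#'
#' @param n_ind individuals.
#' @param n_snps SNPs.
#' @param case_fraction in-sample case proportion.
#' @param freq_range allele-frequency bounds.
#' @param seed RNG seed.
#' @return data.frame: `snp_id`, `beta`, `se`, `freq` (in-sample), `n`.
#' @export
simulate_logistic_gwas <- function(n_ind, n_snps, case_fraction,
                                   freq_range = c(0.05, 0.95), seed = 1) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  f <- stats::runif(n_snps, freq_range[1], freq_range[2])
  y <- stats::rbinom(n_ind, 1, case_fraction)
  beta <- se <- fr <- numeric(n_snps)
  for (s in seq_len(n_snps)) {
    g <- stats::rbinom(n_ind, 2, f[s])
    fit <- stats::glm.fit(cbind(1, g), y, family = stats::binomial())
    cf <- fit$coefficients[2]
    # Wald SE from the final IRLS weights
    X <- cbind(1, g)
    V <- solve(crossprod(X * sqrt(fit$weights), X * sqrt(fit$weights)))
    beta[s] <- cf
    se[s] <- sqrt(V[2, 2])
    fr[s] <- mean(g) / 2
  }
  data.frame(snp_id = sprintf("snp%05d", seq_len(n_snps)),
             beta = beta, se = se, freq = fr, n = n_ind)
}

#' Genomic inflation factor
#'
#' Ratio of the median observed chi-square statistic to the null median at
#' the given degrees of freedom.
#'
#' @param statistic observed chi-square statistics.
#' @param df degrees of freedom.
#' @return scalar lambda.
#' @export
lambda_gc <- function(statistic, df) {
  stats::median(statistic, na.rm = TRUE) / stats::qchisq(0.5, df)
}
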