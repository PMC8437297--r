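# Estimation of the null Z-score covariance Sigma_r (and genetic covariance
# Sigma_g), and the SVD/eigen pseudo-inverse used by the multitrait tests.
#
# At null SNPs the per-trait Z-scores are correlated only through sample
# overlap and phenotypic correlation: cov(z1, z2) = rho * ns / sqrt(n1 * n2).
# Under a polygenic model, cross-trait LD-score regression separates this
# overlap-induced intercept from the genetic-covariance slope.

#' Construct a null Z-score covariance object
#'
#' @param sigma_r K x K symmetric residual covariance of null Z-scores.
#' @param sigma_g optional K x K genetic covariance.
#' @param method provenance tag: one of `"theoretical"`, `"naive"`,
#'   `"pruned"`, `"trimmed"`, `"ldsc"`, `"external"`.
#' @param se_r,se_g optional matrices of standard errors (LDSC jackknife).
#' @return a `NullCovariance` object.
#' @export
null_covariance <- function(sigma_r, sigma_g = NULL, method = "external",
                            se_r = NULL, se_g = NULL) {
  check_symmetric(sigma_r, 1e-10, "sigma_r")
  if (any(diag(sigma_r) <= 0)) stop("sigma_r diagonal must be > 0", call. = FALSE)
  if (!is.null(sigma_g)) check_symmetric(sigma_g, 1e-8, "sigma_g")
  method <- match.arg(method, c("theoretical", "naive", "pruned", "trimmed",
                                "ldsc", "external"))
  ev <- eigen(symmetrize(sigma_r), symmetric = TRUE, only.values = TRUE)$values
  structure(list(sigma_r = symmetrize(sigma_r), sigma_g = sigma_g,
                 method = method, rank = sum(ev > 1e-10 * max(ev)),
                 se_r = se_r, se_g = se_g),
            class = "NullCovariance")
}

#' @export
print.NullCovariance <- function(x, ...) {
  cat("NullCovariance (", x$method, "): K =", ncol(x$sigma_r),
      ", rank =", x$rank,
      if (!is.null(x$sigma_g)) ", with sigma_g" else "", "\n")
  invisible(x)
}

#' Expected null Z-score covariance under sample overlap
#'
#' For two GWAS with sample sizes `n1` and `n2` sharing `ns` individuals
#' whose phenotypic correlation is `rho`, the null covariance of the two
#' Z-scores is `rho * ns / sqrt(n1 * n2)`.
#'
#' @param n1,n2 per-study sample sizes.
#' @param ns overlapping sample count, `ns <= min(n1, n2)`.
#' @param rho phenotypic correlation among the overlapping samples.
#' @return the scalar covariance.
#' @export
theoretical_sigma_r <- function(n1, n2, ns, rho) {
  stopifnot(n1 > 0, n2 > 0, ns >= 0, abs(rho) <= 1)
  if (any(ns > pmin(n1, n2)))
    stop("ns cannot exceed min(n1, n2)", call. = FALSE)
  rho * ns / sqrt(n1 * n2)
}

#' Empirical null covariance from genome-wide Z-scores
#'
#' Pairwise-complete covariance of the panel's Z columns. `"naive"` uses all
#' SNPs; `"pruned"` a random subset (approximating LD pruning when SNPs are
#' dense); `"trimmed"` removes SNPs with any per-trait p-value below `trim_p`
#' first, reducing contamination by true associations.
#'
#' @param panel a [sumstats_panel()] or a plain Z matrix.
#' @param mode `"naive"`, `"pruned"` or `"trimmed"`.
#' @param trim_p per-trait p-value threshold for `"trimmed"` (default 5e-8).
#' @param subset_size SNP count for `"pruned"` (default a tenth, at least
#'   1000).
#' @param min_pairs minimum pairwise-complete observations required per trait
#'   pair (default 1000).
#' @param seed RNG seed for the pruned subset.
#' @return a [null_covariance()] with the matching method tag.
#' @export
empirical_sigma_r <- function(panel, mode = c("naive", "pruned", "trimmed"),
                              trim_p = 5e-8, subset_size = NULL,
                              min_pairs = 1000, seed = 1) {
  mode <- match.arg(mode)
  Z <- if (inherits(panel, "SumstatsPanel")) panel$Z else as.matrix(panel)
  if (mode == "trimmed") {
    hit <- rowSums(p_from_z(Z) < trim_p, na.rm = TRUE) > 0
    Z <- Z[!hit, , drop = FALSE]
  } else if (mode == "pruned") {
    m <- subset_size %||% max(1000L, nrow(Z) %/% 10L)
    m <- min(m, nrow(Z))
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    Z <- Z[sort(sample.int(nrow(Z), m)), , drop = FALSE]
  }
  obs <- !is.na(Z)
  pair_n <- crossprod(obs)
  if (min(pair_n) < min_pairs)
    stop("fewer than ", min_pairs, " pairwise-complete observations for ",
         "some trait pair", call. = FALSE)
  s <- stats::cov(Z, use = "pairwise.complete.obs")
  null_covariance(symmetrize(s), method = mode)
}

# Save/restore .Random.seed so estimator-internal subsampling does not
# perturb the caller's RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Cross-trait LD-score regression estimate of the Z-score covariances
#'
#' For each trait pair (j, k), regresses the per-SNP product `z_j * z_k` on
#' the LD score `l`: the intercept estimates the overlap-induced null
#' covariance `(Sigma_r)_jk` and the slope times `M / sqrt(n_j n_k)` the
#' genetic covariance `(Sigma_g)_jk` (`M` = number of SNPs the LD scores are
#' computed over; diagonal terms use `M / n_j`). Regression weights default
#' to `1 / l`; standard errors come from a delete-block jackknife over
#' contiguous SNP blocks.
#'
#' @param panel a [sumstats_panel()] or Z matrix.
#' @param ld_scores positive per-SNP LD scores aligned to the panel rows.
#' @param m_snps the SNP count `M` behind the LD scores (defaults to the
#'   panel row count).
#' @param n per-trait sample sizes (defaults to per-trait medians of the
#'   panel's `N`).
#' @param n_blocks jackknife block count (default 200).
#' @return a [null_covariance()] with `sigma_g`, `se_r`, `se_g` filled.
#' @export
ldsc_sigma <- function(panel, ld_scores, m_snps = NULL, n = NULL,
                       n_blocks = 200) {
  Z <- if (inherits(panel, "SumstatsPanel")) panel$Z else as.matrix(panel)
  if (length(ld_scores) != nrow(Z))
    stop("ld_scores must align to the panel rows", call. = FALSE)
  if (any(ld_scores <= 0)) stop("ld_scores must be positive", call. = FALSE)
  if (stats::var(ld_scores) == 0)
    stop("constant LD scores: rank-deficient regression design", call. = FALSE)
  K <- ncol(Z)
  m_snps <- m_snps %||% nrow(Z)
  if (is.null(n)) {
    n <- if (inherits(panel, "SumstatsPanel"))
      apply(panel$N, 2, stats::median, na.rm = TRUE)
    else rep(NA_real_, K)
  }
  if (any(is.na(n)))
    stop("per-trait sample sizes required (supply n=)", call. = FALSE)

  n_blocks <- min(n_blocks, nrow(Z) %/% 10L)
  block <- ceiling(seq_len(nrow(Z)) / (nrow(Z) / n_blocks))

  fit_pair <- function(y, x, w, drop_block = 0L) {
    keep <- !is.na(y) & (drop_block == 0L | block != drop_block)
    stats::lm.wfit(cbind(1, x[keep]), y[keep], w[keep])$coefficients
  }

  sigma_r <- sigma_g <- se_r <- se_g <- matrix(0, K, K,
                                               dimnames = list(colnames(Z), colnames(Z)))
  w <- 1 / ld_scores
  for (j in seq_len(K)) for (k in j:K) {
    y <- Z[, j] * Z[, k]
    scale_g <- m_snps / sqrt(n[j] * n[k])
    co <- fit_pair(y, ld_scores, w)
    jack <- vapply(seq_len(n_blocks),
                   function(b) fit_pair(y, ld_scores, w, b), numeric(2))
    jse <- sqrt((n_blocks - 1) / n_blocks *
                  rowSums((jack - rowMeans(jack))^2))
    sigma_r[j, k] <- sigma_r[k, j] <- co[1]
    sigma_g[j, k] <- sigma_g[k, j] <- co[2] * scale_g
    se_r[j, k] <- se_r[k, j] <- jse[1]
    se_g[j, k] <- se_g[k, j] <- jse[2] * scale_g
  }
  if (any(diag(sigma_r) <= 0))
    stop("negative fitted diagonal of sigma_r; check inputs (genomic-control",
         " corrected GWAS can deflate the intercept)", call. = FALSE)
  null_covariance(sigma_r, sigma_g = sigma_g, method = "ldsc",
                  se_r = se_r, se_g = se_g)
}

#' Pseudo-inverse of a (possibly rank-deficient) covariance matrix
#'
#' Eigen-based inversion with three strategies for small or zero eigenvalues:
#' `"truncate"` keeps only eigenvalues greater than `epsilon` (Moore-Penrose
#' on the retained subspace; effective degrees of freedom `K' =` retained
#' count), `"floor"` replaces eigenvalues below `epsilon` by `epsilon`
#' (df = K), `"ridge"` inverts `sigma_r + epsilon * I` (df = K).
#'
#' @param cov a [null_covariance()] or plain symmetric matrix.
#' @param strategy `"truncate"` (default), `"floor"` or `"ridge"`.
#' @param epsilon eigenvalue threshold / ridge (default 1e-6).
#' @return a `PseudoInverse`: list with `inv` (K x K), `df`, `strategy`,
#'   `epsilon`, and the eigen decomposition (`values`, `vectors`).
#' @export
pseudo_inverse <- function(cov, strategy = c("truncate", "floor", "ridge"),
                           epsilon = 1e-6) {
  strategy <- match.arg(strategy)
  stopifnot(epsilon > 0)
  m <- if (inherits(cov, "NullCovariance")) cov$sigma_r else as.matrix(cov)
  check_symmetric(m, 1e-8, "covariance")
  eg <- eigen(symmetrize(m), symmetric = TRUE)
  K <- ncol(m)
  if (strategy == "truncate") {
    keep <- eg$values > epsilon
    if (!any(keep))
      stop("all eigenvalues <= epsilon: covariance is numerically singular",
           call. = FALSE)
    P <- eg$vectors[, keep, drop = FALSE]
    inv <- P %*% (t(P) / eg$values[keep])
    df <- sum(keep)
  } else if (strategy == "floor") {
    vals <- pmax(eg$values, epsilon)
    inv <- eg$vectors %*% (t(eg$vectors) / vals)
    df <- K
  } else {
    inv <- solve(m + epsilon * diag(K))
    df <- K
  }
  structure(list(inv = symmetrize(inv), df = df, strategy = strategy,
                 epsilon = epsilon, values = eg$values, vectors = eg$vectors),
            class = "PseudoInverse")
}
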