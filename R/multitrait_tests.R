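# Omnibus and weighted-sum (sumZ) multitrait association tests on a vector
# of per-trait Z-scores, the four weighting schemes, and the vectorized
# panel scan.
#
# Under the null z ~ N(0, Sigma_r):
#   T_omni = z' Sigma_r^- z           ~ chi^2 with K' df (K' = retained rank)
#   T_sumZ = (w'z)^2 / (w' Sigma_r w) ~ chi^2 with 1 df
# and T_omni decomposes as the sum of T_sumZ over the eigenvectors of
# Sigma_r.

new_test_result <- function(statistic, df, test) {
  p <- stats::pchisq(statistic, df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = df,
                 pvalue = max(p, .Machine$double.xmin), test = test),
            class = "TestResult")
}

#' @export
print.TestResult <- function(x, ...) {
  cat(sprintf("%s test: statistic = %.4g, df = %d, p = %.4g\n",
              x$test, x$statistic, x$df, x$pvalue))
  invisible(x)
}

#' Omnibus multitrait association test
#'
#' Wald statistic `z' Sigma_r^- z` against a chi-square with degrees of
#' freedom equal to the retained rank of the pseudo-inverse. Missing entries
#' are handled by `na_action`: `"error"` (default; imputation is expected
#' upstream) or `"subset"` (test the observed sub-vector against the matching
#' sub-matrix of `Sigma_r`).
#'
#' @param z length-K numeric vector of Z-scores.
#' @param cov a [null_covariance()] (or plain matrix).
#' @param strategy,epsilon pseudo-inverse controls, see [pseudo_inverse()].
#' @param na_action `"error"` or `"subset"`.
#' @return a `TestResult` (statistic, df, pvalue, test tag).
#' @export
omnibus_test <- function(z, cov, strategy = "truncate", epsilon = 1e-6,
                         na_action = c("error", "subset")) {
  na_action <- match.arg(na_action)
  m <- if (inherits(cov, "NullCovariance")) cov$sigma_r else as.matrix(cov)
  obs <- !is.na(z)
  if (!all(obs)) {
    if (na_action == "error")
      stop("z has missing entries; impute upstream or use na_action='subset'",
           call. = FALSE)
    if (!any(obs)) stop("z entirely missing", call. = FALSE)
    z <- z[obs]; m <- m[obs, obs, drop = FALSE]
  }
  pinv <- pseudo_inverse(m, strategy, epsilon)
  new_test_result(drop(t(z) %*% pinv$inv %*% z), pinv$df, "omnibus")
}

#' Weighted-sum (sumZ) multitrait association test
#'
#' `T = (w'z)^2 / (w' Sigma_r w)`, chi-square with 1 df under the null. The
#' statistic is invariant to rescaling `w`.
#'
#' @param z length-K Z-score vector.
#' @param w weight vector (or a `WeightVector` from [make_weights()]).
#' @param cov a [null_covariance()] or matrix.
#' @param na_action `"error"` or `"subset"` (restrict `w`, `z`, `Sigma_r` to
#'   the observed coordinates).
#' @return a `TestResult`.
#' @export
sumz_test <- function(z, w, cov, na_action = c("error", "subset")) {
  na_action <- match.arg(na_action)
  tag <- "sumz"
  if (inherits(w, "WeightVector")) { tag <- paste0("sumz_", w$scheme); w <- w$w }
  m <- if (inherits(cov, "NullCovariance")) cov$sigma_r else as.matrix(cov)
  obs <- !is.na(z)
  if (!all(obs)) {
    if (na_action == "error")
      stop("z has missing entries; impute upstream or use na_action='subset'",
           call. = FALSE)
    z <- z[obs]; w <- w[obs]; m <- m[obs, obs, drop = FALSE]
  }
  denom <- drop(t(w) %*% m %*% w)
  if (!is.finite(denom) || denom <= 0)
    stop("degenerate weights: w' Sigma_r w <= 0", call. = FALSE)
  new_test_result(drop(sum(w * z))^2 / denom, 1L, tag)
}

#' Build sumZ weight vectors
#'
#' Four schemes: `"unit"` (equal weights, fixed-effect-meta flavour),
#' `"pheno_pc1"` (first eigenvector of `Sigma_r`: the dominant axis of
#' phenotypic correlation), `"gene_pc1"` (first eigenvector of `Sigma_g`:
#' dominant axis of genetic correlation), and `"ica"` (loadings of an
#' independent component of the genome-wide Z matrix; the component yielding
#' the most regions significant for its sumZ test but not univariately is
#' selected, ties broken by total significant regions then component index).
#' Eigen/ICA vectors are sign-canonicalized (largest-magnitude loading
#' positive).
#'
#' @param cov a [null_covariance()]; `"gene_pc1"` requires its `sigma_g`.
#' @param panel a [sumstats_panel()] or Z matrix; required for `"ica"`.
#' @param scheme one of `"unit"`, `"pheno_pc1"`, `"gene_pc1"`, `"ica"`.
#' @param regions optional [region_set()] used by the ICA novelty count
#'   (defaults to one region per SNP).
#' @param threshold significance threshold for the ICA novelty count
#'   (default 1e-8).
#' @param max_missing maximum tolerated missing fraction of the Z matrix for
#'   ICA (default 0.2).
#' @param seed RNG seed for ICA initialization.
#' @return a `WeightVector`: list with `w`, `scheme`, and provenance.
#' @export
make_weights <- function(cov, panel = NULL,
                         scheme = c("unit", "pheno_pc1", "gene_pc1", "ica"),
                         regions = NULL, threshold = 1e-8, max_missing = 0.2,
                         seed = 1) {
  scheme <- match.arg(scheme)
  K <- ncol(cov$sigma_r)
  meta <- list()
  if (scheme == "unit") {
    w <- rep(1, K)
  } else if (scheme == "pheno_pc1") {
    eg <- eigen(cov$sigma_r, symmetric = TRUE)
    if ((eg$values[1] - eg$values[2]) < 1e-8 * max(abs(eg$values))) {
      warning("leading eigenvalue of sigma_r is degenerate; ",
              "returning first canonical axis", call. = FALSE)
      w <- c(1, rep(0, K - 1))
    } else w <- canonical_sign(eg$vectors[, 1])
  } else if (scheme == "gene_pc1") {
    if (is.null(cov$sigma_g))
      stop("gene_pc1 weights need sigma_g in the covariance object",
           call. = FALSE)
    eg <- eigen(symmetrize(cov$sigma_g), symmetric = TRUE)
    w <- canonical_sign(eg$vectors[, 1])
  } else {
    if (is.null(panel)) stop("ica weights need the Z panel", call. = FALSE)
    Z <- if (inherits(panel, "SumstatsPanel")) panel$Z else as.matrix(panel)
    if (mean(is.na(Z)) > max_missing)
      stop("ica requires <= ", max_missing * 100,
           "% missing Z after imputation", call. = FALSE)
    ica <- fast_ica(Z, n_comp = K, seed = seed)
    sel <- select_ica_component(Z, ica$weights, cov,
                                if (inherits(panel, "SumstatsPanel"))
                                  panel$snps else NULL,
                                regions, threshold)
    w <- ica$weights[, sel$component]
    meta <- list(component = sel$component, n_novel = sel$n_novel,
                 seed = seed)
  }
  structure(list(w = as.numeric(w), scheme = scheme, meta = meta),
            class = "WeightVector")
}

# Pick the ICA component whose sumZ test yields the most regions significant
# at `threshold` while univariately non-significant ("novel"); ties broken by
# total significant regions, then component index.
select_ica_component <- function(Z, weights, cov, snps = NULL, regions = NULL,
                                 threshold = 1e-8) {
  cc <- stats::complete.cases(Z)
  Zc <- Z[cc, , drop = FALSE]
  p_univ <- apply(p_from_z(Zc), 1, min)
  region_of <- if (!is.null(regions) && !is.null(snps)) {
    assign_regions(snps$chrom[cc], snps$pos[cc], regions)
  } else seq_len(nrow(Zc))
  sr <- cov$sigma_r
  n_novel <- n_sig <- integer(ncol(weights))
  for (i in seq_len(ncol(weights))) {
    w <- weights[, i]
    stat <- drop(Zc %*% w)^2 / drop(t(w) %*% sr %*% w)
    p <- stats::pchisq(stat, 1, lower.tail = FALSE)
    sig_region <- tapply(p, region_of, min) < threshold
    univ_region <- tapply(p_univ, region_of, min) < threshold
    n_sig[i] <- sum(sig_region)
    n_novel[i] <- sum(sig_region & !univ_region)
  }
  ord <- order(-n_novel, -n_sig, seq_along(n_novel))
  list(component = ord[1], n_novel = n_novel[ord[1]], n_sig = n_sig[ord[1]])
}

#' Eigen decomposition of the omnibus statistic into per-eigenvector sumZ
#'
#' Writing `Sigma_r = P D P'`, `T_omni` equals the sum over retained
#' eigenvectors `v_i` of the sumZ statistic with `w = v_i`:
#' `T_omni = sum_i (v_i' z)^2 / lambda_i`.
#'
#' @inheritParams omnibus_test
#' @return list with `components` (per-eigenvector statistics), `total`
#'   (their sum) and `df`.
#' @export
omnibus_eigen_identity <- function(z, cov, strategy = "truncate",
                                   epsilon = 1e-6) {
  m <- if (inherits(cov, "NullCovariance")) cov$sigma_r else as.matrix(cov)
  pinv <- pseudo_inverse(m, strategy, epsilon)
  keep <- if (pinv$strategy == "truncate") pinv$values > epsilon
  else rep(TRUE, length(pinv$values))
  vals <- if (pinv$strategy == "floor") pmax(pinv$values, epsilon)
  else pinv$values
  if (pinv$strategy == "ridge") vals <- pinv$values + epsilon
  comp <- (drop(crossprod(pinv$vectors[, keep, drop = FALSE], z)))^2 /
    vals[keep]
  list(components = comp, total = sum(comp), df = pinv$df)
}

#' Run all multitrait tests across a panel
#'
#' Vectorized per-SNP scan computing, for each requested test, the statistic
#' and p-value. Rows with missing entries are handled by grouping SNPs that
#' share a missingness pattern and testing each observed sub-vector against
#' the matching sub-matrix of `Sigma_r` (`na_action = "subset"`), or skipped
#' (`"complete"`). `univ_min` is the per-SNP minimum univariate p-value.
#'
#' @param panel a [sumstats_panel()] or Z matrix.
#' @param cov a [null_covariance()].
#' @param tests character subset of `c("omnibus", "sumz_1", "sumz_r",
#'   "sumz_g", "sumz_ica", "univ_min")` or `"all"`.
#' @param regions optional [region_set()] for the ICA component selection.
#' @param strategy,epsilon pseudo-inverse controls.
#' @param na_action `"subset"` (default) or `"complete"`.
#' @param seed seed for the ICA weights.
#' @return data.frame with one row per SNP: ids, per-test statistics
#'   (`stat_*`) and p-values (`p_*`). The weight vectors used are attached as
#'   the `"weights"` attribute.
#' @export
multitrait_scan <- function(panel, cov, tests = "all", regions = NULL,
                            strategy = "truncate", epsilon = 1e-6,
                            na_action = c("subset", "complete"), seed = 1) {
  na_action <- match.arg(na_action)
  all_tests <- c("omnibus", "sumz_1", "sumz_r", "sumz_g", "sumz_ica",
                 "univ_min")
  if (identical(tests, "all")) {
    tests <- all_tests
    if (is.null(cov$sigma_g)) {      # no genetic covariance available
      tests <- setdiff(tests, "sumz_g")
      message("sumz_g skipped: covariance object carries no sigma_g")
    }
  }
  tests <- match.arg(tests, all_tests, several.ok = TRUE)
  Z <- if (inherits(panel, "SumstatsPanel")) panel$Z else as.matrix(panel)
  n <- nrow(Z)
  out <- if (inherits(panel, "SumstatsPanel"))
    panel$snps[c("snp_id", "chrom", "pos")]
  else data.frame(snp_id = rownames(Z) %||% as.character(seq_len(n)))

  schemes <- c(sumz_1 = "unit", sumz_r = "pheno_pc1", sumz_g = "gene_pc1",
               sumz_ica = "ica")
  wanted <- intersect(names(schemes), tests)
  weights <- lapply(schemes[wanted], function(s)
    make_weights(cov, panel = panel, scheme = s, regions = regions,
                 seed = seed))
  names(weights) <- wanted

  if ("univ_min" %in% tests) {
    pu <- p_from_z(Z)
    out$p_univ_min <- suppressWarnings(
      apply(pu, 1, min, na.rm = TRUE))
    out$p_univ_min[!is.finite(out$p_univ_min)] <- NA_real_
  }

  pattern <- apply(!is.na(Z), 1, function(o) paste(as.integer(o), collapse = ""))
  sr <- cov$sigma_r
  for (tn in intersect(c("omnibus", wanted), tests)) {
    stat <- rep(NA_real_, n); df <- rep(NA_integer_, n)
    for (pat in unique(pattern)) {
      obs <- as.logical(as.integer(strsplit(pat, "")[[1]]))
      rows <- which(pattern == pat)
      if (!any(obs)) next
      if (na_action == "complete" && !all(obs)) next
      Zo <- Z[rows, obs, drop = FALSE]
      mo <- sr[obs, obs, drop = FALSE]
      if (tn == "omnibus") {
        pinv <- tryCatch(pseudo_inverse(mo, strategy, epsilon),
                         error = function(e) NULL)
        if (is.null(pinv)) next
        stat[rows] <- rowSums((Zo %*% pinv$inv) * Zo)
        df[rows] <- pinv$df
      } else {
        w <- weights[[tn]]$w[obs]
        denom <- drop(t(w) %*% mo %*% w)
        if (denom <= 0) next
        stat[rows] <- drop(Zo %*% w)^2 / denom
        df[rows] <- 1L
      }
    }
    out[[paste0("stat_", tn)]] <- stat
    out[[paste0("df_", tn)]] <- df
    out[[paste0("p_", tn)]] <- stats::pchisq(stat, df, lower.tail = FALSE)
  }
  attr(out, "weights") <- weights
  out
}
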