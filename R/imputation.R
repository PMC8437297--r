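# Conditional-mean imputation of missing Z-scores from local LD, and the
# post-imputation neighborhood QC filter.
#
# Within an LD block, the vector of Z-scores is approximately
# N(mu, R) with R the SNP correlation matrix; the best linear predictor of a
# missing Z given the observed ones is
#   z_t = R[t, obs] (R[obs, obs] + lambda I)^-1 z_obs
# with imputation quality
#   q_t = R[t, obs] (R[obs, obs] + lambda I)^-1 R[obs, t]
# (the fraction of variance of z_t explained by the observed panel).

#' Impute missing Z-scores within one LD region
#'
#' @param z_obs named numeric vector of observed Z-scores; names must be SNP
#'   ids present in `ld`.
#' @param ld region correlation matrix (unit diagonal, SNP ids as dimnames).
#' @param lambda ridge regularization added to the observed-observed block
#'   (default 0.1).
#' @param quality_threshold minimum imputation quality; imputed values below
#'   it are reported but flagged not retained (default 0.6).
#' @return data.frame over the region's missing SNPs: `snp_id`, `z_imp`,
#'   `quality`, `retained`.
#' @export
impute_region <- function(z_obs, ld, lambda = 0.1, quality_threshold = 0.6) {
  all_ids <- rownames(ld)
  if (is.null(names(z_obs)) || !all(names(z_obs) %in% all_ids))
    stop("z_obs must be named by SNP ids present in the LD matrix",
         call. = FALSE)
  miss_ids <- setdiff(all_ids, names(z_obs))
  if (!length(miss_ids))
    return(data.frame(snp_id = character(), z_imp = numeric(),
                      quality = numeric(), retained = logical()))
  if (!length(z_obs)) {
    warning("region has no observed SNPs; nothing imputed", call. = FALSE)
    return(data.frame(snp_id = miss_ids, z_imp = NA_real_,
                      quality = NA_real_, retained = FALSE))
  }
  obs <- names(z_obs)
  A <- ld[obs, obs, drop = FALSE] + lambda * diag(length(obs))
  B <- ld[miss_ids, obs, drop = FALSE]        # cross-correlations
  W <- B %*% solve(A)                          # predictor weights
  z_imp <- drop(W %*% z_obs)
  quality <- rowSums(W * B)
  data.frame(snp_id = miss_ids, z_imp = z_imp, quality = quality,
             retained = quality >= quality_threshold, row.names = NULL)
}

#' Impute a panel's missing Z-scores per trait and region
#'
#' Applies [impute_region()] trait by trait within each LD block of the
#' panel; observed entries are never altered; imputed entries are flagged in
#' `imputed`. Entries whose imputation quality falls below the threshold stay
#' missing.
#'
#' @param panel a [sumstats_panel()].
#' @param ld an [ld_panel()] whose SNP ids cover the panel.
#' @param lambda,quality_threshold see [impute_region()].
#' @return the panel with imputed Z entries and updated `imputed` mask; the
#'   imputation qualities are attached as the `"quality"` attribute
#'   (SNP x trait matrix, `NA` where nothing was imputed).
#' @export
impute_panel <- function(panel, ld, lambda = 0.1, quality_threshold = 0.6) {
  qual <- matrix(NA_real_, nrow(panel$Z), ncol(panel$Z),
                 dimnames = dimnames(panel$Z))
  for (r in seq_along(ld$matrices)) {
    R <- ld$matrices[[r]]
    ids <- intersect(rownames(R), panel$snps$snp_id)
    if (length(ids) < 2) next
    Rr <- R[ids, ids, drop = FALSE]
    rows <- match(ids, panel$snps$snp_id)
    for (k in seq_along(panel$traits)) {
      z <- panel$Z[rows, k]
      names(z) <- ids
      obs <- !is.na(z)
      if (!any(obs) || all(obs)) next
      imp <- impute_region(z[obs], Rr, lambda, quality_threshold)
      tgt <- rows[match(imp$snp_id, ids)]
      qual[tgt, k] <- imp$quality
      keep <- imp$retained
      panel$Z[tgt[keep], k] <- imp$z_imp[keep]
      panel$imputed[tgt[keep], k] <- TRUE
      # sample size of imputed entries: trait median of observed n
      nk <- stats::median(panel$N[rows, k], na.rm = TRUE)
      panel$N[tgt[keep], k] <- ifelse(is.na(panel$N[tgt[keep], k]), nk,
                                      panel$N[tgt[keep], k])
    }
  }
  attr(panel, "quality") <- qual
  panel
}

#' Post-imputation neighborhood quality filter
#'
#' A genome-wide-significant SNP is retained only if at least one distinct
#' SNP in LD with it (`r^2 >= r2_neighbor`, within the same LD block) is
#' significant or near-significant (`p < p_neighbor`). Isolated significant
#' SNPs — a signature of imputation artifacts — are flagged and removed.
#'
#' @param results data.frame with `snp_id` and a p-value column `p`.
#' @param ld an [ld_panel()].
#' @param p_col name of the p-value column (default `"p"`).
#' @param p_sig significance threshold defining which SNPs are screened
#'   (default 1e-8).
#' @param p_neighbor neighbor p-value cutoff (default 1e-6).
#' @param r2_neighbor minimum squared correlation defining a neighbor
#'   (default 0.2).
#' @return `results` with a logical `qc_pass` column (non-significant SNPs
#'   pass trivially).
#' @export
post_imputation_qc <- function(results, ld, p_col = "p", p_sig = 1e-8,
                               p_neighbor = 1e-6, r2_neighbor = 0.2) {
  p <- results[[p_col]]
  if (is.null(p)) stop("no column '", p_col, "' in results", call. = FALSE)
  pass <- rep(TRUE, nrow(results))
  sig <- which(!is.na(p) & p < p_sig)
  if (!length(sig)) { results$qc_pass <- pass; return(results) }
  for (r in seq_along(ld$matrices)) {
    R2 <- ld$matrices[[r]]^2
    ids <- rownames(R2)
    here <- sig[results$snp_id[sig] %in% ids]
    for (i in here) {
      j <- match(results$snp_id[i], ids)
      nb_ids <- ids[R2[j, ] >= r2_neighbor & seq_along(ids) != j]
      nb_p <- p[match(nb_ids, results$snp_id)]
      pass[i] <- any(!is.na(nb_p) & nb_p < p_neighbor)
    }
  }
  results$qc_pass <- pass
  results
}
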