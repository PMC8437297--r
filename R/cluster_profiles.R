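# Per-cluster genetic covariance/correlation with sample-overlap bias
# correction, the allele-coding-free first principal component, allele
# alignment, disease sign tests and the variance-explained decomposition.

#' Per-cluster genetic covariance between two traits, overlap-corrected
#'
#' With standardized effects `bhat = z / sqrt(N)`, the cross-product
#' `bhat_j1 * bhat_j2` of a null SNP has expectation
#' `ns * rho_Y / (n1 * n2)` under sample overlap; each SNP's bias-corrected
#' contribution to the cluster genetic covariance is therefore
#' `X_j = bhat_j1 * bhat_j2 - ns * rho_Y / (n1 * n2)`, and the cluster
#' estimate is `mean(X_j)` over the cluster's M independent SNPs (thin by LD
#' clumping first). Significance is a one-sample two-sided t-test of
#' `mean(X_j) = 0`. The genetic correlation divides by the bias-corrected
#' per-trait deviations `v_l = mean(bhat_l^2 - 1/n_l)` (sampling variance of
#' `bhat` is `1/n`); it is reported missing when either `v_l <= 0`.
#'
#' @param beta1,beta2 standardized effect vectors (`z/sqrt(N)`) over the
#'   cluster's SNPs (length M >= 5).
#' @param n1,n2 per-trait GWAS sample sizes.
#' @param ns overlapping sample count.
#' @param rho_y phenotypic covariance among the overlapping samples.
#' @return list: `covariance`, `correlation` (possibly `NA`), `t`, `df`,
#'   `pvalue`, `m` and the per-SNP contributions `x`.
#' @export
cluster_genetic_covariance <- function(beta1, beta2, n1, n2, ns = 0,
                                       rho_y = 0) {
  stopifnot(length(beta1) == length(beta2))
  keep <- !is.na(beta1) & !is.na(beta2)
  b1 <- beta1[keep]; b2 <- beta2[keep]
  M <- length(b1)
  if (M < 5) stop("need at least 5 SNPs per cluster and trait pair",
                  call. = FALSE)
  bias <- ns * rho_y / (n1 * n2)
  x <- b1 * b2 - bias
  tt <- stats::t.test(x)
  v1 <- mean(b1^2 - 1 / n1)
  v2 <- mean(b2^2 - 1 / n2)
  corr <- if (v1 > 0 && v2 > 0) mean(x) / sqrt(v1 * v2) else NA_real_
  list(covariance = mean(x), correlation = corr,
       t = unname(tt$statistic), df = unname(tt$parameter),
       pvalue = tt$p.value, m = M, x = x)
}

#' All pairwise per-cluster genetic correlations with Bonferroni flags
#'
#' Applies [cluster_genetic_covariance()] to every trait pair within every
#' cluster; the Bonferroni correction is across (pairs x clusters).
#'
#' @param B SNP x trait matrix of standardized effects (`z/sqrt(N)`).
#' @param assignment per-SNP cluster labels aligned to `B` rows.
#' @param n per-trait sample sizes (length K).
#' @param ns K x K matrix (or scalar) of pairwise overlap counts.
#' @param rho_y K x K matrix (or scalar) of pairwise phenotypic covariances.
#' @param min_snps clusters with fewer SNPs are skipped (default 5).
#' @return data.frame: `cluster`, `trait1`, `trait2`, `covariance`,
#'   `correlation`, `t`, `pvalue`, `significant` (Bonferroni at 0.05).
#' @export
cluster_correlation_table <- function(B, assignment, n, ns = 0, rho_y = 0,
                                      min_snps = 5) {
  K <- ncol(B)
  traits <- colnames(B) %||% paste0("trait", seq_len(K))
  if (length(ns) == 1) ns <- matrix(ns, K, K)
  if (length(rho_y) == 1) rho_y <- matrix(rho_y, K, K)
  rows <- list()
  for (cl in sort(unique(assignment))) {
    sel <- which(assignment == cl)
    if (length(sel) < min_snps) next
    for (j in seq_len(K - 1)) for (l in (j + 1):K) {
      res <- tryCatch(
        cluster_genetic_covariance(B[sel, j], B[sel, l], n[j], n[l],
                                   ns[j, l], rho_y[j, l]),
        error = function(e) NULL)
      if (is.null(res)) next
      rows[[length(rows) + 1L]] <- data.frame(
        cluster = cl, trait1 = traits[j], trait2 = traits[l],
        covariance = res$covariance, correlation = res$correlation,
        t = res$t, pvalue = res$pvalue, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(NULL)
  out$significant <- out$pvalue < 0.05 / nrow(out)
  rownames(out) <- NULL
  out
}

#' Allele-coding-free first principal component of a cluster
#'
#' The sign of each SNP's profile depends on the arbitrary choice of coded
#' allele. To obtain a PC1 free of that choice, the per-SNP signs are
#' randomly flipped `n_shuffles` times; after each shuffle a centered PCA is
#' run and its PC1 is sign-aligned to the first replicate (maximal dot
#' product). The averaged, renormalized loadings and the mean fraction of
#' variance explained by PC1 are returned.
#'
#' @param Z cluster SNP x trait matrix of scaled effects (`z/sqrt(N)`); needs
#'   at least as many SNPs as traits.
#' @param n_shuffles number of random sign shuffles (default 20).
#' @param seed RNG seed.
#' @return list: `loadings` (length K, unit norm), `var_explained` (mean PC1
#'   share), `var_explained_reps`.
#' @export
cluster_pc1 <- function(Z, n_shuffles = 20, seed = 1) {
  Z <- as.matrix(Z)
  if (nrow(Z) < ncol(Z))
    stop("cluster needs at least as many SNPs as traits", call. = FALSE)
  if (all(abs(Z) < .Machine$double.eps))
    stop("degenerate (zero-variance) matrix", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ref <- NULL
  loads <- matrix(0, ncol(Z), n_shuffles)
  ve <- numeric(n_shuffles)
  for (s in seq_len(n_shuffles)) {
    flip <- sample(c(-1, 1), nrow(Z), replace = TRUE)
    pc <- stats::prcomp(Z * flip, center = TRUE, scale. = FALSE)
    v <- pc$rotation[, 1]
    if (is.null(ref)) ref <- v
    if (sum(v * ref) < 0) v <- -v
    loads[, s] <- v
    ve[s] <- pc$sdev[1]^2 / sum(pc$sdev^2)
  }
  w <- rowMeans(loads)
  w <- w / sqrt(sum(w^2))
  names(w) <- colnames(Z)
  list(loadings = w, var_explained = mean(ve), var_explained_reps = ve)
}

#' Align a SNP profile's coded allele to a cluster's PC1
#'
#' Flips the profile's sign iff its dot product with the PC1 loadings is
#' negative; an exactly orthogonal profile is left unflipped (logged
#' convention). Applying the alignment twice equals applying it once.
#'
#' @param profile length-K numeric profile (missing entries ignored in the
#'   dot product).
#' @param pc1 PC1 loading vector.
#' @return the possibly sign-flipped profile, with attribute `flipped`.
#' @export
align_alleles_to_pc1 <- function(profile, pc1) {
  d <- sum(profile * pc1, na.rm = TRUE)
  flipped <- d < 0
  out <- if (flipped) -profile else profile
  attr(out, "flipped") <- flipped
  out
}

#' Sign test of effect-direction concordance with a disease
#'
#' After aligning the cluster's SNP profiles to its PC1, tests whether the
#' disease Z-scores of the cluster's independent SNPs (thin at a strict
#' clumping r^2, e.g. 0.05, first) share a direction more often than chance:
#' an exact two-sided binomial test of #positive vs #negative at p = 0.5.
#' Zero Z-scores are excluded.
#'
#' @param z aligned disease Z-scores over the cluster's independent SNPs.
#' @return list: `n_pos`, `n_neg`, `direction` (`"positive"`, `"negative"`
#'   or `"balanced"`), `pvalue`.
#' @export
disease_sign_test <- function(z) {
  z <- z[!is.na(z) & z != 0]
  n <- length(z)
  if (n < 5) stop("need at least 5 nonzero signs", call. = FALSE)
  npos <- sum(z > 0)
  bt <- stats::binom.test(npos, n, p = 0.5, alternative = "two.sided")
  list(n_pos = npos, n_neg = n - npos,
       direction = if (npos * 2 == n) "balanced"
       else if (npos * 2 > n) "positive" else "negative",
       pvalue = bt$p.value)
}

#' Cluster x trait variance-explained shares
#'
#' Each SNP's contribution to a trait's explained variance is `z^2 / n`
#' (the squared standardized effect); shares are normalized per trait over
#' all selected SNPs, so each trait's shares sum to 1 over clusters. Shares
#' below `flag_below` are flagged (display cutoff for alluvial plots).
#'
#' @param Z SNP x trait Z-score matrix for the selected SNPs.
#' @param N matching sample-size matrix.
#' @param assignment per-SNP cluster labels.
#' @param flag_below flag threshold (default 0.001).
#' @return list: `shares` (cluster x trait), `flagged` (logical, same
#'   shape).
#' @export
variance_explained_matrix <- function(Z, N, assignment, flag_below = 0.001) {
  contrib <- Z^2 / N
  contrib[is.na(contrib)] <- 0
  clusters <- sort(unique(assignment))
  shares <- t(vapply(clusters, function(cl)
    colSums(contrib[assignment == cl, , drop = FALSE]),
    numeric(ncol(Z))))
  tot <- colSums(shares)
  shares <- sweep(shares, 2, ifelse(tot > 0, tot, 1), `/`)
  dimnames(shares) <- list(paste0("cluster", clusters),
                           colnames(Z) %||% paste0("trait", seq_len(ncol(Z))))
  list(shares = shares, flagged = shares < flag_below)
}
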