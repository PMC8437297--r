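# Preprocessing of per-trait summary statistics: Z-score derivation from
# p-values and signed effects, sample-size inference from standard errors and
# allele frequencies, and the low-sample-size filter.

#' Derive Z-scores from p-values and signed effects
#'
#' For each row with a two-sided p-value and a sign source (the sign of
#' `beta`), sets `z = sign(beta) * qnorm(1 - p/2)`. Rows with an existing `z`
#' are preserved unless `overwrite = TRUE`; rows with no sign source keep `z`
#' missing. When both `z` and `beta/se` are present but inconsistent
#' (`|z - beta/se| > 0.1`), the p-derived value wins and the conflict is
#' warned about: the p-value is the canonical source.
#'
#' @param table a [sumstats_table()].
#' @param overwrite recompute `z` even where already present.
#' @param p_floor p-values below this are clamped before the quantile
#'   transform (guards against `p = 0` giving infinite Z); default `1e-300`.
#' @return the table with a filled `z` column.
#' @export
derive_z <- function(table, overwrite = FALSE, p_floor = 1e-300) {
  p <- table$pvalue
  sgn <- sign(table$beta)
  floored <- !is.na(p) & p < p_floor
  if (any(floored)) {
    warning(sum(floored), " p-values at or below 0 clamped to ", p_floor,
            call. = FALSE)
    p[floored] <- p_floor
  }
  q <- stats::qnorm(p / 2, lower.tail = FALSE)
  z_new <- sgn * q
  # p = 1 pins z at 0 whatever the (possibly absent) sign source
  z_new[is.na(z_new) & !is.na(q) & q == 0] <- 0

  have_both <- !is.na(table$z) & !is.na(table$beta) & !is.na(table$se)
  conflict <- have_both & abs(table$z - table$beta / table$se) > 0.1 &
    !is.na(z_new)
  if (any(conflict)) {
    warning(sum(conflict),
            " rows where z disagrees with beta/se; p-derived z used",
            call. = FALSE)
    table$z[conflict] <- z_new[conflict]
  }
  fill <- if (overwrite) !is.na(z_new) else is.na(table$z) & !is.na(z_new)
  table$z[fill] <- z_new[fill]
  table
}

#' Infer missing sample sizes from standard errors
#'
#' Estimates a per-SNP sample-size proxy `n_hat = 1 / (se^2 * 2 f (1 - f))`,
#' where `2 f (1 - f)` is the genotype variance at coded-allele frequency `f`.
#' For a linear model on a standardized outcome this targets `N * sigma_e^2`;
#' for a logistic model it is proportional to `N p (1 - p)` with `p` the case
#' fraction. Rows with an observed `n` are untouched.
#'
#' @param table a [sumstats_table()] with `se` filled.
#' @param freq_source optional per-SNP frequencies (named by snp id or aligned
#'   to the table) used where the table's `freq` is missing.
#' @return the table with `n` filled where inferable and a logical
#'   `n_inferred` column.
#' @export
infer_sample_size <- function(table, freq_source = NULL) {
  f <- table$freq
  if (!is.null(freq_source)) {
    ext <- if (!is.null(names(freq_source)))
      unname(freq_source[table$snp_id]) else freq_source
    f[is.na(f)] <- ext[is.na(f)]
  }
  f[!is.na(f) & (f <= 0 | f >= 1)] <- NA_real_
  n_hat <- 1 / (table$se^2 * 2 * f * (1 - f))
  fill <- is.na(table$n) & !is.na(n_hat)
  table$n_inferred <- fill
  table$n[fill] <- n_hat[fill]
  table
}

#' Mask SNPs whose sample size falls below a fraction of the trait maximum
#'
#' Per trait, panel entries with `n < fraction * n_max` are set missing, where
#' `n_max` is by default the 99.9th percentile of the trait's non-missing
#' sample sizes (robust to single-row typos; set `robust = FALSE` for the
#' literal maximum). Entries with missing `n` are left alone.
#'
#' @param panel a [sumstats_panel()] with `N` filled.
#' @param fraction retention threshold as a fraction of the per-trait maximum
#'   (default 0.70).
#' @param robust use the 99.9th percentile instead of the maximum.
#' @return the filtered panel.
#' @export
filter_low_n <- function(panel, fraction = 0.70, robust = TRUE) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must be in (0, 1]", call. = FALSE)
  for (k in seq_along(panel$traits)) {
    n <- panel$N[, k]
    if (all(is.na(n))) next
    n_max <- if (robust) stats::quantile(n, 0.999, na.rm = TRUE, names = FALSE)
    else max(n, na.rm = TRUE)
    drop <- !is.na(n) & n < fraction * n_max
    panel$Z[drop, k] <- NA_real_
    panel$N[drop, k] <- NA_real_
    panel$imputed[drop, k] <- FALSE
  }
  panel
}
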