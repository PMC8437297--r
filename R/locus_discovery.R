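# Region-level signal extraction, greedy LD clumping, novelty
# classification, and the SNP selection feeding the clustering.

#' Per-region minimum p-values
#'
#' For each LD-block region, extracts the minimum multitrait p-value and the
#' minimum univariate p-value (minimum across traits then SNPs) over the
#' SNPs it contains. Regions containing no SNP are absent from the output.
#'
#' @param results data.frame with `snp_id`, `chrom`, `pos`, a multitrait
#'   p-value column `p_joint` and a univariate column `p_univ_min`.
#' @param regions a [region_set()].
#' @param joint_col,univ_col column names (defaults `"p_joint"`,
#'   `"p_univ_min"`).
#' @return data.frame: `region_id`, `chrom`, `start`, `end`, `n_snps`,
#'   `min_p_joint`, `min_p_univ`.
#' @export
region_minp <- function(results, regions, joint_col = "p_joint",
                        univ_col = "p_univ_min") {
  idx <- assign_regions(results$chrom, results$pos, regions)
  if (anyNA(idx))
    stop("SNPs outside all regions: ",
         paste(utils::head(results$snp_id[is.na(idx)], 5), collapse = ", "),
         call. = FALSE)
  safe_min <- function(x) if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  used <- sort(unique(idx))
  out <- data.frame(
    region_id = regions$region_id[used],
    chrom = regions$chrom[used],
    start = regions$start[used],
    end = regions$end[used],
    n_snps = as.integer(tabulate(idx)[used]),
    min_p_joint = vapply(used, function(r)
      safe_min(results[[joint_col]][idx == r]), 0),
    min_p_univ = vapply(used, function(r)
      safe_min(results[[univ_col]][idx == r]), 0),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Classify regions by multitrait vs univariate significance
#'
#' A region is a new multitrait association when its joint p-value is
#' genome-wide significant while its univariate p-value is not.
#'
#' @param minima output of [region_minp()].
#' @param joint_threshold,univ_threshold significance thresholds
#'   (default 1e-8 each).
#' @return `minima` with a `novelty` factor in `multitrait_only`,
#'   `univariate_only`, `both`, `neither`.
#' @export
classify_novel <- function(minima, joint_threshold = 1e-8,
                           univ_threshold = 1e-8) {
  j <- !is.na(minima$min_p_joint) & minima$min_p_joint < joint_threshold
  u <- !is.na(minima$min_p_univ) & minima$min_p_univ < univ_threshold
  minima$novelty <- factor(
    ifelse(j & u, "both",
           ifelse(j, "multitrait_only",
                  ifelse(u, "univariate_only", "neither"))),
    levels = c("multitrait_only", "univariate_only", "both", "neither"))
  minima
}

# Squared correlation between two SNPs under the block LD model:
# within-region entries come from the LD panel, cross-region LD is 0.
ld_r2_lookup <- function(ld) {
  env <- new.env(parent = emptyenv())
  for (r in seq_along(ld$matrices)) {
    ids <- rownames(ld$matrices[[r]])
    for (id in ids) assign(id, r, envir = env)
  }
  list(region_of = function(id) {
    if (exists(id, envir = env, inherits = FALSE))
      get(id, envir = env) else NA_integer_
  }, matrices = ld$matrices)
}

#' Greedy LD clumping of significant SNPs
#'
#' PLINK-style clumping: repeatedly take the smallest-p unabsorbed SNP with
#' `p < p1` as a lead and absorb every SNP with `r^2 >=` `r2` to it
#' (cross-region LD treated as 0). Ties on p are broken by genomic position,
#' then id.
#'
#' @param results data.frame with `snp_id`, `chrom`, `pos` and a p-value
#'   column `p`.
#' @param ld an [ld_panel()].
#' @param p1 lead significance threshold (default 1e-8).
#' @param r2 absorption threshold on squared correlation (default 0.2).
#' @param p_col p-value column name (default `"p"`).
#' @return data.frame of leads in selection order: `snp_id`, `chrom`, `pos`,
#'   `p`, `n_members`, `members` (comma-separated ids, lead included).
#' @export
clump <- function(results, ld, p1 = 1e-8, r2 = 0.2, p_col = "p") {
  p <- results[[p_col]]
  cand <- which(!is.na(p) & p < p1)
  ord <- cand[order(p[cand], results$pos[cand], results$snp_id[cand])]
  lookup <- ld_r2_lookup(ld)
  absorbed <- rep(FALSE, nrow(results))
  leads <- integer(0); members <- list()
  for (i in ord) {
    if (absorbed[i]) next
    leads <- c(leads, i)
    reg <- lookup$region_of(results$snp_id[i])
    mem <- results$snp_id[i]
    if (!is.na(reg)) {
      R2 <- lookup$matrices[[reg]]^2
      ids <- rownames(R2)
      linked <- ids[R2[match(results$snp_id[i], ids), ] >= r2]
      hit <- which(results$snp_id %in% linked)
      mem <- results$snp_id[intersect(hit, which(!absorbed | seq_len(nrow(results)) == i))]
      absorbed[hit] <- TRUE
    }
    absorbed[i] <- TRUE
    members[[length(members) + 1L]] <- mem
  }
  data.frame(snp_id = results$snp_id[leads],
             chrom = results$chrom[leads],
             pos = results$pos[leads],
             p = p[leads],
             n_members = lengths(members),
             members = vapply(members, paste, "", collapse = ","),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select independent SNPs for multitrait-profile clustering
#'
#' Takes the union of SNPs significant at `p1` for any of the three tracks
#' (minimum univariate, ICA sumZ, omnibus), clumps them at (`p1`, `r2`), and
#' within each clump picks as representative the SNP with the smallest
#' p-value across the three tests among those with at least `min_observed`
#' of their Z-profile observed. Clumps with no sufficiently observed member
#' are dropped with a warning.
#'
#' @param results data.frame with `snp_id`, `chrom`, `pos`, `p_univ_min`,
#'   `p_sumz_ica`, `p_omnibus`.
#' @param completeness per-SNP observed fraction of the Z profile, aligned to
#'   `results`.
#' @param ld an [ld_panel()].
#' @param p1,r2 clumping parameters (defaults 1e-8, 0.2).
#' @param min_observed minimum observed fraction for a representative
#'   (default 0.6).
#' @return data.frame of representative SNPs: `snp_id`, `chrom`, `pos`,
#'   `p_best`, `completeness`.
#' @export
select_cluster_snps <- function(results, completeness, ld, p1 = 1e-8,
                                r2 = 0.2, min_observed = 0.6) {
  tracks <- c("p_univ_min", "p_sumz_ica", "p_omnibus")
  missing_cols <- setdiff(tracks, names(results))
  if (length(missing_cols))
    stop("results lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  pmat <- as.matrix(results[tracks])
  p_best <- suppressWarnings(apply(pmat, 1, min, na.rm = TRUE))
  p_best[!is.finite(p_best)] <- NA_real_
  sel <- !is.na(p_best) & p_best < p1
  if (!any(sel)) return(data.frame(snp_id = character(), chrom = character(),
                                   pos = integer(), p_best = numeric(),
                                   completeness = numeric()))
  sub <- results[sel, c("snp_id", "chrom", "pos")]
  sub$p <- p_best[sel]
  sub$completeness <- completeness[sel]
  cl <- clump(sub, ld, p1 = p1, r2 = r2)
  reps <- lapply(seq_len(nrow(cl)), function(i) {
    mem <- strsplit(cl$members[i], ",")[[1]]
    cand <- sub[sub$snp_id %in% mem & sub$completeness >= min_observed, ]
    if (!nrow(cand)) return(NULL)
    cand[order(cand$p, cand$pos, cand$snp_id)[1], ]
  })
  dropped <- sum(vapply(reps, is.null, TRUE))
  if (dropped)
    warning(dropped, " clump(s) dropped: no member with >= ",
            min_observed * 100, "% observed values", call. = FALSE)
  out <- do.call(rbind, reps[!vapply(reps, is.null, TRUE)])
  if (is.null(out)) return(data.frame(snp_id = character(), chrom = character(),
                                      pos = integer(), p_best = numeric(),
                                      completeness = numeric()))
  names(out)[names(out) == "p"] <- "p_best"
  rownames(out) <- NULL
  out
}
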