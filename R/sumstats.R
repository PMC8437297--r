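# Domain types and I/O for per-trait GWAS summary statistics, the aligned
# multitrait Z-score panel, LD reference panels and LD-block region sets.

VALID_ALLELES <- c("A", "C", "G", "T")

#' Construct and validate a summary-statistics table
#'
#' A `SumstatsTable` holds one trait's per-SNP association summary: identifier,
#' genomic position, coded/other alleles, and any of the signed Z-score, the
#' effect estimate with its standard error, the p-value, the sample size and
#' the coded-allele frequency. Missing values are `NA`, never sentinels.
#'
#' @param df data.frame with columns `snp_id`, `chrom`, `pos`, `coded_allele`,
#'   `other_allele` and optionally `z`, `beta`, `se`, `pvalue`, `n`, `freq`.
#' @param drop_invalid drop (rather than error on) rows with unparseable
#'   required fields, duplicated ids, or invalid alleles.
#' @return a `SumstatsTable` (data.frame subclass) with a `log` attribute
#'   counting dropped rows.
#' @export
sumstats_table <- function(df, drop_invalid = TRUE) {
  required <- c("snp_id", "chrom", "pos", "coded_allele", "other_allele")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("missing required columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  optional <- c("z", "beta", "se", "pvalue", "n", "freq")
  for (col in optional) if (!col %in% names(df)) df[[col]] <- NA_real_
  df <- df[c(required, optional)]
  df$snp_id <- as.character(df$snp_id)
  df$chrom <- as.character(df$chrom)
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$coded_allele <- toupper(as.character(df$coded_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  for (col in optional) df[[col]] <- suppressWarnings(as.numeric(df[[col]]))

  log <- list(n_input = nrow(df))
  bad <- is.na(df$snp_id) | is.na(df$chrom) | is.na(df$pos) | df$pos <= 0 |
    !(df$coded_allele %in% VALID_ALLELES) |
    !(df$other_allele %in% VALID_ALLELES) |
    df$coded_allele == df$other_allele
  bad[is.na(bad)] <- TRUE
  if (any(bad) && !drop_invalid)
    stop(sum(bad), " rows with unparseable required fields", call. = FALSE)
  log$n_dropped_invalid <- sum(bad)
  df <- df[!bad, , drop = FALSE]

  dup <- duplicated(df$snp_id)
  if (any(dup)) {
    warning(sum(dup), " duplicated snp_id rows dropped", call. = FALSE)
  }
  log$n_dropped_duplicate <- sum(dup)
  df <- df[!dup, , drop = FALSE]
  if (nrow(df) == 0) stop("no valid rows in summary statistics", call. = FALSE)

  # range checks on optional numeric fields -> value set missing, row kept
  # p = 0 is kept: derive_z() clamps it to the p floor
  df$pvalue[!is.na(df$pvalue) & (df$pvalue < 0 | df$pvalue > 1)] <- NA_real_
  df$se[!is.na(df$se) & df$se <= 0] <- NA_real_
  df$n[!is.na(df$n) & df$n <= 0] <- NA_real_
  df$freq[!is.na(df$freq) & (df$freq <= 0 | df$freq >= 1)] <- NA_real_

  ok <- !is.na(df$z) & !is.na(df$beta)
  if (any(sign(df$z[ok]) * sign(df$beta[ok]) < 0))
    warning("z and beta disagree in sign for some rows", call. = FALSE)

  rownames(df) <- NULL
  structure(df, class = c("SumstatsTable", "data.frame"), log = log)
}

#' Read a summary-statistics file
#'
#' Reads a headered, tab- or whitespace-delimited per-trait GWAS file and
#' returns a validated [sumstats_table()]. Rows whose required fields fail to
#' parse are dropped and counted in the `log` attribute.
#'
#' @param path file path.
#' @param column_map named character vector mapping canonical names
#'   (`snp_id`, `chrom`, `pos`, `coded_allele`, `other_allele`, `z`, `beta`,
#'   `se`, `pvalue`, `n`, `freq`) to the file's column names. Canonical names
#'   already present in the file need not be mapped.
#' @return a `SumstatsTable`.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", "NaN", "nan", ""),
                           comment.char = "")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      src <- column_map[[canon]]
      if (!src %in% names(raw))
        stop("column '", src, "' (mapped to ", canon, ") not in file",
             call. = FALSE)
      names(raw)[names(raw) == src] <- canon
    }
  }
  sumstats_table(raw)
}

#' Write a summary-statistics table
#'
#' Full-precision tab-delimited writer; round-trips through [read_sumstats()].
#' @param table a `SumstatsTable`.
#' @param path output path.
#' @export
write_sumstats <- function(table, path) write_tsv_plain(table, path)

#' Construct a set of LD-block regions
#'
#' Regions are half-open `[start, end)` intervals of 1-based positions;
#' within a chromosome they must be sorted and non-overlapping.
#'
#' @param chrom,start,end vectors defining the blocks.
#' @return a `RegionSet` data.frame with a `region_id` column.
#' @export
region_set <- function(chrom, start, end) {
  df <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                   end = as.integer(end), stringsAsFactors = FALSE)
  if (any(df$end <= df$start)) stop("regions must have end > start", call. = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, ]
    if (nrow(sub) > 1 && any(sub$start[-1] < sub$end[-nrow(sub)]))
      stop("overlapping regions on chromosome ", ch, call. = FALSE)
  }
  df$region_id <- paste0(df$chrom, ":", df$start, "-", df$end)
  rownames(df) <- NULL
  structure(df, class = c("RegionSet", "data.frame"))
}

#' Read / write a BED-like region file
#'
#' Three-column tab-delimited (`chrom`, `start`, `end`), half-open intervals.
#' @param path file path.
#' @return a `RegionSet`.
#' @export
read_regions <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  region_set(df$chrom, df$start, df$end)
}

#' @rdname read_regions
#' @param regions a `RegionSet`.
#' @export
write_regions <- function(regions, path) {
  write_tsv_plain(as.data.frame(regions)[c("chrom", "start", "end")], path)
}

#' Assign SNPs to LD-block regions
#'
#' @param chrom,pos SNP coordinates (1-based).
#' @param regions a [region_set()].
#' @return integer vector of row indices into `regions` (`NA` when a SNP
#'   falls in no region).
#' @export
assign_regions <- function(chrom, pos, regions) {
  idx <- rep(NA_integer_, length(pos))
  for (ch in unique(chrom)) {
    sub <- which(regions$chrom == ch)
    if (!length(sub)) next
    sel <- which(chrom == ch)
    j <- findInterval(pos[sel], regions$start[sub])
    hit <- j >= 1 & pos[sel] < regions$end[sub][pmax(j, 1)]
    idx[sel[hit]] <- sub[j[hit]]
  }
  idx
}

#' Construct an LD panel
#'
#' Per-region SNP correlation matrices keyed to a [region_set()]. Each matrix
#' must be symmetric with unit diagonal and (numerically) positive
#' semi-definite; its row names are SNP ids.
#'
#' @param regions a `RegionSet`.
#' @param matrices list (one per region) of correlation matrices with SNP ids
#'   as dimnames.
#' @param snp_info optional data.frame (`snp_id`, `chrom`, `pos`,
#'   `coded_allele`, `other_allele`) describing the panel's SNPs; used as the
#'   harmonization reference.
#' @return an `LDPanel`.
#' @export
ld_panel <- function(regions, matrices, snp_info = NULL) {
  stopifnot(inherits(regions, "RegionSet"), length(matrices) == nrow(regions))
  for (i in seq_along(matrices)) {
    m <- matrices[[i]]
    check_symmetric(m, 1e-10, paste0("LD matrix ", i))
    if (max(abs(diag(m) - 1)) > 1e-8)
      stop("LD matrix ", i, " diagonal must be 1", call. = FALSE)
    if (min(eigen(symmetrize(m), symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
      stop("LD matrix ", i, " is not positive semi-definite", call. = FALSE)
    if (is.null(rownames(m))) stop("LD matrix ", i, " needs SNP id dimnames",
                                   call. = FALSE)
  }
  structure(list(regions = regions, matrices = matrices, snp_info = snp_info),
            class = "LDPanel")
}

#' @export
print.LDPanel <- function(x, ...) {
  cat("LDPanel:", nrow(x$regions), "regions,",
      sum(vapply(x$matrices, nrow, 0L)), "SNPs\n")
  invisible(x)
}

#' Write / read an LD panel
#'
#' One whitespace-delimited dense matrix file per region plus a JSON sidecar
#' holding the region table and per-region SNP ids; round-trips bit-exactly.
#'
#' @param panel an [ld_panel()].
#' @param dir directory to write into (created if needed).
#' @export
write_ld_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- sprintf("region_%04d.txt", seq_along(panel$matrices))
  for (i in seq_along(panel$matrices)) {
    m <- panel$matrices[[i]]
    utils::write.table(matrix(sprintf("%.17g", m), nrow(m)),
                       file.path(dir, files[i]),
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  sidecar <- list(
    regions = as.data.frame(panel$regions)[c("chrom", "start", "end")],
    files = files,
    snp_ids = lapply(panel$matrices, rownames),
    snp_info = panel$snp_info
  )
  jsonlite::write_json(sidecar, file.path(dir, "ld_panel.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_ld_panel
#' @export
read_ld_panel <- function(dir) {
  sidecar <- jsonlite::read_json(file.path(dir, "ld_panel.json"),
                                 simplifyVector = FALSE)
  rg <- sidecar$regions
  regions <- region_set(vapply(rg, `[[`, "", "chrom"),
                        vapply(rg, function(r) as.integer(r$start), 0L),
                        vapply(rg, function(r) as.integer(r$end), 0L))
  files <- unlist(sidecar$files)
  mats <- vector("list", length(files))
  for (i in seq_along(mats)) {
    ids <- unlist(sidecar$snp_ids[[i]])
    m <- as.matrix(utils::read.table(file.path(dir, files[i])))
    dimnames(m) <- list(ids, ids)
    mats[[i]] <- m
  }
  info <- sidecar$snp_info
  if (!is.null(info))           # array of row objects -> data.frame
    info <- do.call(rbind, lapply(info, function(r)
      as.data.frame(r, stringsAsFactors = FALSE)))
  ld_panel(regions, mats, snp_info = info)
}

#' Construct a multitrait summary-statistics panel
#'
#' The central object: an aligned SNP-by-trait matrix of Z-scores with an
#' explicit missingness mask (`NA` entries), per-entry sample sizes, and a
#' mask marking imputed entries.
#'
#' @param snps data.frame (`snp_id`, `chrom`, `pos`, `coded_allele`,
#'   `other_allele`) describing the aligned SNPs.
#' @param Z numeric SNP x trait matrix (`NA` = missing), trait names as
#'   column names.
#' @param N numeric SNP x trait matrix of sample sizes.
#' @param imputed logical SNP x trait matrix; defaults to all-`FALSE`.
#' @return a `SumstatsPanel`.
#' @export
sumstats_panel <- function(snps, Z, N = NULL, imputed = NULL) {
  stopifnot(is.matrix(Z), nrow(Z) == nrow(snps))
  if (ncol(Z) < 2) stop("a panel needs at least 2 traits", call. = FALSE)
  if (is.null(colnames(Z))) colnames(Z) <- paste0("trait", seq_len(ncol(Z)))
  if (is.null(N)) N <- matrix(NA_real_, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  if (is.null(imputed))
    imputed <- matrix(FALSE, nrow(Z), ncol(Z), dimnames = dimnames(Z))
  stopifnot(all(dim(N) == dim(Z)), all(dim(imputed) == dim(Z)))
  rownames(Z) <- rownames(N) <- rownames(imputed) <- snps$snp_id
  colnames(N) <- colnames(imputed) <- colnames(Z)
  structure(list(snps = snps, traits = colnames(Z), Z = Z, N = N,
                 imputed = imputed),
            class = "SumstatsPanel")
}

#' @export
print.SumstatsPanel <- function(x, ...) {
  cat("SumstatsPanel:", nrow(x$Z), "SNPs x", ncol(x$Z), "traits;",
      sprintf("%.1f%% missing", 100 * mean(is.na(x$Z))), "\n")
  invisible(x)
}

#' @export
dim.SumstatsPanel <- function(x) dim(x$Z)

#' Write / read a multitrait panel as TSV
#'
#' One row per SNP: metadata columns then `z_<trait>`, `n_<trait>`,
#' `imp_<trait>` triplets; round-trips bit-exactly.
#' @param panel a `SumstatsPanel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  df <- panel$snps
  for (tr in panel$traits) {
    df[[paste0("z_", tr)]] <- panel$Z[, tr]
    df[[paste0("n_", tr)]] <- panel$N[, tr]
    df[[paste0("imp_", tr)]] <- as.integer(panel$imputed[, tr])
  }
  write_tsv_plain(df, path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  df <- read_tsv_plain(path)
  traits <- sub("^z_", "", grep("^z_", names(df), value = TRUE))
  Z <- as.matrix(df[paste0("z_", traits)])
  N <- as.matrix(df[paste0("n_", traits)])
  storage.mode(Z) <- storage.mode(N) <- "double"
  imp <- as.matrix(df[paste0("imp_", traits)]) == 1
  colnames(Z) <- colnames(N) <- colnames(imp) <- traits
  snps <- df[c("snp_id", "chrom", "pos", "coded_allele", "other_allele")]
  sumstats_panel(snps, Z, N, imp)
}

# Resolve the orientation of (coded, other) against the reference alleles.
# Returns one of "same", "swap", "comp_same", "comp_swap", "mismatch".
allele_orientation <- function(coded, other, ref_coded, ref_other) {
  cc <- complement_allele(coded); co <- complement_allele(other)
  out <- rep("mismatch", length(coded))
  out[coded == ref_coded & other == ref_other] <- "same"
  out[out == "mismatch" & coded == ref_other & other == ref_coded] <- "swap"
  out[out == "mismatch" & cc == ref_coded & co == ref_other] <- "comp_same"
  out[out == "mismatch" & cc == ref_other & co == ref_coded] <- "comp_swap"
  out
}

#' Harmonize per-trait tables into an aligned multitrait panel
#'
#' Restricts every trait to the SNPs of a strand-unambiguous reference,
#' resolves allele orientation per SNP and trait (swapped alleles flip the
#' signs of `z` and `beta` and replace `freq` by `1 - freq`; strand flips are
#' complemented then matched), and drops entries that match no orientation.
#' The reference must contain no strand-ambiguous (A/T, C/G) SNPs.
#'
#' @param tables named list of [sumstats_table()] objects, one per trait.
#' @param reference data.frame (`snp_id`, `chrom`, `pos`, `coded_allele`,
#'   `other_allele`) or an [ld_panel()] carrying `snp_info`.
#' @return a [sumstats_panel()] aligned to the reference SNPs (reference SNPs
#'   observed in no trait are dropped).
#' @export
harmonize_panel <- function(tables, reference) {
  if (inherits(reference, "LDPanel")) {
    reference <- reference$snp_info
    if (is.null(reference))
      stop("LD panel carries no snp_info to harmonize against", call. = FALSE)
  }
  if (length(tables) < 2) stop("need at least 2 traits", call. = FALSE)
  if (is.null(names(tables)) || any(names(tables) == ""))
    names(tables) <- paste0("trait", seq_along(tables))
  if (any(is_ambiguous_pair(reference$coded_allele, reference$other_allele)))
    stop("reference contains strand-ambiguous (A/T or C/G) SNPs", call. = FALSE)
  if (anyDuplicated(reference$snp_id))
    stop("reference has duplicated snp ids", call. = FALSE)

  n <- nrow(reference)
  K <- length(tables)
  Z <- matrix(NA_real_, n, K, dimnames = list(reference$snp_id, names(tables)))
  N <- Z
  for (k in seq_len(K)) {
    tab <- tables[[k]]
    idx <- match(reference$snp_id, tab$snp_id)
    hit <- which(!is.na(idx))
    if (!length(hit)) next
    tb <- tab[idx[hit], , drop = FALSE]
    ori <- allele_orientation(tb$coded_allele, tb$other_allele,
                              reference$coded_allele[hit],
                              reference$other_allele[hit])
    keep <- ori != "mismatch"
    flip <- ori %in% c("swap", "comp_swap")
    z <- tb$z
    z[flip] <- -z[flip]
    Z[hit[keep], k] <- z[keep]
    N[hit[keep], k] <- tb$n[keep]
  }
  observed <- rowSums(!is.na(Z)) > 0
  snps <- reference[observed, c("snp_id", "chrom", "pos",
                                "coded_allele", "other_allele")]
  rownames(snps) <- NULL
  sumstats_panel(snps, Z[observed, , drop = FALSE], N[observed, , drop = FALSE])
}
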