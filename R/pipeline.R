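# End-to-end orchestration: preprocess -> covariance -> impute -> test ->
# loci -> cluster -> profiles, with per-stage seeds split from one master
# seed, content-hashed artifacts and a machine-readable run manifest.

#' Default pipeline configuration
#'
#' @param sumstats named character vector of per-trait sumstats file paths
#'   (or `NULL` when tables are passed to [run_pipeline()] directly).
#' @param ld_dir directory of a written LD panel ([write_ld_panel()]).
#' @param region_file BED-like region file.
#' @param column_map per-file column mapping for [read_sumstats()].
#' @param n_filter_fraction low-sample-size filter fraction (default 0.70).
#' @param p_floor p-value floor for Z derivation.
#' @param cov_method covariance estimator (`"naive"`, `"trimmed"`,
#'   `"pruned"`).
#' @param impute_lambda,impute_quality imputation controls.
#' @param threshold genome-wide significance threshold (default 1e-8).
#' @param clump_r2 clumping r^2 (default 0.2).
#' @param k_range candidate cluster counts.
#' @param n_boot,subsample model-selection bootstrap controls.
#' @param entropy_threshold assignment-entropy filter (default 0.75).
#' @param seed master seed; every stage derives its own stream from it.
#' @return a config list.
#' @export
pipeline_config <- function(sumstats = NULL, ld_dir = NULL,
                            region_file = NULL, column_map = NULL,
                            n_filter_fraction = 0.70, p_floor = 1e-300,
                            cov_method = "trimmed", impute_lambda = 0.1,
                            impute_quality = 0.6, threshold = 1e-8,
                            clump_r2 = 0.2, k_range = 2:6, n_boot = 10,
                            subsample = 0.8, entropy_threshold = 0.75,
                            seed = 1) {
  as.list(environment())
}

stage_seed <- function(master, stage) {
  (master * 97L + match(stage, c("preprocess", "covariance", "impute",
                                 "test", "loci", "cluster", "profiles"))) %%
    .Machine$integer.max
}

#' Run the full multitrait analysis pipeline
#'
#' Executes every stage on the given inputs, writing one artifact per stage
#' into `out_dir` (TSV/JSON, fixed formatting: reruns with the same config
#' are byte-identical) plus a manifest with parameters and content hashes.
#' A stage failure halts the run with a stage-tagged error; artifacts of
#' completed stages are preserved.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param tables optional named list of in-memory [sumstats_table()]s
#'   (bypasses `config$sumstats`).
#' @param ld optional in-memory [ld_panel()].
#' @param regions optional in-memory [region_set()].
#' @return invisibly, a list of the main in-memory results (`panel`, `cov`,
#'   `results`, `loci`, `model`, `profiles`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir, tables = NULL, ld = NULL,
                         regions = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("mtgwas")),
                   config = config[!vapply(config, is.null, TRUE)],
                   stages = list())
  artifacts <- character(0)
  run_stage <- function(name, expr) {
    res <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seed = stage_seed(config$seed, name))
    res
  }

  # --- preprocess ---------------------------------------------------------
  panel <- run_stage("preprocess", {
    if (is.null(tables)) {
      if (is.null(config$sumstats)) stop("no sumstats given")
      tables <- lapply(config$sumstats, read_sumstats,
                       column_map = config$column_map)
    }
    tables <- lapply(tables, derive_z, p_floor = config$p_floor)
    tables <- lapply(tables, infer_sample_size)
    if (is.null(ld) && !is.null(config$ld_dir)) ld <- read_ld_panel(config$ld_dir)
    if (is.null(ld)) stop("an LD panel (reference) is required")
    p <- harmonize_panel(tables, ld)
    filter_low_n(p, fraction = config$n_filter_fraction)
  })
  write_panel(panel, file.path(out_dir, "panel_preimpute.tsv"))
  artifacts <- c(artifacts, "panel_preimpute.tsv")

  # --- covariance (before imputation) -------------------------------------
  cov <- run_stage("covariance", {
    empirical_sigma_r(panel, mode = config$cov_method,
                      min_pairs = min(1000, floor(nrow(panel$Z) / 2)),
                      seed = stage_seed(config$seed, "covariance"))
  })
  write_tsv_plain(as.data.frame(cov$sigma_r),
                  file.path(out_dir, "sigma_r.tsv"))
  artifacts <- c(artifacts, "sigma_r.tsv")

  # --- impute --------------------------------------------------------------
  panel <- run_stage("impute", impute_panel(panel, ld, config$impute_lambda,
                                            config$impute_quality))
  write_panel(panel, file.path(out_dir, "panel.tsv"))
  artifacts <- c(artifacts, "panel.tsv")

  # --- tests ---------------------------------------------------------------
  if (is.null(regions) && !is.null(config$region_file))
    regions <- read_regions(config$region_file)
  results <- run_stage("test", {
    r <- multitrait_scan(panel, cov, tests = "all", regions = regions,
                         seed = stage_seed(config$seed, "test"))
    r$p <- r$p_omnibus
    post_imputation_qc(r, ld, p_sig = config$threshold,
                       r2_neighbor = config$clump_r2)
  })
  res_out <- results[setdiff(names(results), "p")]
  write_tsv_plain(res_out, file.path(out_dir, "tests.tsv"))
  artifacts <- c(artifacts, "tests.tsv")

  # --- loci ----------------------------------------------------------------
  loci <- run_stage("loci", {
    if (is.null(regions)) NULL else {
      res <- results
      res$p_joint <- pmin(res$p_omnibus, res$p_sumz_ica, na.rm = TRUE)
      mm <- region_minp(res, regions, joint_col = "p_joint")
      mm <- classify_novel(mm, config$threshold, config$threshold)
      leads <- clump(transform(res, p = p_joint), ld, p1 = config$threshold,
                     r2 = config$clump_r2)
      list(minima = mm, leads = leads)
    }
  })
  if (!is.null(loci)) {
    write_tsv_plain(loci$minima, file.path(out_dir, "loci.tsv"))
    write_tsv_plain(loci$leads, file.path(out_dir, "clumps.tsv"))
    artifacts <- c(artifacts, "loci.tsv", "clumps.tsv")
  }

  # --- cluster -------------------------------------------------------------
  cluster_out <- run_stage("cluster", {
    completeness <- rowMeans(!is.na(panel$Z) & !panel$imputed)
    sel <- select_cluster_snps(results, completeness, ld,
                               p1 = config$threshold, r2 = config$clump_r2)
    if (nrow(sel) < 10 * min(config$k_range)) NULL else {
      Zs <- panel$Z[match(sel$snp_id, panel$snps$snp_id), , drop = FALSE]
      ks <- select_k(Zs, k_range = config$k_range, n_boot = config$n_boot,
                     subsample = config$subsample,
                     seed = stage_seed(config$seed, "cluster"))
      model <- fit_mgmm(Zs, ks$k, seed = stage_seed(config$seed, "cluster"))
      assign <- filter_entropy(model, config$entropy_threshold)
      list(selection = sel, select_k = ks, model = model, assignments = assign)
    }
  })
  if (!is.null(cluster_out)) {
    jsonlite::write_json(
      list(k = cluster_out$model$k, pi = cluster_out$model$pi,
           mu = cluster_out$model$mu, sigma = cluster_out$model$sigma,
           bic = cluster_out$model$bic, curves = cluster_out$select_k$curves),
      file.path(out_dir, "cluster_model.json"), digits = NA, auto_unbox = TRUE)
    adf <- cluster_out$assignments
    adf$snp_id <- cluster_out$selection$snp_id[adf$row]
    write_tsv_plain(adf, file.path(out_dir, "cluster_assignments.tsv"))
    artifacts <- c(artifacts, "cluster_model.json", "cluster_assignments.tsv")
  }

  # --- profiles ------------------------------------------------------------
  profiles <- run_stage("profiles", {
    if (is.null(cluster_out)) NULL else {
      sel <- cluster_out$selection
      rows <- match(sel$snp_id, panel$snps$snp_id)
      kept <- cluster_out$assignments
      Zk <- panel$Z[rows[kept$row], , drop = FALSE]
      Nk <- panel$N[rows[kept$row], , drop = FALSE]
      ve <- variance_explained_matrix(Zk, Nk, kept$cluster)
      list(variance_explained = ve)
    }
  })
  if (!is.null(profiles)) {
    write_tsv_plain(as.data.frame(profiles$variance_explained$shares),
                    file.path(out_dir, "variance_explained.tsv"))
    artifacts <- c(artifacts, "variance_explained.tsv")
  }

  manifest$artifacts <- as.list(tools::md5sum(file.path(out_dir, artifacts)))
  names(manifest$artifacts) <- artifacts
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(list(panel = panel, cov = cov, results = results, loci = loci,
                 cluster = cluster_out, profiles = profiles,
                 manifest = manifest))
}
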