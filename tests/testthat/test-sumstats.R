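test_that("reading a sumstats file parses, validates and round-trips", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(rsid = c("rs1", "rs2", "rs3"), chr = "1",
                   bp = c(100L, 200L, 300L),
                   ea = c("A", "C", "G"), oa = c("G", "A", "A"),
                   b = c(0.1, -0.2, 0.05), sderr = c(0.05, 0.04, 0.05),
                   p = c(0.045, 1e-6, "NA"), N = 10000)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_sumstats(path, column_map = c(
    snp_id = "rsid", chrom = "chr", pos = "bp", coded_allele = "ea",
    other_allele = "oa", beta = "b", se = "sderr", pvalue = "p", n = "N"))
  expect_s3_class(tab, "SumstatsTable")
  expect_equal(nrow(tab), 3)
  expect_true(all(is.na(tab$z)))            # z derived later, not at parse
  expect_true(is.na(tab$pvalue[3]))          # "NA" p retained as missing
  expect_equal(tab$beta, c(0.1, -0.2, 0.05))

  # writer round-trips bit-exactly
  out <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tab, out)
  back <- read_sumstats(out)
  expect_identical(back$beta, tab$beta)
  expect_identical(back$pvalue, tab$pvalue)

  # missing required column is a configuration error
  expect_error(read_sumstats(path, column_map = c(snp_id = "nope")),
               "not in file")
})

test_that("duplicate ids are dropped with a warning; invalid rows counted", {
  df <- data.frame(snp_id = c("rs1", "rs1", "rs2", "rs3"), chrom = "1",
                   pos = c(1L, 1L, 2L, -5L),
                   coded_allele = c("A", "A", "C", "A"),
                   other_allele = c("G", "G", "T", "G"),
                   z = c(1, 1, 2, 3))
  expect_warning(tab <- sumstats_table(df), "duplicated")
  expect_equal(nrow(tab), 2)                 # dup dropped + pos<=0 dropped
  log <- attr(tab, "log")
  expect_equal(log$n_dropped_duplicate, 1)
  expect_equal(log$n_dropped_invalid, 1)
})

test_that("harmonization resolves swaps, strand flips and drops mismatches", {
  ld <- toy_ld_panel()
  ref <- ld$snp_info
  z <- seq(-2, 2, length.out = nrow(ref))
  t1 <- sumstats_table(toy_sumstats_df(ref, z))

  # trait 2: alleles swapped -> z sign must flip back
  d2 <- toy_sumstats_df(ref, 2.5)
  tmp <- d2$coded_allele; d2$coded_allele <- d2$other_allele
  d2$other_allele <- tmp
  t2 <- sumstats_table(d2)

  # trait 3: strand-complemented alleles, same orientation -> z unchanged;
  # plus one SNP absent from the reference
  d3 <- toy_sumstats_df(ref, 1.5)
  d3$coded_allele <- chartr("ACGT", "TGCA", d3$coded_allele)
  d3$other_allele <- chartr("ACGT", "TGCA", d3$other_allele)
  d3 <- d3[-1, ]
  t3 <- sumstats_table(d3)

  panel <- harmonize_panel(list(a = t1, b = t2, c = t3), ref)
  expect_s3_class(panel, "SumstatsPanel")
  expect_equal(unname(panel$Z[, "a"]), z)
  expect_equal(unname(panel$Z[, "b"]), rep(-2.5, nrow(ref)))
  expect_true(is.na(panel$Z[1, "c"]))        # absent from trait table
  expect_equal(unname(panel$Z[-1, "c"]), rep(1.5, nrow(ref) - 1))
  expect_lte(nrow(panel$Z), nrow(ref))

  # ambiguous reference refused
  bad_ref <- ref
  bad_ref$other_allele[1] <- chartr("ACGT", "TGCA", bad_ref$coded_allele[1])
  expect_error(harmonize_panel(list(a = t1, b = t2), bad_ref),
               "strand-ambiguous")
})

test_that("harmonization is idempotent and double swap restores z", {
  ld <- toy_ld_panel()
  ref <- ld$snp_info
  z <- rnorm(nrow(ref))
  t1 <- sumstats_table(toy_sumstats_df(ref, z))
  t2 <- sumstats_table(toy_sumstats_df(ref, -z))
  p1 <- harmonize_panel(list(a = t1, b = t2), ref)
  # already aligned to the reference: harmonizing again changes nothing
  t1b <- sumstats_table(toy_sumstats_df(ref, p1$Z[, "a"]))
  t2b <- sumstats_table(toy_sumstats_df(ref, p1$Z[, "b"]))
  p2 <- harmonize_panel(list(a = t1b, b = t2b), ref)
  expect_identical(p2$Z, p1$Z)

  # swapping alleles twice is the identity on z
  d <- toy_sumstats_df(ref, z)
  sw <- function(df) { tmp <- df$coded_allele
    df$coded_allele <- df$other_allele; df$other_allele <- tmp
    df$z <- -df$z; df$beta <- -df$beta; df$freq <- 1 - df$freq; df }
  expect_equal(sw(sw(d))$z, d$z)
})

test_that("LD panel and region I/O round-trip; invariants enforced", {
  ld <- toy_ld_panel(n_regions = 3, block_size = 4, rho = 0.5)
  dir <- withr::local_tempdir()
  write_ld_panel(ld, dir)
  back <- read_ld_panel(dir)
  expect_identical(back$matrices, ld$matrices)
  expect_identical(as.data.frame(back$regions), as.data.frame(ld$regions))

  # asymmetric or non-unit-diagonal matrices rejected
  m <- ld$matrices[[1]]; m[1, 2] <- m[1, 2] + 1e-3
  expect_error(ld_panel(ld$regions[1, ], list(m)), "not symmetric")
  m2 <- ld$matrices[[1]]; diag(m2)[1] <- 2; m2 <- (m2 + t(m2)) / 2
  expect_error(ld_panel(ld$regions[1, ], list(m2)), "diagonal")

  # regions: overlap and end<=start rejected
  expect_error(region_set("1", c(1, 500), c(1000, 1500)), "overlapping")
  expect_error(region_set("1", 10, 10), "end > start")

  # SNP-to-region assignment is half-open [start, end)
  rs <- region_set("1", c(1, 1001), c(1001, 2001))
  expect_equal(assign_regions(c("1", "1", "1", "2"), c(1, 1000, 1001, 50), rs),
               c(1L, 1L, 2L, NA))
})

test_that("panel TSV writer round-trips Z, N and the imputed mask", {
  ld <- toy_ld_panel()
  ref <- ld$snp_info
  z <- rnorm(nrow(ref))
  t1 <- sumstats_table(toy_sumstats_df(ref, z))
  t2 <- sumstats_table(toy_sumstats_df(ref, -z / 3))
  panel <- harmonize_panel(list(a = t1, b = t2), ref)
  panel$Z[2, 1] <- NA
  panel$imputed[3, 2] <- TRUE
  path <- withr::local_tempfile(fileext = ".tsv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_identical(back$Z, panel$Z)
  expect_identical(back$N, panel$N)
  expect_identical(back$imputed, panel$imputed)
})
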