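#' @keywords internal
"_PACKAGE"

# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Complement nucleotide alleles
#' @param x character vector of single-letter alleles (A, C, G, T)
#' @return complemented alleles
#' @keywords internal
complement_allele <- function(x) chartr("ACGT", "TGCA", x)

is_ambiguous_pair <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
    (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

check_symmetric <- function(m, tol = 1e-10, name = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop(name, " must be a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > tol)
    stop(name, " is not symmetric within ", tol, call. = FALSE)
  invisible(TRUE)
}

# Two-sided p-value from a Z-score.
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

# Symmetrize a nearly-symmetric matrix (numerical hygiene after products).
symmetrize <- function(m) (m + t(m)) / 2

# Deterministic full-precision TSV writer; round-trips doubles bit-exactly
# through read_tsv_plain() via the %.17g representation.
write_tsv_plain <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

read_tsv_plain <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA", ...)
}

# Draw n rows from N(0, sigma) via the Cholesky (or eigen, if semi-definite)
# factor.  Returns an n x K matrix.
rmvnorm_rows <- function(n, sigma) {
  K <- nrow(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) NULL)
  if (is.null(ch)) {
    eg <- eigen(symmetrize(sigma), symmetric = TRUE)
    vals <- pmax(eg$values, 0)
    ch <- t(eg$vectors %*% (t(eg$vectors) * sqrt(vals)))
  }
  matrix(stats::rnorm(n * K), n, K) %*% ch
}

# Sign convention for eigen/ICA weight vectors: largest-magnitude loading
# positive, so outputs are deterministic across platforms.
canonical_sign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -w else w
}
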