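# Minimal FastICA (deflation, logcosh contrast) used to build the
# data-driven sumZ weighting. Operates on the SNP x trait Z matrix; returns
# unmixing directions expressed in the original trait space so they can be
# applied directly as sumZ weight vectors.

#' FastICA by deflation
#'
#' Centers and whitens the columns of `X`, then extracts up to `n_comp`
#' independent components one at a time (deflation) with the `tanh`
#' (logcosh) nonlinearity and symmetric decorrelation against previously
#' found components. Rows with any missing value are dropped before fitting.
#'
#' @param X numeric matrix (observations x variables).
#' @param n_comp number of components (default `ncol(X)`).
#' @param max_iter,tol fixed-point iteration controls.
#' @param seed RNG seed for the random initial directions.
#' @param max_rows rows used for fitting; larger inputs are subsampled
#'   (seeded) — the unmixing directions are K-dimensional and stabilize long
#'   before genome scale (default 20000).
#' @return list with `weights` (`ncol(X)` x `n_comp`; column `i` is the
#'   original-space direction of component `i`, sign-canonicalized),
#'   `converged` (logical per component), `n_used` (rows used).
#' @export
fast_ica <- function(X, n_comp = ncol(X), max_iter = 200, tol = 1e-6,
                     seed = 1, max_rows = 20000) {
  X <- as.matrix(X)
  X <- X[stats::complete.cases(X), , drop = FALSE]
  n <- nrow(X); K <- ncol(X)
  n_comp <- min(n_comp, K)
  if (n < 10 * K) stop("too few complete rows for ICA", call. = FALSE)
  if (n > max_rows) {
    old_sub <- .Random.seed_save()
    set.seed(seed)
    X <- X[sort(sample.int(n, max_rows)), , drop = FALSE]
    .Random.seed_restore(old_sub)
    n <- max_rows
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  eg <- eigen(stats::cov(Xc), symmetric = TRUE)
  vals <- pmax(eg$values, 1e-12)
  Kw <- t(eg$vectors) / sqrt(vals)      # whitening matrix (K x K rows)
  Xw <- Xc %*% t(Kw)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  W <- matrix(0, K, 0)                  # found directions (whitened space)
  converged <- logical(n_comp)
  for (i in seq_len(n_comp)) {
    w <- stats::rnorm(K)
    w <- w / sqrt(sum(w^2))
    for (it in seq_len(max_iter)) {
      wx <- drop(Xw %*% w)
      g <- tanh(wx)
      gp <- 1 - g^2
      w_new <- drop(crossprod(Xw, g)) / n - mean(gp) * w
      if (ncol(W) > 0)                  # deflate against earlier components
        w_new <- w_new - W %*% crossprod(W, w_new)
      w_new <- w_new / sqrt(sum(w_new^2))
      delta <- abs(abs(sum(w_new * w)) - 1)
      w <- drop(w_new)
      if (delta < tol) { converged[i] <- TRUE; break }
    }
    W <- cbind(W, w)
  }
  weights <- t(Kw) %*% W                # back to original trait space
  weights <- apply(weights, 2, canonical_sign)
  rownames(weights) <- colnames(X)
  list(weights = weights, converged = converged, n_used = n)
}
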