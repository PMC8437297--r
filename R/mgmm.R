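# Gaussian mixture clustering of SNP x trait Z-score profiles with missing
# coordinates.
#
# Generative model: each SNP i draws a cluster label from Multinomial(1, pi)
# and, conditional on cluster j, a profile Z_i ~ N(mu_j, Sigma_j). With
# missing coordinates the E-step evaluates each component's marginal density
# on the observed sub-vector and the conditional moments of the missing
# block given the observed one; the M-step updates (pi, mu_j, Sigma_j) from
# the completed sufficient statistics (Ghahramani-Jordan EM).

mvn_logdens_obs <- function(X, mu, sigma) {
  # log N(x_obs; mu, sigma) for every row of X (observed block only)
  ch <- chol(sigma)
  d <- ncol(X)
  dev <- sweep(X, 2, mu)
  q <- colSums(backsolve(ch, t(dev), transpose = TRUE)^2)
  -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) + q)
}

floor_eigen <- function(sigma, ridge) {
  eg <- eigen(symmetrize(sigma), symmetric = TRUE)
  if (min(eg$values) >= ridge) return(symmetrize(sigma))
  vals <- pmax(eg$values, ridge)
  symmetrize(eg$vectors %*% (t(eg$vectors) * vals))
}

# k-means++ seeding on a complete matrix
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- X[sample.int(n, 1), , drop = FALSE]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  while (nrow(centers) < k) {
    pr <- d2 / sum(d2)
    pick <- sample.int(n, 1, prob = pr)
    centers <- rbind(centers, X[pick, , drop = FALSE])
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[pick, ])^2))
  }
  centers
}

#' Fit a Gaussian mixture to Z profiles with missing coordinates
#'
#' EM for a k-component multivariate Gaussian mixture where each row may
#' have missing entries (`NA`). Initialization is k-means++ on the
#' column-mean-completed matrix; `n_init` restarts are run for a few burn-in
#' iterations and the best is continued to convergence. Component labels are
#' canonicalized by sorting on the first coordinate of the means, so outputs
#' are stable under label permutation. Covariance eigenvalues are floored at
#' `ridge` to prevent component collapse; a component whose weight collapses
#' is re-seeded once, then the fit fails.
#'
#' @param Z numeric SNP x trait matrix with `NA` for missing; every row must
#'   have at least one observed entry.
#' @param k number of components (>= 1).
#' @param seed RNG seed (initialization and re-seeding).
#' @param max_iter,tol EM stopping controls: stop when the relative
#'   log-likelihood change falls below `tol` (default 1e-6) or at `max_iter`.
#' @param n_init number of k-means++ restarts (default 5).
#' @param burn_iter EM iterations run per restart before the best is chosen
#'   (default 10).
#' @param ridge eigenvalue floor on component covariances (default 1e-6).
#' @param init optional explicit initialization: list with `pi`, `mu`
#'   (k x K) and `sigma` (list of k matrices); skips the k-means++ restarts.
#' @return a `ClusterModel`: list with `k`, `pi`, `mu` (k x K), `sigma`
#'   (list of K x K), `responsibilities` (n x k), `assignment`,
#'   `entropy` (per SNP, natural log), `loglik` (final), `loglik_trace`,
#'   `bic`, `completed` (n x K matrix with missing entries replaced by their
#'   conditional expectation under the assigned component), `n_iter`,
#'   `converged`.
#' @export
fit_mgmm <- function(Z, k, seed = 1, max_iter = 500, tol = 1e-6, n_init = 5,
                     burn_iter = 10, ridge = 1e-6, init = NULL) {
  Z <- as.matrix(Z)
  n <- nrow(Z); K <- ncol(Z)
  stopifnot(k >= 1)
  if (any(rowSums(!is.na(Z)) == 0))
    stop("every SNP needs at least one observed coordinate", call. = FALSE)
  if (k > 1 && k > n / 10)
    stop("k too large for the number of SNPs (need k <= n/10)", call. = FALSE)

  # row order must not matter: fit in id-sorted order, map back at the end
  ord <- if (!is.null(rownames(Z)) && !anyDuplicated(rownames(Z)))
    order(rownames(Z)) else seq_len(n)
  Zs <- Z[ord, , drop = FALSE]

  obs_mask <- !is.na(Zs)
  pattern <- apply(obs_mask, 1, function(o) paste(as.integer(o), collapse = ""))
  pat_levels <- unique(pattern)
  pat_rows <- split(seq_len(n), factor(pattern, levels = pat_levels))
  pat_obs <- lapply(pat_levels,
                    function(p) as.logical(as.integer(strsplit(p, "")[[1]])))

  col_mu <- colMeans(Zs, na.rm = TRUE)
  Zfill <- Zs
  for (j in seq_len(K)) Zfill[is.na(Zfill[, j]), j] <- col_mu[j]

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  run_em <- function(par, n_iter, trace = FALSE) {
    loglik_trace <- numeric(0)
    prev_ll <- -Inf
    reseeded <- FALSE
    for (it in seq_len(n_iter)) {
      logr <- matrix(0, n, k)
      # cache conditional weights per (pattern, component)
      cond <- vector("list", length(pat_levels) * k)
      for (pi_ in seq_along(pat_levels)) {
        o <- pat_obs[[pi_]]
        rows <- pat_rows[[pi_]]
        Xo <- Zs[rows, o, drop = FALSE]
        for (j in seq_len(k)) {
          sj <- par$sigma[[j]]
          logr[rows, j] <- log(par$pi[j]) +
            mvn_logdens_obs(Xo, par$mu[j, o], sj[o, o, drop = FALSE])
          if (!all(o)) {
            W <- sj[!o, o, drop = FALSE] %*% solve(sj[o, o, drop = FALSE])
            Cm <- sj[!o, !o, drop = FALSE] - W %*% sj[o, !o, drop = FALSE]
            cond[[(pi_ - 1) * k + j]] <- list(W = W, Cm = Cm)
          }
        }
      }
      mx <- apply(logr, 1, max)
      ll <- sum(mx + log(rowSums(exp(logr - mx))))
      r <- exp(logr - mx)
      r <- r / rowSums(r)
      loglik_trace <- c(loglik_trace, ll)

      # M-step
      Nj <- colSums(r)
      collapse <- which(Nj < 1)          # effectively empty component
      if (length(collapse)) {
        if (reseeded)
          stop("mixture component collapsed twice; reduce k", call. = FALSE)
        reseeded <- TRUE
        for (j in collapse) {
          par$mu[j, ] <- Zfill[sample.int(n, 1), ]
          par$sigma[[j]] <- floor_eigen(stats::cov(Zfill), ridge)
          par$pi <- rep(1 / k, k)
        }
        next
      }
      new_mu <- matrix(0, k, K)
      new_sigma <- vector("list", k)
      S1 <- matrix(0, K, k)
      S2 <- array(0, c(K, K, k))
      for (pi_ in seq_along(pat_levels)) {
        o <- pat_obs[[pi_]]
        rows <- pat_rows[[pi_]]
        for (j in seq_len(k)) {
          rw <- r[rows, j]
          Xhat <- matrix(0, length(rows), K)
          Xhat[, o] <- Zs[rows, o, drop = FALSE]
          if (!all(o)) {
            cj <- cond[[(pi_ - 1) * k + j]]
            dev <- sweep(Zs[rows, o, drop = FALSE], 2, par$mu[j, o])
            Xhat[, !o] <- sweep(dev %*% t(cj$W), 2, par$mu[j, !o], `+`)
          }
          S1[, j] <- S1[, j] + drop(crossprod(Xhat, rw))
          S2[, , j] <- S2[, , j] + crossprod(Xhat, Xhat * rw)
          if (!all(o)) {
            add <- matrix(0, K, K)
            add[!o, !o] <- cj$Cm * sum(rw)
            S2[, , j] <- S2[, , j] + add
          }
        }
      }
      for (j in seq_len(k)) {
        new_mu[j, ] <- S1[, j] / Nj[j]
        new_sigma[[j]] <- floor_eigen(
          S2[, , j] / Nj[j] - tcrossprod(new_mu[j, ]), ridge)
      }
      par <- list(pi = Nj / n, mu = new_mu, sigma = new_sigma)
      if (is.finite(prev_ll) &&
          abs(ll - prev_ll) < tol * (abs(prev_ll) + 1)) {
        return(list(par = par, loglik = ll, trace = loglik_trace,
                    r = r, converged = TRUE, n_iter = it))
      }
      prev_ll <- ll
    }
    list(par = par, loglik = prev_ll, trace = loglik_trace, r = r,
         converged = FALSE, n_iter = n_iter)
  }

  init_par <- function() {
    centers <- kmeanspp_centers(Zfill, k)
    km <- if (k > 1)
      suppressWarnings(stats::kmeans(Zfill, centers = centers, iter.max = 50,
                                     algorithm = "Lloyd"))
    else list(cluster = rep(1L, n))
    mu <- matrix(0, k, K); sigma <- vector("list", k); piv <- numeric(k)
    glob <- floor_eigen(stats::cov(Zfill), ridge)
    for (j in seq_len(k)) {
      rows <- which(km$cluster == j)
      piv[j] <- max(length(rows), 1) / n
      mu[j, ] <- if (length(rows)) colMeans(Zfill[rows, , drop = FALSE])
      else Zfill[sample.int(n, 1), ]
      sigma[[j]] <- if (length(rows) > K + 1)
        floor_eigen(stats::cov(Zfill[rows, , drop = FALSE]), ridge) else glob
    }
    list(pi = piv / sum(piv), mu = mu, sigma = sigma)
  }

  if (is.null(init)) {
    # a collapsing restart is dropped, not fatal: only failure of every
    # restart (k beyond the data's support) aborts the fit
    best <- NULL
    for (restart in seq_len(max(n_init, 1))) {
      cand <- tryCatch(run_em(init_par(), burn_iter),
                       error = function(e) NULL)
      if (is.null(cand)) next
      if (is.null(best) || cand$loglik > best$loglik) best <- cand
    }
    if (is.null(best))
      stop("every initialization collapsed; reduce k", call. = FALSE)
    fit <- tryCatch(run_em(best$par, max_iter), error = function(e) NULL)
    if (is.null(fit)) fit <- best        # keep the viable burn-in fit
    else fit$trace <- c(best$trace, fit$trace)
  } else {
    fit <- run_em(init, max_iter)
  }

  # canonical label order: ascending first coordinate of mu
  lab_ord <- order(fit$par$mu[, 1])
  par <- list(pi = fit$par$pi[lab_ord],
              mu = fit$par$mu[lab_ord, , drop = FALSE],
              sigma = fit$par$sigma[lab_ord])
  r <- fit$r[, lab_ord, drop = FALSE]

  assignment <- max.col(r, ties.method = "first")
  ent <- apply(r, 1, entropy)

  # complete missing coordinates under each SNP's assigned component
  completed <- Zs
  for (pi_ in seq_along(pat_levels)) {
    o <- pat_obs[[pi_]]
    if (all(o)) next
    rows <- pat_rows[[pi_]]
    for (j in seq_len(k)) {
      rj <- rows[assignment[rows] == j]
      if (!length(rj)) next
      sj <- par$sigma[[j]]
      W <- sj[!o, o, drop = FALSE] %*% solve(sj[o, o, drop = FALSE])
      dev <- sweep(Zs[rj, o, drop = FALSE], 2, par$mu[j, o])
      completed[rj, !o] <- sweep(dev %*% t(W), 2, par$mu[j, !o], `+`)
    }
  }

  npar <- (k - 1) + k * K + k * K * (K + 1) / 2
  inv <- order(ord)   # map back to input row order
  structure(list(k = k, pi = par$pi, mu = par$mu, sigma = par$sigma,
                 responsibilities = r[inv, , drop = FALSE],
                 assignment = assignment[inv],
                 entropy = ent[inv],
                 loglik = fit$loglik, loglik_trace = fit$trace,
                 bic = -2 * fit$loglik + npar * log(n),
                 completed = completed[inv, , drop = FALSE],
                 n_iter = fit$n_iter, converged = fit$converged),
            class = "ClusterModel")
}

#' @export
print.ClusterModel <- function(x, ...) {
  cat("ClusterModel: k =", x$k, ", n =", nrow(x$responsibilities),
      ", loglik =", format(x$loglik), ", BIC =", format(x$bic),
      if (x$converged) "(converged)" else "(max_iter reached)", "\n")
  invisible(x)
}

#' Assignment entropy of a posterior probability vector
#'
#' `-sum(p * ln p)` with `0 * ln 0 = 0`. Natural logarithm: zero for a
#' certain assignment, `ln k` for a uniform one. Higher values flag SNPs
#' whose cluster attribution is ambiguous.
#'
#' Note the conventional minus sign is used so that entropy is nonnegative
#' and increases with ambiguity.
#'
#' @param p probability vector summing to 1.
#' @return nonnegative scalar.
#' @export
entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Filter ambiguous cluster assignments by entropy
#'
#' SNPs with assignment entropy above `threshold` are excluded; each
#' retained SNP goes to its maximum-responsibility cluster (ties to the
#' lower cluster index).
#'
#' Note with natural-log entropy the default threshold 0.75 exceeds
#' `ln 2 ~ 0.693`, so no SNP can be filtered from a 2-cluster model.
#'
#' @param model a `ClusterModel` from [fit_mgmm()].
#' @param threshold entropy cutoff (default 0.75).
#' @return data.frame over retained SNPs: `row`, `cluster`, `posterior`,
#'   `entropy`.
#' @export
filter_entropy <- function(model, threshold = 0.75) {
  keep <- which(model$entropy <= threshold)
  r <- model$responsibilities[keep, , drop = FALSE]
  cl <- max.col(r, ties.method = "first")
  data.frame(row = keep, cluster = cl,
             posterior = r[cbind(seq_along(keep), cl)],
             entropy = model$entropy[keep], row.names = NULL)
}

#' Mean silhouette of a fitted model
#' @param model a `ClusterModel`.
#' @return mean silhouette width over SNPs (Euclidean distance on the
#'   conditional-expectation-completed data, hard assignments); `NA` for
#'   k = 1.
#' @export
model_silhouette <- function(model) {
  if (model$k < 2 || length(unique(model$assignment)) < 2) return(NA_real_)
  sil <- cluster::silhouette(model$assignment,
                             stats::dist(model$completed))
  mean(sil[, "sil_width"])
}

#' Compound BIC/silhouette rule for the number of clusters
#'
#' If the BIC-optimal k exceeds the silhouette-optimal k, walk upward from
#' the silhouette optimum and stop before the first step that significantly
#' decreases the silhouette (one-sided Welch t-test on replicate silhouettes
#' at `alpha`), or at the BIC optimum, whichever comes first; otherwise
#' return the silhouette optimum.
#'
#' @param k_values candidate k values (increasing).
#' @param bic_mean mean BIC per k (lower is better).
#' @param sil_reps list (per k) of replicate silhouette values.
#' @param alpha Welch-test level (default 0.05).
#' @return list with `k`, `k_sil`, `k_bic`.
#' @export
compound_k_rule <- function(k_values, bic_mean, sil_reps, alpha = 0.05) {
  sil_mean <- vapply(sil_reps, mean, 0, na.rm = TRUE)
  k_sil <- k_values[which.max(sil_mean)]
  k_bic <- k_values[which.min(bic_mean)]
  k <- k_sil
  if (k_bic > k_sil) {
    while (k < k_bic) {
      i <- match(k, k_values)
      a <- sil_reps[[i + 1]]; b <- sil_reps[[i]]
      sig_drop <- length(a) >= 2 && length(b) >= 2 &&
        tryCatch(stats::t.test(a, b, alternative = "less")$p.value < alpha,
                 # degenerate (constant) replicates: fall back to the means
                 error = function(e) mean(a) < mean(b) - 1e-12)
      if (sig_drop) break
      k <- k_values[i + 1]
    }
  }
  list(k = k, k_sil = k_sil, k_bic = k_bic)
}

#' Select the number of clusters by bootstrapped BIC and silhouette
#'
#' For each candidate k, fits the mixture `n_boot` times on a random subset
#' of `subsample` of the SNPs (subsampling is keyed to sorted SNP ids, so
#' row order is irrelevant), records BIC and mean silhouette per replicate,
#' and applies [compound_k_rule()].
#'
#' @param Z SNP x trait matrix with missing values (rownames = SNP ids).
#' @param k_range candidate cluster counts (default 2:10).
#' @param n_boot bootstrap replicates per k (default 100).
#' @param subsample subset fraction (default 0.8).
#' @param seed RNG seed.
#' @param ... passed to [fit_mgmm()] (e.g. `n_init`, `max_iter`).
#' @return list with `k` (selected), `k_sil`, `k_bic`, and `curves` (a
#'   data.frame of per-k mean/sd of BIC and silhouette) plus `sil_reps`,
#'   `bic_reps`.
#' @export
select_k <- function(Z, k_range = 2:10, n_boot = 100, subsample = 0.8,
                     seed = 1, ...) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  ids <- rownames(Z) %||% as.character(seq_len(n))
  id_order <- order(ids)
  m <- max(2, round(subsample * n))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  subsets <- lapply(seq_len(n_boot),
                    function(b) id_order[sort(sample.int(n, m))])

  bic_reps <- sil_reps <- vector("list", length(k_range))
  ok <- logical(length(k_range))
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    bb <- ss <- rep(NA_real_, n_boot)
    for (b in seq_len(n_boot)) {
      fit <- tryCatch(
        fit_mgmm(Z[subsets[[b]], , drop = FALSE], k,
                 seed = seed + 1000L * i + b, ...),
        error = function(e) NULL)
      if (is.null(fit)) next
      bb[b] <- fit$bic
      ss[b] <- model_silhouette(fit)
    }
    if (all(is.na(bb))) {
      warning("all fits failed for k = ", k, "; excluded", call. = FALSE)
      next
    }
    ok[i] <- TRUE
    bic_reps[[i]] <- bb[!is.na(bb)]
    sil_reps[[i]] <- ss[!is.na(ss)]
  }
  kv <- k_range[ok]
  bic_reps <- bic_reps[ok]; sil_reps <- sil_reps[ok]
  rule <- compound_k_rule(kv, vapply(bic_reps, mean, 0), sil_reps)
  curves <- data.frame(
    k = kv,
    bic_mean = vapply(bic_reps, mean, 0),
    bic_sd = vapply(bic_reps, stats::sd, 0),
    sil_mean = vapply(sil_reps, mean, 0),
    sil_sd = vapply(sil_reps, stats::sd, 0))
  c(rule, list(curves = curves, sil_reps = sil_reps, bic_reps = bic_reps))
}

#' Detect mirror clusters induced by arbitrary allele coding
#'
#' Flips of the coded allele negate a SNP's whole profile, which can split
#' one biological cluster into two sign-symmetric ones. Pairs of components
#' with `mu_a ~ -mu_b` (within `tol * ||mu||`) are reported for optional
#' manual merging; nothing is merged automatically.
#'
#' @param model a `ClusterModel`.
#' @param tol relative tolerance (default 0.5).
#' @return data.frame of candidate pairs (`a`, `b`, `distance`).
#' @export
detect_mirror_clusters <- function(model, tol = 0.5) {
  k <- model$k
  out <- NULL
  for (a in seq_len(k)) for (b in seq_len(k)) {
    if (b <= a) next
    d <- sqrt(sum((model$mu[a, ] + model$mu[b, ])^2))
    scale <- sqrt(sum(model$mu[a, ]^2) + sum(model$mu[b, ]^2)) / sqrt(2)
    if (scale > 0 && d <= tol * scale)
      out <- rbind(out, data.frame(a = a, b = b, distance = d))
  }
  out %||% data.frame(a = integer(), b = integer(), distance = numeric())
}
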