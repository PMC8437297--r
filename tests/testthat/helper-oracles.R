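# Independent oracles and small fixture builders used across the suite.
# Everything here is deliberately naive/brute-force and shares no code with
# the package internals it checks.

# --- complete-data GMM EM (plain textbook implementation) -----------------
oracle_gmm_em <- function(X, pi0, mu0, sigma0, n_iter = 50, tol = 1e-6) {
  n <- nrow(X); k <- length(pi0)
  pi_ <- pi0; mu <- mu0; sigma <- sigma0
  prev <- -Inf
  dens <- function(x, m, s) {
    d <- length(m)
    exp(-0.5 * (d * log(2 * pi) + determinant(s)$modulus +
                  mahalanobis(x, m, s)))
  }
  for (it in seq_len(n_iter)) {
    r <- sapply(seq_len(k), function(j) pi_[j] * dens(X, mu[j, ], sigma[[j]]))
    ll <- sum(log(rowSums(r)))
    r <- r / rowSums(r)
    Nj <- colSums(r)
    for (j in seq_len(k)) {
      mu[j, ] <- colSums(X * r[, j]) / Nj[j]
      dev <- sweep(X, 2, mu[j, ])
      sigma[[j]] <- crossprod(dev, dev * r[, j]) / Nj[j]
    }
    pi_ <- Nj / n
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(prev) + 1)) break
    prev <- ll
  }
  list(pi = pi_, mu = mu, sigma = sigma, loglik = ll)
}

# --- tiny mvn sampler (independent of the package internals) -------------
rmvnorm_rows_test <- function(n, sigma) {
  matrix(rnorm(n * ncol(sigma)), n) %*% chol(sigma)
}

# --- brute-force greedy clumping -----------------------------------------
oracle_clump <- function(snp_id, pos, p, r2mat, p1, r2) {
  avail <- !is.na(p) & p < p1
  leads <- character(0)
  absorbed <- rep(FALSE, length(p))
  repeat {
    cand <- which(avail & !absorbed)
    if (!length(cand)) break
    cand <- cand[order(p[cand], pos[cand], snp_id[cand])]
    lead <- cand[1]
    leads <- c(leads, snp_id[lead])
    absorbed[r2mat[lead, ] >= r2] <- TRUE
    absorbed[lead] <- TRUE
  }
  leads
}

# --- tiny LD panel fixture -----------------------------------------------
# One chromosome, `n_regions` blocks of `block_size` SNPs, AR(1)-style
# within-block correlation with parameter `rho`.
toy_ld_panel <- function(n_regions = 2, block_size = 5, rho = 0.6,
                         chrom = "1") {
  mats <- list()
  ids_all <- character(0)
  starts <- integer(n_regions)
  for (r in seq_len(n_regions)) {
    ids <- sprintf("rs%03d", (r - 1) * block_size + seq_len(block_size))
    m <- rho^abs(outer(seq_len(block_size), seq_len(block_size), `-`))
    dimnames(m) <- list(ids, ids)
    mats[[r]] <- m
    ids_all <- c(ids_all, ids)
    starts[r] <- (r - 1) * block_size * 1000 + 1
  }
  regions <- region_set(rep(chrom, n_regions), starts,
                        starts + block_size * 1000)
  snp_info <- data.frame(
    snp_id = ids_all, chrom = chrom,
    pos = as.integer(seq_along(ids_all) * 1000 - 500),
    coded_allele = rep(c("A", "C"), length.out = length(ids_all)),
    other_allele = rep(c("G", "T"), length.out = length(ids_all)),
    stringsAsFactors = FALSE)
  ld_panel(regions, mats, snp_info = snp_info)
}

# A small in-memory sumstats data.frame for a trait, aligned to toy_ld_panel
toy_sumstats_df <- function(panel_info, z, n = 1e4) {
  data.frame(snp_id = panel_info$snp_id, chrom = panel_info$chrom,
             pos = panel_info$pos,
             coded_allele = panel_info$coded_allele,
             other_allele = panel_info$other_allele,
             z = z, beta = z / sqrt(n), se = 1 / sqrt(n),
             pvalue = 2 * pnorm(-abs(z)), n = n, freq = 0.3,
             stringsAsFactors = FALSE)
}

# well-separated 3-component mixture fixture shared by recovery tests.
# Means are 10 sigma apart in every coordinate so that any observed subset
# of a profile identifies its component.
cluster_fixture_mu <- function(K = 4) rbind(rep(-10, K), rep(0, K), rep(10, K))

cluster_fixture <- function(n = 2000, missing_rate = 0.2, seed = 1, K = 4) {
  simulate_cluster_panel(c(0.3, 0.4, 0.3), cluster_fixture_mu(K), diag(K), n,
                         missing_rate = missing_rate, seed = seed)
}
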