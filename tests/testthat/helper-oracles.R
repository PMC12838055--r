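# Shared fixtures and independent reference implementations used as oracles.

# Draw n samples from N(0, Sigma) via Cholesky (deterministic given the seed).
rmvn <- function(n, Sigma, seed) {
  p <- ncol(Sigma)
  withr::with_seed(seed, matrix(rnorm(n * p), n) %*% chol(Sigma))
}

# Correlation matrix implied by a chain-graph precision matrix with equal
# partial correlations `rho` between neighbors.
chain_sigma <- function(p, rho) {
  Theta <- diag(p)
  for (i in seq_len(p - 1)) Theta[i, i + 1] <- Theta[i + 1, i] <- -rho
  cov2cor(solve(Theta))
}

# Naive nested-loop reference for the records -> standardized composites
# path: explicit cosines, explicit per-person means, explicit column
# standardization. Deliberately slow and independent of the package's
# vectorized path.
naive_composites <- function(records, lexicon, emb) {
  keep <- list()
  for (pid in unique(records$pid)) {
    rows <- records[records$pid == pid, ]
    seen <- character(0)
    terms <- character(0)
    for (i in seq_len(nrow(rows))) {
      t_norm <- tolower(trimws(gsub("\\s+", " ", rows$raw_term[i])))
      if (t_norm %in% c("nan", "n/a", "", "lorem", "click here")) next
      if (t_norm %in% seen) next
      seen <- c(seen, t_norm)
      terms <- c(terms, t_norm)
    }
    keep[[pid]] <- terms
  }
  pids <- names(keep)[vapply(keep, length, 1L) > 0]
  facets <- lexicon$facets
  X <- matrix(NA_real_, length(pids), length(facets),
              dimnames = list(pids, facets))
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  for (pid in pids) {
    for (f in facets) {
      svals <- numeric(0)
      for (term in keep[[pid]]) {
        et <- drop(embed_text(emb, term))
        sims <- numeric(0)
        for (a in lexicon$anchors[[f]]) {
          sims <- c(sims, cosv(et, drop(embed_text(emb, a))))
        }
        svals <- c(svals, mean(sims))
      }
      X[pid, f] <- mean(svals)
    }
  }
  Z <- X
  for (f in facets) {
    mu <- mean(X[, f]); s <- sd(X[, f])
    Z[, f] <- if (s > 0) (X[, f] - mu) / s else 0
  }
  list(X = X, Z = Z)
}

# Direct double-loop distance correlation (Szekely's V-statistic formulas).
naive_dcor <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  A <- as.matrix(dist(X)); B <- as.matrix(dist(Y))
  Ac <- A - outer(rowMeans(A), rep(1, n)) - outer(rep(1, n), colMeans(A)) + mean(A)
  Bc <- B - outer(rowMeans(B), rep(1, n)) - outer(rep(1, n), colMeans(B)) + mean(B)
  dcov2 <- sum(Ac * Bc) / n^2
  dvx <- sum(Ac * Ac) / n^2
  dvy <- sum(Bc * Bc) / n^2
  sqrt(dcov2 / sqrt(dvx * dvy))
}

parallel_R <- function(k, r) { R <- matrix(r, k, k); diag(R) <- 1; R }

# Small anchor lexicon + geometric embedding for scoring tests.
tiny_cohort <- function(n_persons = 8, seed = 11, ...) {
  cfg <- sim_config(n_persons = n_persons, n_domains = 2, facets_per_domain = 3,
                    vocab_per_facet = 4, anchors_per_facet = 3, embed_dim = 16,
                    terms_per_person = 6, seed = seed, ...)
  simulate_cohort(cfg)
}

random_orthogonal <- function(d, seed) {
  withr::with_seed(seed, qr.Q(qr(matrix(rnorm(d * d), d))))
}
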