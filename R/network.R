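#' Spearman correlation matrix
#'
#' Pairwise Spearman rank correlations (average ranks for ties), used as the
#' input to regularized partial-correlation estimation because rank-based
#' association is robust to zero inflation and non-normal margins.
#'
#' @param data person x node numeric matrix (n >= 3 rows).
#' @return symmetric correlation matrix with unit diagonal; columns with zero
#'   variance get NA correlations and are listed in attribute
#'   `flagged_nodes`.
#' @export
spearman_matrix <- function(data) {
  data <- as.matrix(data)
  stopifnot(nrow(data) >= 3)
  sds <- apply(data, 2, sd)
  R <- suppressWarnings(cor(data, method = "spearman"))
  diag(R) <- 1
  flagged <- colnames(data)[!is.na(sds) & sds == 0]
  if (length(flagged)) {
    R[, sds == 0] <- NA
    R[sds == 0, ] <- NA
    diag(R) <- 1
  }
  attr(R, "flagged_nodes") <- flagged
  R
}

#' Nearest positive-definite repair
#'
#' Clips eigenvalues at 1e-6 and rescales to unit diagonal. An input that is
#' already positive definite passes through unchanged.
#'
#' @param R symmetric matrix.
#' @return positive-definite matrix with unit diagonal.
#' @export
nearest_pd <- function(R) {
  R <- (R + t(R)) / 2
  e <- eigen(R, symmetric = TRUE)
  eps <- 1e-6
  if (min(e$values) >= eps) return(R)
  vals <- pmax(e$values, eps)
  out <- e$vectors %*% diag(vals) %*% t(e$vectors)
  d <- sqrt(diag(out))
  out <- out / outer(d, d)
  (out + t(out)) / 2
}

#' EBIC-selected graphical-lasso network
#'
#' Fits the graphical lasso along a logarithmically spaced penalty path from
#' `lambda_max` (the smallest penalty giving an empty graph) down to
#' `0.01 * lambda_max`, scores each solution with the extended BIC
#' `-2 loglik + E log(n) + 4 E gamma log(p)` (E = number of edges), and
#' returns the partial-correlation network at the minimizing penalty.
#'
#' @param R correlation matrix (repaired to positive definite internally).
#' @param n sample size behind `R`.
#' @param gamma EBIC hyperparameter; 0 reduces to ordinary BIC.
#' @param n_lambda number of path points.
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`.
#' @return A `network_model`: `nodes`, `W` (partial correlations, zero
#'   diagonal), `lambda_selected`, `gamma`, `input_corr`, `path` (lambda,
#'   edges, ebic per path point).
#' @export
ebic_glasso <- function(R, n, gamma = 0.5, n_lambda = 100,
                        lambda_min_ratio = 0.01) {
  stopifnot(nrow(R) == ncol(R), n > 1)
  nodes <- colnames(R)
  if (is.null(nodes)) nodes <- paste0("v", seq_len(ncol(R)))
  S <- nearest_pd(R)
  p <- ncol(S)
  lam_max <- max(abs(S[upper.tri(S)]))
  if (lam_max == 0) lam_max <- 0.1  # independence input: any path works
  lambdas <- exp(seq(log(lam_max), log(lam_max * lambda_min_ratio),
                     length.out = n_lambda))
  # EBIC scores each candidate support by its maximized (refit) likelihood:
  # a constrained MLE with zero penalty on active edges and a prohibitive
  # penalty elsewhere. Scoring the shrunken estimate instead lets the
  # shrinkage bias of strong edges masquerade as fit gain and over-selects
  # density.
  refit_cache <- new.env(parent = emptyenv())
  refit_ll <- function(active_ut, warm) {
    key <- paste0("k", paste(which(active_ut), collapse = ","))
    hit <- get0(key, envir = refit_cache, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    Rho <- matrix(1e9, p, p)
    act <- matrix(FALSE, p, p)
    act[upper.tri(act)] <- active_ut
    act <- act | t(act)
    Rho[act] <- 0
    Wr <- glasso_mat_cpp(S, Rho, W0 = warm$W, B0 = warm$B)$W
    # at the constrained MLE, S and W agree wherever Theta is nonzero, so
    # tr(S Theta) = p and loglik = -(n/2)(log det W + p)
    ll <- -(n / 2) * (as.numeric(determinant(Wr, logarithm = TRUE)$modulus) + p)
    if (!is.finite(ll)) ll <- -Inf
    assign(key, ll, envir = refit_cache)
    ll
  }
  fits <- vector("list", n_lambda)
  ebic <- edges <- numeric(n_lambda)
  warm <- list(W = NULL, B = NULL)
  for (i in seq_along(lambdas)) {
    fit <- glasso_cpp(S, lambdas[i], W0 = warm$W, B0 = warm$B)
    warm <- list(W = fit$W, B = fit$B)
    active <- abs(fit$partials[upper.tri(fit$partials)]) > 1e-10
    E <- sum(active)
    ebic[i] <- -2 * refit_ll(active, fit) + E * log(n) + 4 * E * gamma * log(p)
    edges[i] <- E
    fits[[i]] <- fit
  }
  best <- which.min(ebic)
  W <- fits[[best]]$partials
  W[abs(W) <= 1e-10] <- 0
  dimnames(W) <- list(nodes, nodes)
  structure(list(nodes = nodes, W = W, lambda_selected = lambdas[best],
                 gamma = gamma, input_corr = R,
                 path = data.frame(lambda = lambdas, edges = edges,
                                   ebic = ebic)),
            class = "network_model")
}

#' Network from raw data
#'
#' Convenience wrapper: Spearman matrix, positive-definite repair, then
#' [ebic_glasso()].
#'
#' @param data person x node matrix.
#' @param ... passed to [ebic_glasso()].
#' @return a `network_model`.
#' @export
estimate_network <- function(data, ...) {
  ebic_glasso(spearman_matrix(data), n = nrow(as.matrix(data)), ...)
}

#' Facet-facet similarity network
#'
#' Builds a `network_model` whose edge weights are the cosine similarities
#' between facet configurations (each facet = mean of its anchor embeddings).
#' This is the graph on which the modular five-domain organization of a
#' lexicon's semantic space is assessed.
#'
#' @param lexicon an [anchor_lexicon()].
#' @param emb an `embedding_provider`.
#' @return a `network_model` (complete weighted graph, zero diagonal).
#' @export
facet_similarity_network <- function(lexicon, emb) {
  config <- t(vapply(lexicon$facets, function(f) {
    colMeans(unit_rows(embed_text(emb, lexicon$anchors[[f]])))
  }, numeric(emb$dim)))
  U <- unit_rows(config)
  W <- U %*% t(U)
  diag(W) <- 0
  W <- (W + t(W)) / 2
  dimnames(W) <- list(lexicon$facets, lexicon$facets)
  structure(list(nodes = lexicon$facets, W = W, lambda_selected = NA_real_,
                 gamma = NA_real_, input_corr = NULL),
            class = "network_model")
}

net_graph <- function(net) {
  A <- abs(net$W)
  igraph::graph_from_adjacency_matrix(A, mode = "undirected", weighted = TRUE,
                                      diag = FALSE)
}

#' Node centralities
#'
#' Strength is the sum of absolute edge weights at the node. Betweenness and
#' closeness use edge lengths `1 / |w|` (stronger edges are shorter);
#' closeness is harmonic, so disconnected pairs contribute zero.
#'
#' @param net a `network_model`.
#' @return matrix nodes x c(strength, betweenness, closeness).
#' @export
centralities <- function(net) {
  p <- length(net$nodes)
  out <- matrix(0, p, 3, dimnames = list(net$nodes,
                                         c("strength", "betweenness", "closeness")))
  g <- net_graph(net)
  if (igraph::ecount(g) == 0) return(out)
  len <- 1 / igraph::E(g)$weight
  out[, "strength"] <- rowSums(abs(net$W))
  out[, "betweenness"] <- igraph::betweenness(g, weights = len)
  out[, "closeness"] <- igraph::harmonic_centrality(g, weights = len)
  out
}

#' Case-dropping centrality-stability coefficient
#'
#' For each drop proportion in the grid, re-estimates the network on random
#' person subsamples and correlates subsample centralities with the
#' full-sample ones. The CS coefficient is the largest drop proportion at
#' which that correlation stays at or above `threshold` in at least
#' `confidence` of the resamples; 0 if none. Grid levels whose retained
#' sample would fall below `3 * p` cases are truncated.
#'
#' @param data person x node matrix.
#' @param index `"strength"`, `"betweenness"` or `"closeness"`.
#' @param n_boot total resamples, split evenly across the grid.
#' @param drop_grid drop proportions.
#' @param threshold,confidence CS rule parameters.
#' @param seed master seed.
#' @param ... passed to [estimate_network()] (e.g. a shorter lambda path).
#' @return CS value with attribute `detail` (per-drop pass proportions).
#' @export
case_drop_cs <- function(data, index = "strength", n_boot = 1000,
                         drop_grid = seq(0.05, 0.75, by = 0.05),
                         threshold = 0.7, confidence = 0.95, seed = 1L, ...) {
  data <- as.matrix(data)
  if (!index %in% c("strength", "betweenness", "closeness"))
    stop("unknown centrality index: ", index)
  n <- nrow(data); p <- ncol(data)
  keep <- round(n * (1 - drop_grid)) >= 3 * p
  if (!all(keep))
    message("drop grid truncated at ",
            max(drop_grid[keep], 0), ": subsamples need >= 3p cases")
  grid <- drop_grid[keep]
  if (!length(grid)) return(structure(0, detail = NULL))
  full <- estimate_network(data, ...)
  cent0 <- centralities(full)[, index]
  reps_per <- max(2L, floor(n_boot / length(grid)))
  pass <- vapply(seq_along(grid), function(gi) {
    m <- round(n * (1 - grid[gi]))
    ok <- vapply(seq_len(reps_per), function(b) {
      idx <- with_seed(derive_seed(seed, gi * 100000L + b),
                       sample.int(n, m, replace = FALSE))
      sub <- tryCatch(estimate_network(data[idx, , drop = FALSE], ...),
                      error = function(e) NULL)
      if (is.null(sub)) return(FALSE)
      cs <- centralities(sub)[, index]
      if (sd(cs) == 0 || sd(cent0) == 0) return(FALSE)
      cor(cent0, cs) >= threshold
    }, logical(1))
    mean(ok)
  }, numeric(1))
  ok_grid <- grid[pass >= confidence]
  cs <- if (length(ok_grid)) max(ok_grid) else 0
  structure(cs, detail = data.frame(drop = grid, pass = pass))
}

#' Edge-weight bootstrap
#'
#' Resamples persons with replacement, re-estimates the network per
#' replicate, and summarizes edge reproducibility: mean retention of the
#' full-sample edges, the median (over replicates) Pearson correlation
#' between full-sample and replicate upper-triangle weights, and percentile
#' CIs per edge.
#'
#' @param data person x node matrix.
#' @param n_boot replicates.
#' @param seed master seed.
#' @param level CI level for per-edge intervals.
#' @param ... passed to [estimate_network()].
#' @return list with `edge_mean_retention`, `edge_median_weight_corr`,
#'   `edge_ci` (edge x low/high), `n_boot`, `full` network.
#' @export
edge_bootstrap <- function(data, n_boot = 1000, seed = 1L, level = 0.95, ...) {
  data <- as.matrix(data)
  n <- nrow(data)
  full <- estimate_network(data, ...)
  ut <- upper.tri(full$W)
  w_full <- full$W[ut]
  nz <- which(w_full != 0)
  boot_w <- matrix(NA_real_, n_boot, sum(ut))
  for (b in seq_len(n_boot)) {
    idx <- with_seed(derive_seed(seed, b), sample.int(n, n, replace = TRUE))
    net <- tryCatch(estimate_network(data[idx, , drop = FALSE], ...),
                    error = function(e) NULL)
    if (!is.null(net)) boot_w[b, ] <- net$W[ut]
  }
  boot_w <- boot_w[stats::complete.cases(boot_w), , drop = FALSE]
  if (!length(nz)) {
    warning("full-sample network is empty: edge retention undefined")
    retention <- NA_real_
  } else {
    retention <- mean(colMeans(boot_w[, nz, drop = FALSE] != 0))
  }
  wcorr <- apply(boot_w, 1, function(w) {
    if (sd(w) == 0 || sd(w_full) == 0) NA_real_ else cor(w_full, w)
  })
  alpha <- (1 - level) / 2
  ci <- t(apply(boot_w, 2, quantile, probs = c(alpha, 1 - alpha)))
  pairs <- which(ut, arr.ind = TRUE)
  rownames(ci) <- paste(full$nodes[pairs[, 1]], full$nodes[pairs[, 2]],
                        sep = "--")
  list(edge_mean_retention = retention,
       edge_median_weight_corr = stats::median(wcorr, na.rm = TRUE),
       edge_ci = ci, n_boot = nrow(boot_w), full = full)
}

#' Louvain community detection
#'
#' Runs seeded Louvain on absolute edge weights, best of `restarts` by
#' modularity. An empty network returns singleton communities with Q = 0.
#'
#' @param net a `network_model`.
#' @param resolution Louvain resolution parameter.
#' @param seed master seed (restart r uses a derived seed).
#' @param restarts number of restarts.
#' @return A `community_partition`: `membership` (node -> contiguous integer
#'   label), `Q`, `resolution`, `seed`.
#' @export
louvain_communities <- function(net, resolution = 1, seed = 1L, restarts = 20) {
  g <- net_graph(net)
  p <- length(net$nodes)
  if (igraph::ecount(g) == 0) {
    return(structure(list(membership = setNames(seq_len(p), net$nodes),
                          Q = 0, resolution = resolution, seed = seed),
                     class = "community_partition"))
  }
  best <- NULL; bestq <- -Inf
  for (r in seq_len(restarts)) {
    cl <- with_seed(derive_seed(seed, r),
                    igraph::cluster_louvain(g, resolution = resolution))
    q <- igraph::modularity(g, igraph::membership(cl),
                            weights = igraph::E(g)$weight)
    if (q > bestq) { bestq <- q; best <- cl }
  }
  memb <- as.integer(igraph::membership(best))
  memb <- as.integer(factor(memb, levels = unique(memb)))
  structure(list(membership = setNames(memb, net$nodes), Q = bestq,
                 resolution = resolution, seed = seed),
            class = "community_partition")
}

#' Global connectivity metrics
#'
#' @param net a `network_model`.
#' @return list: `global_strength` (sum of absolute upper-triangle weights)
#'   and `density` (realized edges over possible edges).
#' @export
global_metrics <- function(net) {
  ut <- net$W[upper.tri(net$W)]
  list(global_strength = sum(abs(ut)),
       density = if (length(ut)) mean(ut != 0) else 0)
}

#' Bootstrapped structure-recovery frequency
#'
#' Fraction of person-resampled replicates whose Louvain partition has the
#' same number of communities as the reference and adjusted Rand >= 0.8
#' against it — the dimensional-recovery reliability of the network.
#'
#' @param data person x node matrix.
#' @param reference a `community_partition` (defaults to the full-sample one).
#' @param n_boot replicates.
#' @param seed master seed.
#' @param resolution,restarts Louvain settings.
#' @param ... passed to [estimate_network()].
#' @return recovery frequency in \[0, 1\].
#' @export
structure_recovery_frequency <- function(data, reference = NULL, n_boot = 200,
                                         seed = 1L, resolution = 1,
                                         restarts = 5, ...) {
  data <- as.matrix(data)
  n <- nrow(data)
  if (is.null(reference)) {
    reference <- louvain_communities(estimate_network(data, ...),
                                     resolution = resolution,
                                     seed = seed, restarts = restarts)
  }
  ref <- reference$membership
  hits <- vapply(seq_len(n_boot), function(b) {
    idx <- with_seed(derive_seed(seed, 500000L + b),
                     sample.int(n, n, replace = TRUE))
    net <- tryCatch(estimate_network(data[idx, , drop = FALSE], ...),
                    error = function(e) NULL)
    if (is.null(net)) return(FALSE)
    part <- louvain_communities(net, resolution = resolution,
                                seed = derive_seed(seed, 600000L + b),
                                restarts = restarts)
    m <- part$membership
    length(unique(m)) == length(unique(ref)) && adjusted_rand(ref, m) >= 0.8
  }, logical(1))
  mean(hits)
}
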