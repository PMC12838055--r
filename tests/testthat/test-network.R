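test_that("spearman matrix matches rank-then-Pearson with ties", {
  X <- withr::with_seed(3, matrix(sample(1:4, 20, replace = TRUE), 5, 4))
  S <- spearman_matrix(X)
  ranked <- apply(X, 2, rank)
  expect_equal(unname(S), unname(cor(ranked)), tolerance = 1e-12)
  # monotone invariance and reversal
  x <- rnorm(10)
  expect_equal(spearman_matrix(cbind(x, exp(x), -x))[1, 2], 1)
  expect_equal(spearman_matrix(cbind(x, exp(x), -x))[1, 3], -1)
})

test_that("nearest_pd is a no-op on PD input and repairs indefinite input", {
  expect_equal(nearest_pd(diag(3)), diag(3), tolerance = 1e-14)
  R <- parallel_R(4, 0.3)
  expect_equal(nearest_pd(R), R, tolerance = 1e-12)
  bad <- matrix(c(1, 0.9, 0.1, 0.9, 1, 0.9, 0.1, 0.9, 1), 3)
  bad[1, 3] <- bad[3, 1] <- -0.8  # min eigenvalue < 0
  fixed <- nearest_pd(bad)
  expect_gte(min(eigen(fixed)$values), 1e-7)
  expect_equal(unname(diag(fixed)), rep(1, 3), tolerance = 1e-12)
})

test_that("glasso at vanishing penalty matches analytic partial correlations", {
  R3 <- matrix(c(1, .5, .3, .5, 1, .4, .3, .4, 1), 3)
  Th <- solve(R3)
  P <- -Th / sqrt(outer(diag(Th), diag(Th)))
  diag(P) <- 0
  fit <- semanchor:::glasso_cpp(R3, 1e-8)
  expect_equal(fit$partials, P, tolerance = 1e-6)
})

test_that("identity input yields an empty network and independence data near-empty", {
  net <- ebic_glasso(diag(5), n = 100)
  expect_true(all(net$W == 0))
  expect_equal(global_metrics(net), list(global_strength = 0, density = 0))
})

test_that("EBIC glasso recovers a sparse chain support", {
  Sig <- chain_sigma(10, 0.3)
  X <- rmvn(800, Sig, seed = 71)
  net <- estimate_network(X)
  Theta <- diag(10); for (i in 1:9) Theta[i, i + 1] <- Theta[i + 1, i] <- -0.3
  est <- abs(net$W) > 0 & upper.tri(net$W)
  tru <- abs(Theta) > 0 & upper.tri(Theta)
  sens <- sum(est & tru) / sum(tru)
  fpr <- sum(est & !tru) / sum(!tru & upper.tri(Theta))
  expect_gte(sens, 0.9)
  expect_lte(fpr, 0.1)
  # edge count non-increasing in lambda along the path
  expect_true(all(diff(net$path$edges) >= 0))  # path runs lambda_max -> small
})

test_that("EBIC at gamma 0 equals BIC", {
  Sig <- chain_sigma(6, 0.3)
  X <- rmvn(300, Sig, seed = 5)
  R <- nearest_pd(spearman_matrix(X))
  n0 <- ebic_glasso(R, 300, gamma = 0, n_lambda = 20)
  # recompute BIC from the path loglik relation: ebic(gamma=0) must equal
  # ebic(gamma=g) - 4 E g log p for every path point
  ng <- ebic_glasso(R, 300, gamma = 0.5, n_lambda = 20)
  expect_equal(n0$path$ebic,
               ng$path$ebic - 4 * ng$path$edges * 0.5 * log(6),
               tolerance = 1e-8)
})

test_that("centralities match hand computation on a 3-node line", {
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 0.5
  W["b", "c"] <- W["c", "b"] <- 0.5
  net <- structure(list(nodes = c("a", "b", "c"), W = W),
                   class = "network_model")
  cen <- centralities(net)
  expect_equal(unname(cen[, "strength"]), c(0.5, 1.0, 0.5))
  expect_equal(unname(cen[, "betweenness"]), c(0, 1, 0))
  # harmonic closeness with lengths 1/0.5 = 2: a: 1/2 + 1/4; b: 1/2 + 1/2
  expect_equal(unname(cen[, "closeness"]), c(0.75, 1, 0.75))
  # fully connected equal weights: full symmetry
  Wf <- matrix(0.2, 4, 4); diag(Wf) <- 0
  dimnames(Wf) <- rep(list(letters[1:4]), 2)
  cenf <- centralities(structure(list(nodes = letters[1:4], W = Wf),
                                 class = "network_model"))
  for (j in 1:3) expect_equal(length(unique(round(cenf[, j], 10))), 1)
})

test_that("empty networks give zero centralities", {
  net <- structure(list(nodes = c("a", "b"), W = matrix(0, 2, 2)),
                   class = "network_model")
  expect_true(all(centralities(net) == 0))
})

test_that("case-dropping CS hits the grid maximum for a planted hub and zero for noise", {
  p <- 8
  Theta <- diag(p)
  for (j in 2:5) Theta[1, j] <- Theta[j, 1] <- -0.35
  Theta[6, 7] <- Theta[7, 6] <- -0.15
  Sig <- cov2cor(solve(nearest_pd(Theta)))
  X <- rmvn(1000, Sig, seed = 2)
  cs <- case_drop_cs(X, "strength", n_boot = 150, seed = 11, n_lambda = 30)
  expect_equal(as.numeric(cs), 0.75)
  Xn <- withr::with_seed(4, matrix(rnorm(100 * 8), 100))
  csn <- case_drop_cs(Xn, "strength", n_boot = 150, seed = 12, n_lambda = 30)
  expect_equal(as.numeric(csn), 0)
  expect_identical(as.numeric(case_drop_cs(Xn, "strength", n_boot = 60,
                                           seed = 7, n_lambda = 20)),
                   as.numeric(case_drop_cs(Xn, "strength", n_boot = 60,
                                           seed = 7, n_lambda = 20)))
  expect_error(case_drop_cs(Xn, "pagerank"), "unknown")
})

test_that("edge bootstrap retains strong-signal edges and is seed-stable", {
  Theta <- diag(6)
  Theta[1, 2] <- Theta[2, 1] <- -0.6
  Theta[3, 4] <- Theta[4, 3] <- -0.6
  Theta[5, 6] <- Theta[6, 5] <- -0.6
  X <- rmvn(2000, cov2cor(solve(nearest_pd(Theta))), seed = 13)
  eb1 <- edge_bootstrap(X, n_boot = 60, seed = 3, n_lambda = 30)
  expect_gte(eb1$edge_mean_retention, 0.99)
  expect_gte(eb1$edge_median_weight_corr, 0.9)
  eb2 <- edge_bootstrap(X, n_boot = 60, seed = 3, n_lambda = 30)
  expect_identical(eb1$edge_mean_retention, eb2$edge_mean_retention)
  # identity data: no edges, retention missing
  Xi <- withr::with_seed(9, matrix(rnorm(200 * 4), 200))
  expect_warning(ebi <- edge_bootstrap(Xi, n_boot = 10, seed = 1,
                                       n_lambda = 20), "empty")
  expect_true(is.na(ebi$edge_mean_retention))
})

test_that("Louvain finds two 5-cliques with Q = 0.5 and one block when complete", {
  W <- matrix(0, 10, 10)
  W[1:5, 1:5] <- 0.3; W[6:10, 6:10] <- 0.3
  diag(W) <- 0
  dimnames(W) <- rep(list(paste0("v", 1:10)), 2)
  net <- structure(list(nodes = paste0("v", 1:10), W = W),
                   class = "network_model")
  part <- louvain_communities(net, seed = 4)
  expect_equal(length(unique(part$membership)), 2)
  expect_equal(part$Q, 0.5, tolerance = 1e-12)
  # one community on the complete equal-weight graph
  Wc <- matrix(0.2, 6, 6); diag(Wc) <- 0
  dimnames(Wc) <- rep(list(paste0("n", 1:6)), 2)
  pc <- louvain_communities(structure(list(nodes = paste0("n", 1:6), W = Wc),
                                      class = "network_model"), seed = 4)
  expect_equal(length(unique(pc$membership)), 1)
  # empty network: singletons, Q = 0
  pe <- louvain_communities(structure(list(nodes = c("a", "b"),
                                           W = matrix(0, 2, 2)),
                                      class = "network_model"))
  expect_equal(unname(pe$membership), c(1, 2))
  expect_equal(pe$Q, 0)
})

test_that("planted five-domain cohort is recovered by Louvain", {
  co <- simulate_cohort(sim_config(n_persons = 300, domain_cohesion = 0.8,
                                   seed = 42))
  # on the facet-facet similarity graph of the lexicon's semantic space
  netf <- facet_similarity_network(co$anchor_lexicon, co$embedding)
  pf <- louvain_communities(netf, seed = 3)
  truth <- co$ground_truth_partition[netf$nodes]
  expect_equal(length(unique(pf$membership)), 5)
  expect_gt(adjusted_rand(pf$membership, truth), 0.9)
  # and on the person-score partial-correlation network
  cm <- build_composites(co$term_records, co$anchor_lexicon, co$embedding)
  net <- estimate_network(cm$Z, n_lambda = 30)
  ps <- louvain_communities(net, seed = 3)
  expect_gt(adjusted_rand(ps$membership, co$ground_truth_partition[net$nodes]),
            0.9)
})

test_that("adjusted Rand agrees with the mclust reference", {
  skip_if_not_installed("mclust")
  a <- withr::with_seed(8, sample(1:4, 60, replace = TRUE))
  b <- withr::with_seed(9, sample(1:3, 60, replace = TRUE))
  expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
               tolerance = 1e-12)
  expect_equal(adjusted_rand(a, a), 1)
})

test_that("structure recovery frequency separates signal from noise", {
  co <- simulate_cohort(sim_config(n_persons = 300, seed = 6))
  cm <- build_composites(co$term_records, co$anchor_lexicon, co$embedding)
  f_sig <- structure_recovery_frequency(cm$Z, n_boot = 25, seed = 3,
                                        n_lambda = 25)
  expect_gte(f_sig, 0.9)
  Xn <- withr::with_seed(10, matrix(rnorm(100 * 10), 100))
  f_noise <- structure_recovery_frequency(Xn, n_boot = 25, seed = 3,
                                          n_lambda = 25)
  expect_lte(f_noise, 0.3)
  expect_identical(structure_recovery_frequency(Xn, n_boot = 10, seed = 5,
                                                n_lambda = 20),
                   structure_recovery_frequency(Xn, n_boot = 10, seed = 5,
                                                n_lambda = 20))
})

test_that("global metrics on a complete 4-node graph match the closed form", {
  W <- matrix(0.2, 4, 4); diag(W) <- 0
  net <- structure(list(nodes = paste0("v", 1:4), W = W),
                   class = "network_model")
  gm <- global_metrics(net)
  expect_equal(gm$global_strength, 1.2)
  expect_equal(gm$density, 1)
})
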