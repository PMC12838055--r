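center_cols <- function(M) sweep(as.matrix(M), 2, colMeans(as.matrix(M)), "-")

#' Person-level convergent/discriminant correlations
#'
#' Cross-correlates two sets of domain composites (Pearson and Spearman,
#' pairwise-complete per cell), summarizes the matched diagonal, and scans
#' the facet-level cross-correlation matrix for the largest absolute
#' correlation among cells with adequate pairwise n.
#'
#' @param dm_domains person x domain matrix (rownames = person ids).
#' @param b5_domains person x domain matrix for the comparison instrument.
#' @param matching named character vector mapping each `dm_domains` column to
#'   a `b5_domains` column; defaults to identical column names.
#' @param dm_facets,b5_facets optional person x facet matrices for the
#'   facet-level scan.
#' @param min_n minimum pairwise n for a facet cell to enter the max scan.
#' @return A `convergence_report`.
#' @export
convergence_matrix <- function(dm_domains, b5_domains, matching = NULL,
                               dm_facets = NULL, b5_facets = NULL,
                               min_n = 10) {
  ids <- intersect(rownames(dm_domains), rownames(b5_domains))
  if (length(ids) < min_n)
    stop("need at least ", min_n, " overlapping persons; found ", length(ids))
  X <- as.matrix(dm_domains[ids, , drop = FALSE])
  Y <- as.matrix(b5_domains[ids, , drop = FALSE])
  if (is.null(matching))
    matching <- setNames(colnames(X), colnames(X))
  stopifnot(all(names(matching) %in% colnames(X)),
            all(matching %in% colnames(Y)))

  pear <- suppressWarnings(cor(X, Y, use = "pairwise.complete.obs"))
  spear <- suppressWarnings(cor(X, Y, use = "pairwise.complete.obs",
                                method = "spearman"))
  diag_r <- vapply(names(matching), function(d) pear[d, matching[[d]]],
                   numeric(1))
  diag_rho <- vapply(names(matching), function(d) spear[d, matching[[d]]],
                     numeric(1))

  facet_block <- NULL
  if (!is.null(dm_facets) && !is.null(b5_facets)) {
    fid <- intersect(rownames(dm_facets), rownames(b5_facets))
    FX <- as.matrix(dm_facets[fid, , drop = FALSE])
    FY <- as.matrix(b5_facets[fid, , drop = FALSE])
    fr <- suppressWarnings(cor(FX, FY, use = "pairwise.complete.obs"))
    nmat <- crossprod(!is.na(FX) + 0, !is.na(FY) + 0)
    ok <- nmat >= min_n & !is.na(fr)
    max_cell <- if (any(ok)) {
      w <- which(ok & abs(fr) == max(abs(fr[ok])), arr.ind = TRUE)[1, , drop = TRUE]
      list(value = fr[w[1], w[2]], dm_facet = rownames(fr)[w[1]],
           b5_facet = colnames(fr)[w[2]], n = nmat[w[1], w[2]])
    } else NULL
    facet_block <- list(corr = fr, pairwise_n = nmat, max_abs = max_cell)
  }

  structure(list(domain_corr_pearson = pear, domain_corr_spearman = spear,
                 matched_r = diag_r, matched_rho = diag_rho,
                 matched_mean_abs_r = mean(abs(diag_r)),
                 matched_range = range(diag_r),
                 facet = facet_block, n_overlap = length(ids)),
            class = "convergence_report")
}

#' RV coefficient
#'
#' Matrix correlation between two configurations' cross-product matrices,
#' computed on column-centered data; invariant to rotation and isotropic
#' scaling of either configuration.
#'
#' @param X,Y configuration matrices with the same row count.
#' @return RV in \[0, 1\].
#' @export
rv_coefficient <- function(X, Y) {
  X <- center_cols(X); Y <- center_cols(Y)
  stopifnot(nrow(X) == nrow(Y))
  if (all(X == 0) || all(Y == 0)) stop("all-zero configuration")
  Sx <- tcrossprod(X); Sy <- tcrossprod(Y)
  sum(Sx * Sy) / sqrt(sum(Sx * Sx) * sum(Sy * Sy))
}

#' Procrustes similarity
#'
#' Optimally translates, isotropically scales, and rotates/reflects `Y` onto
#' `X`, and returns `1 - m2` where `m2` is the minimized residual sum of
#' squares divided by the total variance of centered `X`. A narrower matrix
#' is padded with zero columns.
#'
#' @param X,Y configuration matrices with equal row counts.
#' @return similarity in \[0, 1\].
#' @export
procrustes_similarity <- function(X, Y) {
  X <- center_cols(X); Y <- center_cols(Y)
  stopifnot(nrow(X) == nrow(Y))
  d <- max(ncol(X), ncol(Y))
  pad <- function(M) cbind(M, matrix(0, nrow(M), d - ncol(M)))
  X <- pad(X); Y <- pad(Y)
  ssx <- sum(X^2); ssy <- sum(Y^2)
  if (ssx == 0 || ssy == 0) stop("degenerate (zero-variance) configuration")
  sv <- svd(crossprod(X, Y))
  # m2 = 1 - (sum of singular values)^2 / (ssx * ssy) after optimal scaling
  m2 <- 1 - sum(sv$d)^2 / (ssx * ssy)
  1 - m2
}

#' Sample distance correlation
#'
#' Distance correlation between the row configurations of `X` and `Y`, from
#' doubly-centered Euclidean distance matrices; detects nonlinear dependence.
#'
#' @param X,Y matrices (or vectors) with the same row count, n >= 4.
#' @return distance correlation in \[0, 1\].
#' @export
distance_correlation <- function(X, Y) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  stopifnot(n == nrow(Y), n >= 4)
  dc <- function(M) {
    D <- as.matrix(dist(M))
    if (all(D == 0)) stop("constant rows: distance correlation undefined")
    sweep(sweep(D, 1, rowMeans(D)), 2, colMeans(D)) + mean(D)
  }
  A <- dc(X); B <- dc(Y)
  dcov2 <- mean(A * B)
  dvarx <- mean(A * A); dvary <- mean(B * B)
  if (dvarx == 0 || dvary == 0) return(0)
  sqrt(max(dcov2, 0) / sqrt(dvarx * dvary))
}

#' Mantel permutation test
#'
#' Pearson correlation between the strict upper triangles of two distance
#' matrices, with a one-sided permutation p-value under simultaneous
#' row/column label permutation of `D2`:
#' `p = (#permuted r >= observed + 1) / (n_perm + 1)`.
#'
#' @param D1,D2 square symmetric zero-diagonal matrices of equal size (>= 4).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return list with `r`, `p`, `n_permutations`.
#' @export
mantel_test <- function(D1, D2, n_perm = 5000, seed = 1L) {
  D1 <- as.matrix(D1); D2 <- as.matrix(D2)
  n <- nrow(D1)
  stopifnot(n == ncol(D1), n == nrow(D2), n == ncol(D2), n >= 4,
            isSymmetric(unname(D1), tol = 1e-8),
            isSymmetric(unname(D2), tol = 1e-8),
            all(abs(diag(D1)) < 1e-12), all(abs(diag(D2)) < 1e-12))
  ut <- upper.tri(D1)
  r_obs <- cor(D1[ut], D2[ut])
  perm_r <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    ord <- sample.int(n)
    cor(D1[ut], D2[ord, ord][ut])
  }, numeric(1)))
  p <- (sum(perm_r >= r_obs) + 1) / (n_perm + 1)
  list(r = r_obs, p = p, n_permutations = n_perm)
}

#' First canonical correlation with rank-degeneracy flags
#'
#' Reduces each configuration to its leading principal components (rank at
#' most `min(cap, n - 1, p)`), runs canonical correlation analysis, and
#' returns the first canonical correlation. When the two retained ranks sum
#' to at least n, r1 = 1 is a linear-algebra certainty for generic data, so a
#' degeneracy flag is attached instead of suppressing the value.
#'
#' @param X,Y configuration matrices with equal row counts (n >= 3).
#' @param n_components_cap maximum PCs retained per side.
#' @return list with `r1` and `degeneracy_flags` (character, possibly empty).
#' @export
cca_first <- function(X, Y, n_components_cap = Inf) {
  X <- center_cols(X); Y <- center_cols(Y)
  n <- nrow(X)
  stopifnot(n == nrow(Y), n >= 3)
  reduce <- function(M) {
    sv <- svd(M)
    keep <- which(sv$d > max(sv$d) * 1e-8)
    keep <- head(keep, min(n_components_cap, n - 1))
    M %*% sv$v[, keep, drop = FALSE]
  }
  Xr <- reduce(X); Yr <- reduce(Y)
  flags <- character(0)
  if (ncol(Xr) + ncol(Yr) >= n)
    flags <- c(flags, "rank_degenerate: p_x + p_y >= n, r1 = 1 is unavoidable")
  cc <- cancor(Xr, Yr)
  r1 <- cc$cor[1]
  if (r1 > 1 - 1e-10 && !length(flags))
    flags <- c(flags, "perfect_first_canonical_correlation")
  list(r1 = r1, degeneracy_flags = flags)
}

#' Facet configurations from two anchor lexicons
#'
#' Represents each facet by the mean of its anchor-phrase embeddings and
#' aligns rows across the two lexicons by facet name (or an explicit map).
#' The resulting configurations feed the alignment indices; cosine distance
#' matrices for the Mantel test come from [cosine_distance()].
#'
#' @param lexicon_dm,lexicon_b5 [anchor_lexicon()] objects.
#' @param emb an `embedding_provider`.
#' @param correspondence named character vector mapping `lexicon_dm` facets to
#'   `lexicon_b5` facets; default matches facet names.
#' @return list with `X`, `Y` (facet x dim configurations, rows aligned) and
#'   `facets` (the DM-side facet order).
#' @export
facet_configurations <- function(lexicon_dm, lexicon_b5, emb,
                                 correspondence = NULL) {
  if (is.null(correspondence))
    correspondence <- setNames(lexicon_dm$facets, lexicon_dm$facets)
  unmatched <- setdiff(names(correspondence), lexicon_dm$facets)
  unmatched <- c(unmatched, setdiff(unname(correspondence), lexicon_b5$facets))
  if (length(unmatched))
    stop("unmatched facet(s): ", paste(unique(unmatched), collapse = ", "))
  facet_vec <- function(lex, f) {
    colMeans(unit_rows(embed_text(emb, lex$anchors[[f]])))
  }
  X <- t(vapply(names(correspondence), function(f) facet_vec(lexicon_dm, f),
                numeric(emb$dim)))
  Y <- t(vapply(unname(correspondence), function(f) facet_vec(lexicon_b5, f),
                numeric(emb$dim)))
  rownames(X) <- rownames(Y) <- names(correspondence)
  list(X = X, Y = Y, facets = names(correspondence))
}

#' Cosine distance matrix of a configuration's rows
#'
#' @param M matrix whose rows are configuration points.
#' @return symmetric zero-diagonal matrix of `1 - cosine similarity`.
#' @export
cosine_distance <- function(M) {
  U <- unit_rows(as.matrix(M))
  D <- 1 - U %*% t(U)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  D
}

#' Full configuration-alignment report
#'
#' Computes the alignment battery between two facet configurations: first
#' canonical correlation (with degeneracy flags), RV coefficient, Procrustes
#' similarity, distance correlation, and the Mantel test on cosine-distance
#' matrices.
#'
#' @param X,Y facet configuration matrices with aligned rows.
#' @param n_perm Mantel permutations.
#' @param seed RNG seed for the Mantel permutations.
#' @param cca_cap PC cap per side for the CCA step.
#' @return An `alignment_report` list.
#' @export
alignment_report <- function(X, Y, n_perm = 5000, seed = 1L, cca_cap = Inf) {
  cca <- cca_first(X, Y, n_components_cap = cca_cap)
  mt <- mantel_test(cosine_distance(X), cosine_distance(Y),
                    n_perm = n_perm, seed = seed)
  structure(list(cca_r1 = cca$r1,
                 rv = rv_coefficient(X, Y),
                 procrustes_sim = procrustes_similarity(X, Y),
                 dcor = distance_correlation(X, Y),
                 mantel_r = mt$r, mantel_p = mt$p,
                 n_permutations = n_perm,
                 degeneracy_flags = cca$degeneracy_flags),
            class = "alignment_report")
}
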