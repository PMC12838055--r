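#' Minimum-residual factor extraction
#'
#' Extracts `nfactors` common factors from a correlation matrix by minimizing
#' the sum of squared off-diagonal residuals of `R - L L'` over the
#' uniquenesses (ordinary least squares / minres). Loadings are recovered from
#' the eigendecomposition of the reduced matrix at the optimum.
#'
#' @param R correlation matrix (symmetric, unit diagonal).
#' @param nfactors number of factors to extract.
#' @return list with `loadings` (p x nfactors), `uniquenesses`, `converged`.
#' @export
fa_minres <- function(R, nfactors = 1) {
  p <- ncol(R)
  stopifnot(isSymmetric(unname(R), tol = 1e-8), nfactors >= 1, nfactors < p)
  low <- lower.tri(R)

  load_from_psi <- function(psi) {
    Rs <- R
    diag(Rs) <- 1 - psi
    e <- eigen(Rs, symmetric = TRUE)
    m <- nfactors
    vals <- pmax(e$values[seq_len(m)], 0)
    e$vectors[, seq_len(m), drop = FALSE] %*% diag(sqrt(vals), m)
  }
  objective <- function(psi) {
    L <- load_from_psi(psi)
    resid <- R - tcrossprod(L)
    sum(resid[low]^2)
  }
  # start at 1 - squared multiple correlation
  Rinv <- tryCatch(solve(R), error = function(e) solve(nearest_pd(R)))
  start <- pmin(pmax(1 / diag(Rinv), 0.05), 0.95)
  fit <- optim(start, objective, method = "L-BFGS-B",
               lower = rep(0.005, p), upper = rep(0.995, p),
               control = list(maxit = 500))
  L <- load_from_psi(fit$par)
  # orient each factor so its loading sum is non-negative
  for (j in seq_len(ncol(L))) if (sum(L[, j]) < 0) L[, j] <- -L[, j]
  rownames(L) <- colnames(R)
  list(loadings = L, uniquenesses = setNames(fit$par, colnames(R)),
       converged = fit$convergence == 0, objective = fit$value)
}

#' Schmid-Leiman decomposition
#'
#' Extracts `n_groups` group factors by minres, rotates them obliquely
#' (promax), fits a single higher-order factor to the group-factor correlation
#' matrix, and orthogonalizes: every indicator's oblique loading is split into
#' a general-factor part and an orthogonal group-specific part.
#'
#' @param R correlation matrix over the indicators.
#' @param n_groups number of group factors (at least 2; with fewer the
#'   hierarchical partition is not identified).
#' @return A `schmid_leiman` solution: `general_loadings`, `group_loadings`
#'   (indicator x group), `uniquenesses`, `n_groups`, `phi` (group factor
#'   correlations), `second_order_loadings`.
#' @export
schmid_leiman <- function(R, n_groups) {
  if (n_groups < 2)
    stop("hierarchical partitioning unstable: need at least 2 group factors")
  p <- ncol(R)
  if (p < 2 * n_groups)
    warning("fewer than 2 indicators per group factor; solution may be unstable")
  fit <- fa_minres(R, n_groups)
  hier <- tryCatch({
    pr <- promax(fit$loadings)
    P <- unclass(pr$loadings)                # oblique pattern matrix
    phi <- solve(crossprod(pr$rotmat))       # group-factor correlations
    phi <- (phi + t(phi)) / 2
    if (any(!is.finite(phi)) || any(abs(phi[upper.tri(phi)]) > 0.999))
      stop("group factors collinear")
    g2 <- fa_minres(phi, 1)
    gamma <- pmin(pmax(drop(g2$loadings), -1), 1)
    list(P = P, phi = phi, gamma = gamma)
  }, error = function(e) NULL)
  if (is.null(hier)) {
    # rotation degenerate (effectively one common factor): all common
    # variance is general, group parts vanish
    one <- fa_minres(R, 1)
    hier <- list(P = cbind(drop(one$loadings),
                           matrix(0, p, n_groups - 1)),
                 phi = diag(n_groups),
                 gamma = c(1, rep(0, n_groups - 1)))
  }
  P <- hier$P; phi <- hier$phi; gamma <- hier$gamma
  general <- drop(P %*% gamma)
  if (sum(general) < 0) { gamma <- -gamma; general <- -general }
  group <- P %*% diag(sqrt(pmax(1 - gamma^2, 0)), n_groups)
  h2 <- general^2 + rowSums(group^2)
  structure(list(general_loadings = setNames(general, colnames(R)),
                 group_loadings = group,
                 uniquenesses = setNames(pmax(1 - h2, 0), colnames(R)),
                 n_groups = n_groups, phi = phi,
                 second_order_loadings = gamma),
            class = "schmid_leiman")
}

#' McDonald's omega total
#'
#' Proportion of composite variance attributable to all common factors. With
#' only `R`, a single factor is extracted and
#' `omega = (sum lambda)^2 / ((sum lambda)^2 + sum psi)`. With a
#' Schmid-Leiman solution, the general and group factors all count as common
#' variance.
#'
#' @param R correlation matrix (ignored when `sl` is supplied).
#' @param sl optional [schmid_leiman()] solution.
#' @return omega total in \[0, 1\].
#' @export
omega_total <- function(R = NULL, sl = NULL) {
  if (!is.null(sl)) {
    stopifnot(inherits(sl, "schmid_leiman"))
    gen <- sum(sl$general_loadings)^2
    grp <- sum(colSums(sl$group_loadings)^2)
    return((gen + grp) / (gen + grp + sum(sl$uniquenesses)))
  }
  stopifnot(!is.null(R), ncol(R) >= 2)
  fit <- fa_minres(R, 1)
  lam <- drop(fit$loadings)
  common <- sum(lam)^2
  common / (common + sum(1 - lam^2))
}

#' McDonald's omega hierarchical
#'
#' Proportion of composite variance attributable to the general factor alone,
#' from a Schmid-Leiman orthogonalization. Always `<= omega_total(sl = sl)`.
#'
#' @param sl a [schmid_leiman()] solution.
#' @return omega hierarchical in \[0, 1\].
#' @export
omega_hierarchical <- function(sl) {
  stopifnot(inherits(sl, "schmid_leiman"))
  gen <- sum(sl$general_loadings)^2
  grp <- sum(colSums(sl$group_loadings)^2)
  gen / (gen + grp + sum(sl$uniquenesses))
}

#' Percentile bootstrap confidence interval
#'
#' Resamples persons (rows) with replacement and returns percentile bounds of
#' the statistic's resample distribution. Replicate seeds are derived from the
#' master seed by counter, so replicate b is reproducible in isolation.
#' Resamples where the statistic fails are dropped and counted; more than 10%
#' failures is an error.
#'
#' @param data person x indicator matrix or data frame.
#' @param statistic function of such a matrix returning a scalar.
#' @param n_boot number of resamples.
#' @param level confidence level.
#' @param seed master seed.
#' @return numeric `c(low, high)` with attributes `n_failed`, `replicates`.
#' @export
bootstrap_ci <- function(data, statistic, n_boot = 1000, level = 0.95,
                         seed = 1L) {
  data <- as.matrix(data)
  n <- nrow(data)
  stopifnot(n >= 10, n_boot >= 2)
  reps <- vapply(seq_len(n_boot), function(b) {
    idx <- with_seed(derive_seed(seed, b), sample.int(n, n, replace = TRUE))
    tryCatch(as.numeric(statistic(data[idx, , drop = FALSE])),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * n_boot)
    stop("statistic failed on ", n_failed, " of ", n_boot, " resamples")
  alpha <- (1 - level) / 2
  ci <- unname(quantile(reps, c(alpha, 1 - alpha), na.rm = TRUE))
  attr(ci, "n_failed") <- n_failed
  attr(ci, "replicates") <- reps
  ci
}

#' Corrected indicator-total correlations and leave-one-out omega deltas
#'
#' `r_it` correlates each indicator with the sum of the remaining k-1
#' indicators; `loo_delta_omega[j]` is `omega(all) - omega(without j)` using
#' single-factor omega on the Pearson correlation matrix.
#'
#' @param data person x indicator matrix (k >= 3 columns).
#' @return list with `item_total`, `loo_delta_omega`, `omega_all`.
#' @export
item_total_diagnostics <- function(data) {
  data <- as.matrix(data)
  k <- ncol(data)
  stopifnot(k >= 3)
  sds <- apply(data, 2, sd)
  r_it <- vapply(seq_len(k), function(j) {
    if (sds[j] == 0) return(NA_real_)
    cor(data[, j], rowSums(data[, -j, drop = FALSE]))
  }, numeric(1))
  if (any(sds == 0)) warning("zero-variance indicator(s): r_it set to NA")
  ok <- sds > 0
  Rfull <- cor(data[, ok, drop = FALSE])
  om_all <- omega_total(Rfull)
  loo <- rep(NA_real_, k)
  pos <- which(ok)
  for (j in seq_along(pos)) {
    loo[pos[j]] <- om_all - omega_total(Rfull[-j, -j, drop = FALSE])
  }
  list(item_total = setNames(r_it, colnames(data)),
       loo_delta_omega = setNames(loo, colnames(data)),
       omega_all = om_all)
}

#' Two-way random-effects ICC for absolute agreement
#'
#' Classical two-way ANOVA decomposition of a complete targets x raters
#' matrix. `icc_single` is ICC(A,1) — agreement of a single rater; `icc_avg`
#' is ICC(A,k) for the mean of the k raters. Negative estimates are reported
#' as computed.
#'
#' @param ratings complete numeric matrix, targets in rows, raters in columns.
#' @return list with `icc_single`, `icc_avg`, `variance_components`.
#' @export
icc_absolute <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  stopifnot(n >= 2, k >= 2)
  if (anyNA(ratings)) stop("ratings matrix has missing cells; no imputation")
  g <- mean(ratings)
  rm_ <- rowMeans(ratings); cm_ <- colMeans(ratings)
  msr <- k * sum((rm_ - g)^2) / (n - 1)
  msc <- n * sum((cm_ - g)^2) / (k - 1)
  resid <- ratings - outer(rm_, rep(1, k)) - outer(rep(1, n), cm_) + g
  mse <- sum(resid^2) / ((n - 1) * (k - 1))
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
  icck <- (msr - mse) / (msr + (msc - mse) / n)
  list(icc_single = icc1, icc_avg = icck,
       variance_components = c(target = (msr - mse) / k,
                               rater = (msc - mse) / n,
                               error = mse))
}

#' Per-domain reliability report
#'
#' Bundles omega total (with percentile bootstrap CI), omega hierarchical when
#' enough viable group factors exist, and indicator-level diagnostics for one
#' domain's person x indicator matrix — the battery reported per trait domain.
#'
#' @param data person x indicator matrix for one domain.
#' @param domain domain label for the report.
#' @param n_groups group factors for the Schmid-Leiman step; `NA` skips
#'   omega_h (reported missing), mirroring the refusal rule for very small k.
#' @param n_boot bootstrap resamples for the omega CI.
#' @param seed master seed.
#' @return A `reliability_report` list.
#' @export
reliability_report <- function(data, domain = "domain", n_groups = 2,
                               n_boot = 1000, seed = 1L) {
  data <- as.matrix(data)
  k <- ncol(data)
  stopifnot(k >= 2)
  R <- cor(data)
  om <- omega_total(R)
  ci <- bootstrap_ci(data, function(d) omega_total(cor(d)),
                     n_boot = n_boot, seed = seed)
  omh <- NA_real_
  # refuse the hierarchical split when groups cannot each carry >= 3 indicators
  if (!is.na(n_groups) && n_groups >= 2 && k >= 3 * n_groups) {
    sl <- schmid_leiman(R, n_groups)
    omh <- omega_hierarchical(sl)
  }
  diag_ <- if (k >= 3) item_total_diagnostics(data) else
    list(item_total = setNames(rep(NA_real_, k), colnames(data)),
         loo_delta_omega = setNames(rep(NA_real_, k), colnames(data)))
  structure(list(domain = domain, k = k, omega_total = om, omega_h = omh,
                 ci_low = ci[1], ci_high = ci[2], n_boot = n_boot,
                 item_total = diag_$item_total,
                 loo_delta_omega = diag_$loo_delta_omega),
            class = "reliability_report")
}
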