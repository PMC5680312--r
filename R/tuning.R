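# Fold assignment stratified by cohort label: within each cohort, fold sizes
# differ by at most one. Falls back to non-stratified folds (with a warning)
# when k exceeds the smaller cohort.
make_cv_folds <- function(cohort, k) {
  n <- length(cohort)
  if (n < k) stop("fewer observations (", n, ") than folds (", k, ")")
  tab <- table(cohort)
  if (length(tab) > 1L && min(tab) < k) {
    warning("k = ", k, " exceeds the smaller cohort (", min(tab),
            "); using non-stratified folds")
    return(sample(rep(seq_len(k), length.out = n)))
  }
  folds <- integer(n)
  for (lab in names(tab)) {
    idx <- which(cohort == lab)
    folds[idx] <- sample(rep(seq_len(k), length.out = length(idx)))
  }
  folds
}

# Lambda grid for a stacked design with given L1 weights: lambda1 log-spaced
# from lambda_max down to 1e-3 * lambda_max, crossed with lambda2_values.
# Rows are ordered lambda2-major with lambda1 strictly decreasing.
lambda_grid_stacked <- function(X, y, obsw, l1w, n_lambda1, lambda2_values) {
  if (stats::sd(y) == 0)
    stop("degenerate data: response has zero variance")
  lmax <- lambda_max_weighted(X, y, l1w, obsw)
  if (lmax <= 0) stop("degenerate data: all marginal gradients are zero")
  l1s <- exp(seq(log(lmax), log(1e-3 * lmax), length.out = n_lambda1))
  grid <- expand.grid(lambda1 = l1s, lambda2 = lambda2_values,
                      KEEP.OUT.ATTRS = FALSE)
  attr(grid, "lambda_max") <- lmax
  grid
}

#' Build the tuning grid for a cohort pair
#'
#' `lambda1` values are log-spaced from `lambda_max` (the smallest L1
#' strength that zeroes every coefficient, computed from the marginal
#' gradients and the current L1 weights) down to `1e-3 * lambda_max`,
#' crossed with a small fixed set of `lambda2` values.
#'
#' @param data a [cohort_pair()].
#' @param n_lambda1 number of L1 grid points (default 20).
#' @param lambda2_values L2 grid values (default `c(0.001, 0.01, 0.1, 1)`).
#' @param r balance factor, default `1/sqrt(2)`.
#' @param formulation `"F1"` or `"F2"`.
#' @param omega,psi optional adaptive L1 weight vectors (default all ones).
#' @param loss loss convention, see [shared_options()].
#' @return data.frame with columns `lambda1`, `lambda2` (lambda1 strictly
#'   decreasing within each lambda2) and attribute `"lambda_max"`.
#' @export
make_lambda_grid <- function(data, n_lambda1 = 20L,
                             lambda2_values = c(0.001, 0.01, 0.1, 1),
                             r = 1 / sqrt(2), formulation = c("F1", "F2"),
                             omega = NULL, psi = NULL,
                             loss = c("symmetric", "asymmetric_half")) {
  formulation <- match.arg(formulation); loss <- match.arg(loss)
  p <- n_features(data)
  if (is.null(omega)) omega <- rep(1, p)
  if (is.null(psi)) psi <- rep(1, p)
  stacked <- build_stacked_design(data, formulation)
  pw <- stacked_penalty_weights(stacked$roles, r, omega, psi)
  obsw <- loss_obs_weights(stacked$cohort, loss)
  lambda_grid_stacked(stacked$X, stacked$y, obsw, pw$l1,
                      n_lambda1, lambda2_values)
}

# Core CV loop on a stacked problem. `grid` must be ordered lambda2-major
# with decreasing lambda1 (as produced by lambda_grid_stacked) so paths can
# be warm-started. Held-out rows are predicted through their own stacked
# rows, which automatically uses beta for G rows and beta+delta for C rows.
cv_stacked <- function(X, y, obsw, l1w, l2w, grid, folds, tol, max_sweeps) {
  k <- max(folds)
  n <- length(y)
  npair <- nrow(grid)
  sqerr <- numeric(npair)
  fold_mse <- matrix(NA_real_, k, npair)
  l2vals <- unique(grid$lambda2)
  for (f in seq_len(k)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; ytr <- y[tr]; wtr <- obsw[tr]
    Xte <- X[!tr, , drop = FALSE]; yte <- y[!tr]
    # Gram form: one O(n m^2) product per fold, then O(1) coordinate visits
    G <- crossprod(Xtr * sqrt(wtr))
    cvec <- drop(crossprod(Xtr, wtr * ytr))
    for (l2 in l2vals) {
      rows <- which(grid$lambda2 == l2)
      lam1s <- grid$lambda1[rows]
      path <- cd_enet_gram_path(G, cvec, l1w, l2w, lam1s, l2,
                                tol, as.integer(max_sweeps))
      pred <- Xte %*% path$coef
      se <- colSums((yte - pred)^2)
      sqerr[rows] <- sqerr[rows] + se
      fold_mse[f, rows] <- se / length(yte)
    }
  }
  cv_error <- sqerr / n
  cv_se <- apply(fold_mse, 2, stats::sd) / sqrt(k)
  ord <- order(cv_error, -grid$lambda1, -grid$lambda2)
  best_i <- ord[1]
  structure(list(grid = cbind(grid, cv_error = cv_error, cv_se = cv_se),
                 best = c(lambda1 = grid$lambda1[best_i],
                          lambda2 = grid$lambda2[best_i]),
                 best_index = best_i, fold_assignments = folds),
            class = "cv_result")
}

#' Ten-fold cross-validation over a penalty grid
#'
#' Folds are drawn separately within the G and C cohorts so every fold
#' contains both cohorts in proportion (both `beta` and `delta` stay
#' estimable in each training split). Per fold, the model is fitted on the
#' training portion; held-out G rows are predicted with `beta` and held-out
#' C rows with `beta + delta`. The CV error for each grid pair is the mean
#' of squared errors pooled over all held-out rows. Ties in the minimum are
#' broken toward larger `lambda1`, then larger `lambda2` (sparser model).
#'
#' @param data a [cohort_pair()].
#' @param grid data.frame of `(lambda1, lambda2)` pairs from
#'   [make_lambda_grid()].
#' @param k number of folds (default 10).
#' @param seed integer seed for fold assignment.
#' @param r,formulation,omega,psi,loss as in [make_lambda_grid()]; supply
#'   `omega`/`psi` to cross-validate the adaptive stage at fixed weights.
#' @param tol,max_sweeps solver controls.
#' @return An object of class `cv_result`: `grid` (with `cv_error`,
#'   `cv_se`), `best`, `best_index`, `fold_assignments` (data.frame with
#'   cohort labels).
#' @export
cross_validate <- function(data, grid, k = 10L, seed = NULL,
                           r = 1 / sqrt(2), formulation = c("F1", "F2"),
                           omega = NULL, psi = NULL,
                           loss = c("symmetric", "asymmetric_half"),
                           tol = 1e-7, max_sweeps = 10000L) {
  formulation <- match.arg(formulation); loss <- match.arg(loss)
  p <- n_features(data)
  if (nrow(data$X_G) + nrow(data$X_C) < k)
    stop("need at least k observations for ", k, "-fold cross-validation")
  if (is.null(omega)) omega <- rep(1, p)
  if (is.null(psi)) psi <- rep(1, p)
  stacked <- build_stacked_design(data, formulation)
  pw <- stacked_penalty_weights(stacked$roles, r, omega, psi)
  obsw <- loss_obs_weights(stacked$cohort, loss)
  folds <- with_seed(seed, make_cv_folds(stacked$cohort, k))
  out <- cv_stacked(stacked$X, stacked$y, obsw, pw$l1, pw$l2, grid, folds,
                    tol, max_sweeps)
  out$fold_assignments <- data.frame(row = seq_along(folds),
                                     cohort = stacked$cohort, fold = folds)
  out
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d grid pairs; best lambda1 = %.4g, lambda2 = %.4g (cv error %.4g)\n",
              nrow(x$grid), x$best[1], x$best[2],
              x$grid$cv_error[x$best_index]))
  invisible(x)
}
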