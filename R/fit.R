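#' Options for the two-stage shared fit
#'
#' @param tol coordinate-descent tolerance (max coefficient change per sweep).
#' @param max_sweeps sweep budget for the solver.
#' @param cv_tol,cv_max_sweeps looser solver controls used inside the
#'   cross-validation grid search only (hundreds of path fits); final and
#'   pilot fits always use `tol`/`max_sweeps`.
#' @param loss `"symmetric"` applies the 1/2 factor to both cohorts' residual
#'   sums (default); `"asymmetric_half"` keeps it on cohort G only.
#' @param pilot_lambda optional fixed `c(lambda1, lambda2)` for the pilot
#'   (non-adaptive) fit; when `NULL` the pilot penalties are chosen by
#'   cross-validation.
#' @param weight_floor optional floor `eps` applied to `|pilot|` before
#'   taking reciprocals; `NULL` (default) uses the exclusion convention: a
#'   pilot estimate of exactly zero gives an infinite weight and the
#'   coordinate is dropped.
#' @param n_lambda1 number of L1 grid points (see [make_lambda_grid()]).
#' @param lambda2_values L2 grid values.
#' @param cv_folds number of cross-validation folds.
#' @return list of options for [fit_shared()].
#' @export
shared_options <- function(tol = 1e-7, max_sweeps = 10000L,
                           loss = c("symmetric", "asymmetric_half"),
                           pilot_lambda = NULL, weight_floor = NULL,
                           n_lambda1 = 20L,
                           lambda2_values = c(0.001, 0.01, 0.1, 1),
                           cv_folds = 10L,
                           cv_tol = 1e-3, cv_max_sweeps = 1000L) {
  list(tol = tol, max_sweeps = as.integer(max_sweeps),
       loss = match.arg(loss), pilot_lambda = pilot_lambda,
       weight_floor = weight_floor, n_lambda1 = as.integer(n_lambda1),
       lambda2_values = lambda2_values, cv_folds = as.integer(cv_folds),
       cv_tol = cv_tol, cv_max_sweeps = as.integer(cv_max_sweeps))
}

# Evaluate code with a local, restorable RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Observation weights implementing the loss convention on stacked rows.
loss_obs_weights <- function(cohort, loss) {
  if (loss == "symmetric") rep(1, length(cohort)) else
    ifelse(cohort == "C", 2, 1)
}

# Per-stacked-column L1/L2 weights from block roles. `omega` applies to the
# beta block; `psi`, `psi_G`, `psi_C` to the discrepancy blocks, each scaled
# by r in the L1 part; L2 weights are 1 for beta and r for discrepancies.
stacked_penalty_weights <- function(roles, r, omega, psi,
                                    psi_G = NULL, psi_C = NULL) {
  m <- nrow(roles)
  l1 <- numeric(m); l2 <- numeric(m)
  b <- roles$block == "beta"
  l1[b] <- omega[roles$feature[b]]; l2[b] <- 1
  for (blk in c("delta", "delta_G", "delta_C")) {
    sel <- roles$block == blk
    if (!any(sel)) next
    w <- switch(blk,
                delta = psi,
                delta_G = if (is.null(psi_G)) psi else psi_G,
                delta_C = if (is.null(psi_C)) psi else psi_C)
    l1[sel] <- r * w[roles$feature[sel]]
    l2[sel] <- r
  }
  list(l1 = l1, l2 = l2)
}

#' Fit the data-shared adaptive elastic net
#'
#' Two-stage procedure: (i) a pilot non-adaptive elastic net (all L1 weights
#' one) on the stacked cohort design, with its penalties chosen by
#' cross-validation unless `options$pilot_lambda` is supplied; (ii) adaptive
#' L1 weights formed as reciprocal absolute pilot estimates
#' (`omega_j = 1/|beta_j^pilot|`, `psi_j = 1/|delta_j^pilot|`; a pilot zero
#' excludes the coordinate); (iii) the weighted elastic net solved at
#' `(lambda1, lambda2)`, themselves chosen by cross-validation when left
#' `NULL`. The same fold assignment (derived from `seed`) is used for both
#' CV stages.
#'
#' If one cohort is empty the fit degenerates to a single-dataset adaptive
#' elastic net on the other cohort with all discrepancies zero (flagged).
#' If every pilot estimate is zero, an all-zero fit is returned with a
#' warning flag.
#'
#' @param data a [cohort_pair()], preprocessed (standardized, no missing).
#' @param lambda1,lambda2 adaptive-stage penalties; `NULL` selects them by
#'   cross-validation.
#' @param r shared/discrepancy balance factor, default `1/sqrt(2)`.
#' @param formulation `"F1"` (one discrepancy vector, the default) or `"F2"`
#'   (cohort-specific discrepancies).
#' @param options a [shared_options()] list.
#' @param seed integer seed driving fold assignment; `NULL` leaves the RNG
#'   stream as-is.
#' @return An object of class `shared_fit` with elements `beta`, `delta`
#'   (F1) or `delta_G`/`delta_C` (F2), `formulation`, `objective_value`,
#'   `converged`, `n_sweeps`, `penalty` (the [penalty_spec()] used,
#'   including the adaptive weights), `pilot_coef`, `cv` (pilot and adaptive
#'   [cross_validate()] results, when run), `flags`, `feature_names`.
#' @export
fit_shared <- function(data, lambda1 = NULL, lambda2 = NULL,
                       r = 1 / sqrt(2), formulation = c("F1", "F2"),
                       options = shared_options(), seed = NULL) {
  formulation <- match.arg(formulation)
  p <- n_features(data)
  flags <- character()

  if (nrow(data$X_G) == 0L || nrow(data$X_C) == 0L) {
    side <- if (nrow(data$X_G) > 0L) "G" else "C"
    warning("cohort ", setdiff(c("G", "C"), side),
            " is empty; fitting a single-dataset model with zero discrepancies")
    X <- if (side == "G") data$X_G else data$X_C
    y <- if (side == "G") data$y_G else data$y_C
    ind <- fit_individual(X, y, options = options, seed = seed)
    zero <- setNames(rep(0, p), data$feature_names)
    fit <- list(beta = setNames(ind$coef, data$feature_names),
                formulation = formulation,
                objective_value = ind$objective, converged = ind$converged,
                n_sweeps = ind$n_sweeps,
                penalty = penalty_spec(ind$lambda[1], ind$lambda[2], r, p = p),
                pilot_coef = ind$pilot_coef, cv = ind$cv,
                flags = c(flags, "empty_cohort"),
                feature_names = data$feature_names)
    if (formulation == "F1") fit$delta <- zero else {
      fit$delta_G <- zero; fit$delta_C <- zero
    }
    return(structure(fit, class = "shared_fit"))
  }

  stacked <- build_stacked_design(data, formulation)
  obsw <- loss_obs_weights(stacked$cohort, options$loss)
  ones <- rep(1, p)
  pw <- stacked_penalty_weights(stacked$roles, r, ones, ones)
  folds <- with_seed(seed, make_cv_folds(stacked$cohort, options$cv_folds))

  # --- stage (i): pilot -----------------------------------------------------
  cv_out <- list()
  if (is.null(options$pilot_lambda)) {
    grid <- lambda_grid_stacked(stacked$X, stacked$y, obsw, pw$l1,
                                options$n_lambda1, options$lambda2_values)
    cvp <- cv_stacked(stacked$X, stacked$y, obsw, pw$l1, pw$l2, grid, folds,
                      options$cv_tol, options$cv_max_sweeps)
    pilot_lambda <- cvp$best
    cv_out$pilot <- cvp
  } else {
    pilot_lambda <- as.numeric(options$pilot_lambda)
  }
  pilot <- solve_weighted_enet(stacked$X, stacked$y, pw$l1, pw$l2,
                               pilot_lambda[1], pilot_lambda[2],
                               obs_weights = obsw, tol = options$tol,
                               max_sweeps = options$max_sweeps)

  # --- stage (ii): adaptive weights ----------------------------------------
  recip <- function(v) {
    a <- abs(v)
    if (!is.null(options$weight_floor)) a <- pmax(a, options$weight_floor)
    ifelse(a == 0, Inf, 1 / a)
  }
  block_coef <- function(blk) {
    sel <- stacked$roles$block == blk
    setNames(pilot$coef[sel][order(stacked$roles$feature[sel])],
             data$feature_names)
  }
  beta_p <- block_coef("beta")
  omega <- recip(beta_p)
  if (formulation == "F1") {
    delta_p <- block_coef("delta")
    psi <- recip(delta_p); psi_G <- psi_C <- NULL
  } else {
    dG_p <- block_coef("delta_G"); dC_p <- block_coef("delta_C")
    psi_G <- recip(dG_p); psi_C <- recip(dC_p)
    psi <- psi_G # representative; blocks carry their own weights
  }

  if (all(pilot$coef == 0)) {
    warning("all pilot estimates are zero; returning the all-zero fit")
    flags <- c(flags, "all_zero_pilot")
    zero <- setNames(rep(0, p), data$feature_names)
    pen <- penalty_spec(if (is.null(lambda1)) pilot_lambda[1] else lambda1,
                        if (is.null(lambda2)) pilot_lambda[2] else lambda2,
                        r, omega = omega, psi = psi)
    fit <- list(beta = zero, formulation = formulation,
                objective_value = weighted_enet_objective(
                  stacked$X, stacked$y, rep(0, ncol(stacked$X)),
                  pw$l1, pw$l2, pen$lambda1, pen$lambda2, obsw),
                converged = TRUE, n_sweeps = 0L, penalty = pen,
                pilot_coef = pilot$coef, cv = cv_out, flags = flags,
                feature_names = data$feature_names)
    if (formulation == "F1") fit$delta <- zero else {
      fit$delta_G <- zero; fit$delta_C <- zero
    }
    return(structure(fit, class = "shared_fit"))
  }

  aw <- stacked_penalty_weights(stacked$roles, r, omega, psi, psi_G, psi_C)

  # --- stage (iii): adaptive fit -------------------------------------------
  if (is.null(lambda1) || is.null(lambda2)) {
    grid <- lambda_grid_stacked(stacked$X, stacked$y, obsw, aw$l1,
                                options$n_lambda1, options$lambda2_values)
    cva <- cv_stacked(stacked$X, stacked$y, obsw, aw$l1, aw$l2, grid, folds,
                      options$cv_tol, options$cv_max_sweeps)
    if (is.null(lambda1)) lambda1 <- cva$best[1]
    if (is.null(lambda2)) lambda2 <- cva$best[2]
    cv_out$adaptive <- cva
  }
  sol <- solve_weighted_enet(stacked$X, stacked$y, aw$l1, aw$l2,
                             lambda1, lambda2, obs_weights = obsw,
                             tol = options$tol,
                             max_sweeps = options$max_sweeps)
  if (!sol$converged) flags <- c(flags, "not_converged")

  pen <- penalty_spec(lambda1, lambda2, r, omega = omega, psi = psi)
  fit <- list(beta = setNames(sol$coef[stacked$roles$block == "beta"],
                              data$feature_names),
              formulation = formulation, converged = sol$converged,
              n_sweeps = sol$n_sweeps, penalty = pen,
              pilot_coef = pilot$coef, cv = cv_out, flags = flags,
              feature_names = data$feature_names)
  if (formulation == "F1") {
    fit$delta <- setNames(sol$coef[stacked$roles$block == "delta"],
                          data$feature_names)
    fit$objective_value <- as.numeric(
      evaluate_objective(data, fit$beta, fit$delta, pen,
                         loss = if (options$loss == "symmetric")
                           "symmetric" else "asymmetric_half"))
  } else {
    fit$delta_G <- setNames(sol$coef[stacked$roles$block == "delta_G"],
                            data$feature_names)
    fit$delta_C <- setNames(sol$coef[stacked$roles$block == "delta_C"],
                            data$feature_names)
    fit$objective_value <- as.numeric(
      evaluate_objective(data, fit$beta, penalty = pen,
                         delta_G = fit$delta_G, delta_C = fit$delta_C,
                         psi_G = psi_G, psi_C = psi_C,
                         loss = if (options$loss == "symmetric")
                           "symmetric" else "asymmetric_half"))
  }
  structure(fit, class = "shared_fit")
}

#' @export
print.shared_fit <- function(x, ...) {
  nz <- function(v) if (is.null(v)) NA_integer_ else sum(v != 0)
  cat(sprintf("<shared_fit %s> p = %d, nonzero beta = %d", x$formulation,
              length(x$beta), nz(x$beta)))
  if (x$formulation == "F1") cat(sprintf(", nonzero delta = %d", nz(x$delta)))
  else cat(sprintf(", nonzero delta_G = %d, delta_C = %d",
                   nz(x$delta_G), nz(x$delta_C)))
  cat(sprintf("\n  lambda1 = %.4g, lambda2 = %.4g, objective = %.6g, converged = %s\n",
              x$penalty$lambda1, x$penalty$lambda2, x$objective_value,
              x$converged))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Single-dataset adaptive elastic net (baseline model)
#'
#' The same two-stage pilot/adaptive machinery as [fit_shared()], applied to
#' one design matrix. Used as the individual-G, individual-C and pooled
#' comparators.
#'
#' @inheritParams fit_shared
#' @param X design matrix; `y` response.
#' @param y numeric response vector.
#' @return list with `coef`, `lambda`, `objective`, `converged`, `n_sweeps`,
#'   `pilot_coef`, `cv`.
#' @export
fit_individual <- function(X, y, lambda1 = NULL, lambda2 = NULL,
                           options = shared_options(), seed = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  ones <- rep(1, m)
  folds <- with_seed(seed, make_cv_folds(rep("G", nrow(X)), options$cv_folds))
  cv_out <- list()
  if (is.null(options$pilot_lambda)) {
    grid <- lambda_grid_stacked(X, y, NULL, ones,
                                options$n_lambda1, options$lambda2_values)
    cvp <- cv_stacked(X, y, rep(1, nrow(X)), ones, ones, grid, folds,
                      options$cv_tol, options$cv_max_sweeps)
    pilot_lambda <- cvp$best
    cv_out$pilot <- cvp
  } else pilot_lambda <- as.numeric(options$pilot_lambda)
  pilot <- solve_weighted_enet(X, y, ones, ones, pilot_lambda[1],
                               pilot_lambda[2], tol = options$tol,
                               max_sweeps = options$max_sweeps)
  a <- abs(pilot$coef)
  if (!is.null(options$weight_floor)) a <- pmax(a, options$weight_floor)
  w1 <- ifelse(a == 0, Inf, 1 / a)
  if (all(pilot$coef == 0)) {
    warning("all pilot estimates are zero; returning the all-zero fit")
    return(list(coef = setNames(rep(0, m), colnames(X)),
                lambda = pilot_lambda,
                objective = 0.5 * sum(y^2), converged = TRUE, n_sweeps = 0L,
                pilot_coef = pilot$coef, cv = cv_out))
  }
  if (is.null(lambda1) || is.null(lambda2)) {
    grid <- lambda_grid_stacked(X, y, NULL, w1,
                                options$n_lambda1, options$lambda2_values)
    cva <- cv_stacked(X, y, rep(1, nrow(X)), w1, ones, grid, folds,
                      options$cv_tol, options$cv_max_sweeps)
    if (is.null(lambda1)) lambda1 <- cva$best[1]
    if (is.null(lambda2)) lambda2 <- cva$best[2]
    cv_out$adaptive <- cva
  }
  sol <- solve_weighted_enet(X, y, w1, ones, lambda1, lambda2,
                             tol = options$tol,
                             max_sweeps = options$max_sweeps)
  list(coef = setNames(sol$coef, colnames(X)),
       lambda = c(lambda1, lambda2), objective = sol$objective,
       converged = sol$converged, n_sweeps = sol$n_sweeps,
       pilot_coef = pilot$coef, cv = cv_out)
}

#' Convert a fit between the two model formulations
#'
#' The two parameterizations describe the same fitted surface: with
#' Formulation-2 parameters `(beta2, delta_G, delta_C)`, the Formulation-1
#' parameters are `beta1 = beta2 + delta_G` and `delta = delta_C - delta_G`.
#' The reverse direction is not unique; the `delta_G = 0` convention is used
#' (so `beta2 = beta1`, `delta_C = delta`). Fitted values on both cohorts
#' are preserved exactly. The penalized objective value does not transport
#' across parameterizations and is set to `NA` on the result.
#'
#' @param fit a `shared_fit` of either formulation.
#' @return a `shared_fit` of the other formulation.
#' @export
transform_formulations <- function(fit) {
  stopifnot(inherits(fit, "shared_fit"))
  out <- fit
  if (fit$formulation == "F2") {
    out$beta <- fit$beta + fit$delta_G
    out$delta <- fit$delta_C - fit$delta_G
    out$delta_G <- NULL; out$delta_C <- NULL
    out$formulation <- "F1"
  } else {
    out$delta_G <- setNames(rep(0, length(fit$beta)), names(fit$beta))
    out$delta_C <- fit$delta
    out$delta <- NULL
    out$formulation <- "F2"
  }
  out$objective_value <- NA_real_
  out$flags <- union(out$flags, "transformed")
  out
}

#' Predict drug response from a shared fit
#'
#' `mode = "as_G"` predicts as a G-cohort observation; `"as_C"` as a
#' C-cohort observation. Under Formulation 1 these are `X beta` and
#' `X (beta + delta)`; under Formulation 2, `X (beta + delta_G)` and
#' `X (beta + delta_C)`. The model is intercept-free: inputs must be on the
#' training (standardized) scale.
#'
#' @param fit a `shared_fit`.
#' @param X numeric matrix with `p` columns.
#' @param mode `"as_G"` or `"as_C"`.
#' @return numeric prediction vector of length `nrow(X)`.
#' @export
predict_shared <- function(fit, X, mode = c("as_G", "as_C")) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (ncol(X) != length(fit$beta))
    stop("X has ", ncol(X), " columns but the fit has p = ", length(fit$beta))
  eff <- if (fit$formulation == "F1") {
    if (mode == "as_G") fit$beta else fit$beta + fit$delta
  } else {
    if (mode == "as_G") fit$beta + fit$delta_G else fit$beta + fit$delta_C
  }
  drop(X %*% eff)
}

#' @export
predict.shared_fit <- function(object, newdata, mode = c("as_G", "as_C"), ...) {
  predict_shared(object, newdata, mode)
}
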