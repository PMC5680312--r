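#' Evaluate the data-shared penalized objective
#'
#' Computes
#' \deqn{\tfrac12\big[\mathrm{RSS}_G(\beta) + \mathrm{RSS}_C(\beta+\delta)\big]
#'   + \lambda_1\big(\sum_j \omega_j|\beta_j| + r\sum_j \psi_j|\delta_j|\big)
#'   + \lambda_2\big(\|\beta\|_2^2 + r\|\delta\|_2^2\big),}
#' the criterion minimized by [fit_shared()]. The loss part is symmetric in
#' the two cohorts by default; `loss = "asymmetric_half"` keeps the 1/2
#' factor on the G residual sum only (equivalently, C rows get observation
#' weight 2 under the global 1/2 convention).
#'
#' Formulation 2 replaces \eqn{\delta} by cohort-specific discrepancies:
#' G rows use \eqn{\beta+\delta_G}, C rows \eqn{\beta+\delta_C}, and the
#' penalty extends symmetrically over both discrepancy blocks.
#'
#' @param data a [cohort_pair()].
#' @param beta length-`p` shared coefficient vector.
#' @param delta length-`p` discrepancy vector (Formulation 1).
#' @param penalty a [penalty_spec()].
#' @param delta_G,delta_C length-`p` discrepancy vectors (Formulation 2);
#'   supply both instead of `delta`.
#' @param psi_G,psi_C optional Formulation-2 L1 weights for the two
#'   discrepancy blocks; default `penalty$psi` for both.
#' @param loss `"symmetric"` (default) or `"asymmetric_half"`.
#' @return A finite nonnegative scalar with attribute `"parts"`, a list with
#'   components `loss`, `l1`, `l2` whose sum is the returned value.
#' @export
evaluate_objective <- function(data, beta, delta = NULL, penalty,
                               delta_G = NULL, delta_C = NULL,
                               psi_G = NULL, psi_C = NULL,
                               loss = c("symmetric", "asymmetric_half")) {
  loss <- match.arg(loss)
  p <- n_features(data)
  chk <- function(v, nm) {
    if (length(v) != p)
      stop(nm, " has length ", length(v), " but the design has p = ", p)
    as.numeric(v)
  }
  beta <- chk(beta, "beta")
  f2 <- !is.null(delta_G) || !is.null(delta_C)
  if (f2) {
    if (is.null(delta_G) || is.null(delta_C))
      stop("Formulation 2 requires both delta_G and delta_C")
    delta_G <- chk(delta_G, "delta_G"); delta_C <- chk(delta_C, "delta_C")
  } else {
    if (is.null(delta)) stop("supply either delta or (delta_G, delta_C)")
    delta <- chk(delta, "delta")
  }
  if (length(penalty$omega) != p)
    stop("penalty weights have length ", length(penalty$omega),
         " but the design has p = ", p)
  if (any(is.infinite(penalty$omega) & beta != 0))
    stop("beta is nonzero at a coordinate excluded by an infinite omega weight")
  if (f2) {
    pg0 <- if (is.null(psi_G)) penalty$psi else psi_G
    pc0 <- if (is.null(psi_C)) penalty$psi else psi_C
    if (any(is.infinite(pg0) & delta_G != 0) ||
        any(is.infinite(pc0) & delta_C != 0))
      stop("delta is nonzero at a coordinate excluded by an infinite psi weight")
  } else if (any(is.infinite(penalty$psi) & delta != 0)) {
    stop("delta is nonzero at a coordinate excluded by an infinite psi weight")
  }

  eff_G <- if (f2) beta + delta_G else beta
  eff_C <- if (f2) beta + delta_C else beta + delta
  rss_G <- sum((data$y_G - drop(data$X_G %*% eff_G))^2)
  rss_C <- sum((data$y_C - drop(data$X_C %*% eff_C))^2)
  loss_val <- if (loss == "symmetric") 0.5 * (rss_G + rss_C) else
    0.5 * rss_G + rss_C

  w_abs <- function(w, v) sum((w * abs(v))[v != 0]) # Inf * 0 guarded
  r <- penalty$r
  if (f2) {
    pg <- if (is.null(psi_G)) penalty$psi else psi_G
    pc <- if (is.null(psi_C)) penalty$psi else psi_C
    l1 <- penalty$lambda1 * (w_abs(penalty$omega, beta) +
                               r * w_abs(pg, delta_G) + r * w_abs(pc, delta_C))
    l2 <- penalty$lambda2 * (sum(beta^2) + r * sum(delta_G^2) + r * sum(delta_C^2))
  } else {
    l1 <- penalty$lambda1 * (w_abs(penalty$omega, beta) +
                               r * w_abs(penalty$psi, delta))
    l2 <- penalty$lambda2 * (sum(beta^2) + r * sum(delta^2))
  }
  out <- loss_val + l1 + l2
  attr(out, "parts") <- list(loss = loss_val, l1 = l1, l2 = l2)
  out
}

#' Stack a cohort pair into a single penalized least-squares problem
#'
#' Formulation 1 stacks to `[[X_G, 0], [X_C, X_C]]` with coordinate roles
#' (beta-block, delta-block); Formulation 2 stacks to
#' `[[X_G, X_G, 0], [X_C, 0, X_C]]` with roles (beta, delta_G, delta_C). The
#' stacked response is `c(y_G, y_C)`. The role map records, per stacked
#' column, the block it belongs to and the original feature index, which
#' determines the penalty weight applied to it.
#'
#' @param data a [cohort_pair()].
#' @param formulation `"F1"` or `"F2"`.
#' @return list with `X` (stacked matrix), `y` (stacked response), `roles`
#'   (data.frame: `block`, `feature`), `cohort` (per-row label `"G"`/`"C"`).
#' @export
build_stacked_design <- function(data, formulation = c("F1", "F2")) {
  formulation <- match.arg(formulation)
  p <- n_features(data)
  nG <- nrow(data$X_G); nC <- nrow(data$X_C)
  zG <- matrix(0, nG, p); zC <- matrix(0, nC, p)
  if (formulation == "F1") {
    X <- rbind(cbind(data$X_G, zG), cbind(data$X_C, data$X_C))
    roles <- data.frame(block = rep(c("beta", "delta"), each = p),
                        feature = rep(seq_len(p), 2L),
                        stringsAsFactors = FALSE)
  } else {
    X <- rbind(cbind(data$X_G, data$X_G, zG),
               cbind(data$X_C, zC, data$X_C))
    roles <- data.frame(block = rep(c("beta", "delta_G", "delta_C"), each = p),
                        feature = rep(seq_len(p), 3L),
                        stringsAsFactors = FALSE)
  }
  colnames(X) <- paste(roles$block, data$feature_names[roles$feature], sep = ".")
  list(X = X, y = c(data$y_G, data$y_C), roles = roles,
       cohort = rep(c("G", "C"), c(nG, nC)))
}
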