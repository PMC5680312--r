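#' Paired cohort data for the data-shared model
#'
#' Bundles two aligned design/response sets, labelled `G` and `C` (e.g. the
#' GDSC and CCLE drug-screening cohorts). Both design matrices must have the
#' same columns in the same order; one cohort may be empty (zero rows), in
#' which case shared fits degenerate to a single-dataset fit.
#'
#' @param X_G numeric matrix of predictors for cohort G (`n_G x p`),
#'   standardized upstream (see [impute_and_standardize()]).
#' @param y_G numeric response vector for cohort G (length `n_G`).
#' @param X_C numeric matrix of predictors for cohort C (`n_C x p`), same
#'   column order as `X_G`.
#' @param y_C numeric response vector for cohort C.
#' @param feature_names character vector of `p` unique feature identifiers;
#'   defaults to the column names of `X_G` (or `X_C`), falling back to
#'   `f1..fp`.
#' @return An object of class `cohort_pair`.
#' @export
cohort_pair <- function(X_G, y_G, X_C, y_C, feature_names = NULL) {
  X_G <- as.matrix(X_G); X_C <- as.matrix(X_C)
  y_G <- as.numeric(y_G); y_C <- as.numeric(y_C)
  if (ncol(X_G) != ncol(X_C))
    stop("X_G and X_C must have the same number of columns (",
         ncol(X_G), " vs ", ncol(X_C), ")")
  p <- ncol(X_G)
  if (nrow(X_G) != length(y_G))
    stop("cohort G: nrow(X_G) = ", nrow(X_G), " but length(y_G) = ", length(y_G))
  if (nrow(X_C) != length(y_C))
    stop("cohort C: nrow(X_C) = ", nrow(X_C), " but length(y_C) = ", length(y_C))
  if (nrow(X_G) + nrow(X_C) < 1)
    stop("at least one cohort must be non-empty")
  if (is.null(feature_names)) {
    feature_names <- colnames(X_G)
    if (is.null(feature_names)) feature_names <- colnames(X_C)
    if (is.null(feature_names)) feature_names <- paste0("f", seq_len(p))
  }
  if (length(feature_names) != p)
    stop("feature_names must have length ", p)
  if (anyDuplicated(feature_names))
    stop("feature_names must be unique")
  if (anyNA(X_G) || anyNA(y_G) || anyNA(X_C) || anyNA(y_C))
    stop("cohort_pair does not accept missing values; run preprocessing first")
  colnames(X_G) <- colnames(X_C) <- feature_names
  structure(list(X_G = X_G, y_G = y_G, X_C = X_C, y_C = y_C,
                 feature_names = feature_names),
            class = "cohort_pair")
}

#' @export
print.cohort_pair <- function(x, ...) {
  cat("<cohort_pair> p =", length(x$feature_names),
      " n_G =", nrow(x$X_G), " n_C =", nrow(x$X_C), "\n")
  invisible(x)
}

#' Number of features in a cohort pair
#' @param data a [cohort_pair()].
#' @return integer feature count.
#' @export
n_features <- function(data) length(data$feature_names)

#' Restrict a cohort pair to a column subset
#' @param data a [cohort_pair()].
#' @param idx integer or character index of features to keep.
#' @return a new `cohort_pair` with the selected columns.
#' @export
subset_features <- function(data, idx) {
  cohort_pair(data$X_G[, idx, drop = FALSE], data$y_G,
              data$X_C[, idx, drop = FALSE], data$y_C)
}

#' Penalty specification for the data-shared elastic net
#'
#' Collects the two tuning parameters, the shared/discrepancy balance factor
#' `r`, and the per-coordinate L1 weights for the shared block (`omega`) and
#' the discrepancy block (`psi`). An infinite entry in `omega` or `psi`
#' excludes that coordinate (it is held at exactly zero), the adaptive-lasso
#' convention for a zero pilot estimate.
#'
#' @param lambda1 nonnegative L1 strength.
#' @param lambda2 nonnegative L2 strength.
#' @param r positive balance factor between the shared and discrepancy
#'   penalties; default `1/sqrt(2)`.
#' @param omega length-`p` nonnegative vector of L1 weights for the shared
#'   coefficients; default all ones.
#' @param psi length-`p` nonnegative vector of L1 weights for the
#'   discrepancy coefficients; default all ones.
#' @param p feature count, required when `omega`/`psi` are left `NULL`.
#' @return An object of class `penalty_spec`.
#' @export
penalty_spec <- function(lambda1, lambda2, r = 1 / sqrt(2),
                         omega = NULL, psi = NULL, p = NULL) {
  if (length(lambda1) != 1L || is.na(lambda1) || lambda1 < 0)
    stop("lambda1 must be a nonnegative scalar")
  if (length(lambda2) != 1L || is.na(lambda2) || lambda2 < 0)
    stop("lambda2 must be a nonnegative scalar")
  if (length(r) != 1L || is.na(r) || r <= 0)
    stop("r must be a positive scalar")
  if (is.null(omega)) {
    if (is.null(p)) stop("supply p when omega is NULL")
    omega <- rep(1, p)
  }
  if (is.null(psi)) {
    if (is.null(p)) p <- length(omega)
    psi <- rep(1, p)
  }
  if (length(omega) != length(psi))
    stop("omega and psi must have equal length")
  if (any(omega < 0) || any(psi < 0))
    stop("L1 weights must be nonnegative")
  structure(list(lambda1 = lambda1, lambda2 = lambda2, r = r,
                 omega = as.numeric(omega), psi = as.numeric(psi)),
            class = "penalty_spec")
}

#' @export
print.penalty_spec <- function(x, ...) {
  cat(sprintf("<penalty_spec> lambda1 = %.4g, lambda2 = %.4g, r = %.4g, p = %d (%d excluded beta, %d excluded delta)\n",
              x$lambda1, x$lambda2, x$r, length(x$omega),
              sum(is.infinite(x$omega)), sum(is.infinite(x$psi))))
  invisible(x)
}

#' Noise model for the synthetic-data generator
#'
#' The residuals of both cohort equations are i.i.d. mean-zero Gaussian with
#' this variance.
#'
#' @param variance positive error variance.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(variance = 1) {
  if (length(variance) != 1L || is.na(variance) || variance <= 0)
    stop("variance must be a positive scalar")
  structure(list(variance = variance), class = "noise_model")
}
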