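#' Sure independence screening with per-cohort union
#'
#' Within each cohort, features are ranked by the absolute Pearson
#' correlation between the feature column and that cohort's response
#' (zero-variance columns rank last with correlation 0). The top `k` per
#' cohort are taken and their union returned in ascending feature-index
#' order, together with the cohort pair restricted to those columns. Ties at
#' the k-th rank are broken by ascending feature index.
#'
#' @param data a [cohort_pair()], standardized.
#' @param k number of features to keep per cohort (`k >= 1`); `k > p` keeps
#'   everything with a warning.
#' @return An object of class `screen_result`: `selected_indices` (ascending),
#'   `selected_names`, `per_cohort_rank` (matrix of absolute marginal
#'   correlations, columns `G` and `C`), `data` (the restricted cohort pair),
#'   `k`.
#' @export
sis_union_screen <- function(data, k) {
  p <- n_features(data)
  if (k < 1) stop("k must be at least 1")
  if (k > p) {
    warning("k = ", k, " exceeds p = ", p, "; keeping all features")
    k <- p
  }
  abs_cor <- function(X, y) {
    if (nrow(X) == 0L) return(rep(0, ncol(X)))
    sds <- apply(X, 2, stats::sd)
    out <- rep(0, ncol(X))
    ok <- sds > 0 & stats::sd(y) > 0
    if (any(ok)) out[ok] <- abs(stats::cor(X[, ok, drop = FALSE], y))
    out
  }
  cG <- abs_cor(data$X_G, data$y_G)
  cC <- abs_cor(data$X_C, data$y_C)
  top_k <- function(v) order(-v, seq_along(v))[seq_len(k)]
  sel <- sort(union(top_k(cG), top_k(cC)))
  ranks <- cbind(G = cG, C = cC)
  rownames(ranks) <- data$feature_names
  structure(list(selected_indices = sel,
                 selected_names = data$feature_names[sel],
                 per_cohort_rank = ranks,
                 data = subset_features(data, sel), k = k),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> k = %d per cohort; |union| = %d of %d features\n",
              x$k, length(x$selected_indices), nrow(x$per_cohort_rank)))
  invisible(x)
}
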