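#' Raw feature table with possible missing entries
#'
#' @param values numeric matrix, possibly with `NA` entries.
#' @param row_ids unique sample (cell-line) identifiers.
#' @param col_ids unique feature identifiers.
#' @param col_kind optional per-column kind, one of `"mutation"`,
#'   `"expression"`, `"copy_number"`, `"tissue"`.
#' @return An object of class `raw_table`.
#' @export
raw_table <- function(values, row_ids = rownames(values),
                      col_ids = colnames(values), col_kind = NULL) {
  values <- as.matrix(values)
  if (is.null(row_ids)) row_ids <- paste0("s", seq_len(nrow(values)))
  if (is.null(col_ids)) col_ids <- paste0("f", seq_len(ncol(values)))
  if (anyDuplicated(row_ids)) stop("row_ids must be unique")
  if (anyDuplicated(col_ids)) stop("col_ids must be unique")
  if (length(row_ids) != nrow(values) || length(col_ids) != ncol(values))
    stop("id lengths must match the value matrix")
  if (!is.null(col_kind)) {
    col_kind <- match.arg(col_kind,
                          c("mutation", "expression", "copy_number", "tissue"),
                          several.ok = TRUE)
    if (length(col_kind) == 1L) col_kind <- rep(col_kind, ncol(values))
    if (length(col_kind) != ncol(values))
      stop("col_kind must have one entry per column")
  }
  dimnames(values) <- list(row_ids, col_ids)
  structure(list(values = values, row_ids = row_ids, col_ids = col_ids,
                 col_kind = col_kind),
            class = "raw_table")
}

#' @export
print.raw_table <- function(x, ...) {
  cat(sprintf("<raw_table> %d samples x %d features; %.2f%% missing\n",
              nrow(x$values), ncol(x$values), 100 * mean(is.na(x$values))))
  invisible(x)
}

#' Drop samples with too many missing feature values
#'
#' A row is removed when its count of missing entries is strictly greater
#' than `max_missing_count` (rows at exactly the threshold are retained).
#'
#' @param table a [raw_table()].
#' @param max_missing_count missing-entry threshold per sample (default 10000).
#' @return The filtered `raw_table`, with attribute `"removed"`, a
#'   data.frame logging removed ids and their missing counts.
#' @export
filter_samples <- function(table, max_missing_count = 10000) {
  counts <- rowSums(is.na(table$values))
  drop <- counts > max_missing_count
  if (all(drop)) stop("sample filter removed every row")
  out <- raw_table(table$values[!drop, , drop = FALSE],
                   table$row_ids[!drop], table$col_ids, table$col_kind)
  attr(out, "removed") <- data.frame(row_id = table$row_ids[drop],
                                     n_missing = counts[drop],
                                     row.names = NULL)
  out
}

#' Drop features with too high a missing rate
#'
#' A column is removed when its fraction of missing entries is strictly
#' greater than `max_missing_rate`.
#'
#' @param table a [raw_table()].
#' @param max_missing_rate missing-fraction threshold per feature (default 0.3).
#' @return The filtered `raw_table`, with attribute `"removed"` logging
#'   removed feature ids and their missing rates.
#' @export
filter_features <- function(table, max_missing_rate = 0.3) {
  rates <- colMeans(is.na(table$values))
  drop <- rates > max_missing_rate
  if (all(drop)) stop("feature filter removed every column")
  out <- raw_table(table$values[, !drop, drop = FALSE], table$row_ids,
                   table$col_ids[!drop],
                   if (is.null(table$col_kind)) NULL else table$col_kind[!drop])
  attr(out, "removed") <- data.frame(col_id = table$col_ids[drop],
                                     missing_rate = rates[drop],
                                     row.names = NULL)
  out
}

#' Mean-impute remaining gaps and standardize to mean 0, variance 1
#'
#' Remaining missing entries are replaced by the column mean over observed
#' entries; every column is then centered and scaled to sample mean 0 and
#' variance 1 (population denominator `n`, so the post-condition is exact).
#' Columns with zero variance after imputation are dropped with a warning.
#' The centering/scaling parameters are retained so held-out data can be
#' transformed on the training scale with [apply_scaling()].
#'
#' @param table a [raw_table()] (filters already applied).
#' @return list: `values` (standardized matrix, no missing), `center`,
#'   `scale` (named per retained column), `dropped` (zero-variance column
#'   ids), `table` (the standardized `raw_table`).
#' @export
impute_and_standardize <- function(table) {
  v <- table$values
  mu <- colMeans(v, na.rm = TRUE)
  for (j in seq_len(ncol(v))) {
    na <- is.na(v[, j])
    if (any(na)) v[na, j] <- mu[j]
  }
  n <- nrow(v)
  ctr <- colMeans(v)
  scl <- sqrt(colMeans(sweep(v, 2, ctr)^2)) # population sd
  keep <- scl > 0
  if (!all(keep)) {
    warning(sum(!keep), " zero-variance column(s) dropped: ",
            paste(utils::head(table$col_ids[!keep], 5), collapse = ", "))
  }
  v <- sweep(v[, keep, drop = FALSE], 2, ctr[keep])
  v <- sweep(v, 2, scl[keep], "/")
  out_tab <- raw_table(v, table$row_ids, table$col_ids[keep],
                       if (is.null(table$col_kind)) NULL else
                         table$col_kind[keep])
  list(values = v, center = ctr[keep], scale = scl[keep],
       dropped = table$col_ids[!keep], table = out_tab)
}

#' Transform new data on a stored training scale
#'
#' @param X numeric matrix whose columns match `names(center)`.
#' @param center,scale training centering/scaling parameters from
#'   [impute_and_standardize()].
#' @return the transformed matrix.
#' @export
apply_scaling <- function(X, center, scale) {
  X <- as.matrix(X)
  if (!is.null(colnames(X)) && !is.null(names(center)))
    X <- X[, names(center), drop = FALSE]
  if (ncol(X) != length(center)) stop("column mismatch against scaling parameters")
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Optional outlier-removal hook
#'
#' The published workflow mentions removing a few outliers without stating a
#' rule; this hook implements a configurable robust z-score criterion on the
#' response (|y - median| / mad > `z`) and is OFF by default.
#'
#' @param y numeric response.
#' @param method `"none"` (default) or `"robust_z"`.
#' @param z robust z-score cutoff (default 4).
#' @return logical vector, `TRUE` for rows to keep.
#' @export
flag_outliers <- function(y, method = c("none", "robust_z"), z = 4) {
  method <- match.arg(method)
  if (method == "none") return(rep(TRUE, length(y)))
  m <- stats::median(y); s <- stats::mad(y)
  if (s == 0) return(rep(TRUE, length(y)))
  abs(y - m) / s <= z
}

#' Full preprocessing pipeline for a pair of cohort tables
#'
#' Runs, per cohort: sample filter, feature filter, optional outlier hook on
#' the response, imputation and standardization (response included); then
#' intersects the surviving feature sets of the two cohorts so the design
#' matrices align column-for-column, and assembles a [cohort_pair()].
#'
#' @param table_G,table_C [raw_table()] objects for the two cohorts.
#' @param y_G,y_C raw response vectors aligned with the table rows.
#' @param max_missing_count,max_missing_rate filter thresholds.
#' @param outlier_method,outlier_z see [flag_outliers()].
#' @param include_kinds optional character vector of `col_kind` values to
#'   keep (e.g. excluding `"copy_number"` for the prediction analyses).
#' @return list: `data` (the cohort pair), `scaling` (per cohort: feature
#'   `center`/`scale` and response `y_center`/`y_scale`), `log` (filter logs).
#' @export
preprocess_pair <- function(table_G, y_G, table_C, y_C,
                            max_missing_count = 10000,
                            max_missing_rate = 0.3,
                            outlier_method = "none", outlier_z = 4,
                            include_kinds = NULL) {
  one <- function(tab, y) {
    if (!is.null(include_kinds) && !is.null(tab$col_kind)) {
      keep <- tab$col_kind %in% include_kinds
      tab <- raw_table(tab$values[, keep, drop = FALSE], tab$row_ids,
                       tab$col_ids[keep], tab$col_kind[keep])
    }
    stopifnot(length(y) == nrow(tab$values))
    t1 <- filter_samples(tab, max_missing_count)
    y <- y[match(t1$row_ids, tab$row_ids)]
    t2 <- filter_features(t1, max_missing_rate)
    feature_log <- attr(t2, "removed")
    keep_row <- flag_outliers(y, outlier_method, outlier_z)
    t2 <- raw_table(t2$values[keep_row, , drop = FALSE],
                    t2$row_ids[keep_row], t2$col_ids, t2$col_kind)
    y <- y[keep_row]
    std <- impute_and_standardize(t2)
    ys <- impute_and_standardize(raw_table(matrix(y, ncol = 1),
                                           t2$row_ids, "response"))
    list(X = std$values, y = drop(ys$values),
         center = std$center, scale = std$scale,
         y_center = ys$center, y_scale = ys$scale,
         log = list(samples = attr(t1, "removed"),
                    features = feature_log,
                    outliers = t2$row_ids[!keep_row],
                    dropped_zero_var = std$dropped))
  }
  g <- one(table_G, y_G)
  c_ <- one(table_C, y_C)
  common <- intersect(colnames(g$X), colnames(c_$X))
  if (length(common) == 0L) stop("no features survive in both cohorts")
  data <- cohort_pair(g$X[, common, drop = FALSE], g$y,
                      c_$X[, common, drop = FALSE], c_$y)
  list(data = data,
       scaling = list(G = g[c("center", "scale", "y_center", "y_scale")],
                      C = c_[c("center", "scale", "y_center", "y_scale")]),
       log = list(G = g$log, C = c_$log, common_features = common))
}
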