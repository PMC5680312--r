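#' Repeated-cross-validation stability analysis
#'
#' Runs `n_runs` independent rounds of the full tuned fit: each round
#' re-randomizes the cross-validation folds (pilot and adaptive stage) and
#' re-selects the penalties, then records which coefficients are nonzero.
#' For every feature and coefficient ledger (`beta` and `delta` under
#' Formulation 1; `beta`, `delta_G`, `delta_C` under Formulation 2) the
#' output accumulates the selection frequency (fraction of runs with a
#' nonzero estimate) and the average coefficient over the runs in which the
#' feature appears.
#'
#' @param data a screened, preprocessed [cohort_pair()].
#' @param n_runs number of repeated fits (default 200).
#' @param seed master seed; per-run seeds are derived from it.
#' @param formulation `"F1"` or `"F2"`.
#' @param options a [shared_options()] list.
#' @return An object of class `variable_list`: a named list of ledgers, each
#'   a data.frame (`feature`, `frequency`, `avg_coefficient`) restricted to
#'   features that appeared at least once; attributes `n_runs`,
#'   `formulation`.
#' @export
run_stability <- function(data, n_runs = 200L, seed = 1L,
                          formulation = c("F1", "F2"),
                          options = shared_options()) {
  formulation <- match.arg(formulation)
  p <- n_features(data)
  ledger_names <- if (formulation == "F1") c("beta", "delta") else
    c("beta", "delta_G", "delta_C")
  hits <- sums <- sapply(ledger_names, function(x) numeric(p),
                         simplify = FALSE)
  run_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_runs))
  for (run in seq_len(n_runs)) {
    fit <- fit_shared(data, formulation = formulation, options = options,
                      seed = run_seeds[run])
    for (lg in ledger_names) {
      v <- fit[[lg]]
      nz <- v != 0
      hits[[lg]][nz] <- hits[[lg]][nz] + 1
      sums[[lg]][nz] <- sums[[lg]][nz] + v[nz]
    }
  }
  ledgers <- lapply(ledger_names, function(lg) {
    appeared <- hits[[lg]] > 0
    data.frame(feature = data$feature_names[appeared],
               frequency = hits[[lg]][appeared] / n_runs,
               avg_coefficient = sums[[lg]][appeared] / hits[[lg]][appeared],
               stringsAsFactors = FALSE)
  })
  names(ledgers) <- ledger_names
  structure(ledgers, class = "variable_list", n_runs = n_runs,
            formulation = formulation,
            feature_names = data$feature_names)
}

#' @export
print.variable_list <- function(x, ...) {
  cat(sprintf("<variable_list> %d runs, formulation %s\n",
              attr(x, "n_runs"), attr(x, "formulation")))
  for (lg in names(x))
    cat(sprintf("  %s: %d features appeared, %d with frequency >= 0.8\n",
                lg, nrow(x[[lg]]), sum(x[[lg]]$frequency >= 0.8)))
  invisible(x)
}

#' Select significant markers from a variable list
#'
#' Within one coefficient ledger, let `m` and `s` be the mean and standard
#' deviation of the average coefficients over all entries of the list. A
#' feature is selected when its frequency is at least `freq_threshold` and
#' its average coefficient lies strictly beyond `m +/- sd_multiplier * s`.
#'
#' @param vlist a [run_stability()] result.
#' @param freq_threshold selection-frequency gate (default 0.8).
#' @param sd_multiplier effect-size gate in s.d. units (default 2).
#' @param ledger which ledger to apply the rule to (default `"beta"`).
#' @return character vector of selected feature names (empty, with a
#'   warning, when the ledger has fewer than two entries).
#' @export
select_significant <- function(vlist, freq_threshold = 0.8,
                               sd_multiplier = 2, ledger = "beta") {
  stopifnot(inherits(vlist, "variable_list"))
  if (!ledger %in% names(vlist))
    stop("no ledger '", ledger, "' in this variable list")
  df <- vlist[[ledger]]
  if (nrow(df) < 2L) {
    warning("fewer than 2 entries in ledger '", ledger,
            "'; returning the empty set")
    return(character(0))
  }
  m <- mean(df$avg_coefficient)
  s <- stats::sd(df$avg_coefficient)
  sel <- df$frequency >= freq_threshold &
    (df$avg_coefficient > m + sd_multiplier * s |
       df$avg_coefficient < m - sd_multiplier * s)
  df$feature[sel]
}

#' Assemble the drug-by-cohort signature matrix
#'
#' Rows are (drug, cohort-label) pairs — `<drug>_g` for the G-side effects
#' and `<drug>_c` for the C-side effects; columns are the union of markers
#' significant (per [select_significant()]) in at least one ledger of at
#' least one drug. Cells carry the signed average effect size: `beta` for g
#' rows and `beta + delta` for c rows under Formulation 1 (`beta + delta_G`
#' / `beta + delta_C` under Formulation 2), using the per-ledger average
#' coefficients from the stability runs. The significance mask marks g
#' cells significant in the `beta` ledger and c cells significant in the
#' `beta` or discrepancy ledger.
#'
#' @param drug_results named list (one element per drug) of
#'   [run_stability()] results.
#' @param freq_threshold,sd_multiplier passed to [select_significant()].
#' @return An object of class `signature_matrix`: `effects` (numeric matrix),
#'   `mask` (logical matrix), `formulation`. Empty marker union yields
#'   zero-column matrices with a warning.
#' @export
build_signature_matrix <- function(drug_results, freq_threshold = 0.8,
                                   sd_multiplier = 2) {
  stopifnot(length(drug_results) > 0, !is.null(names(drug_results)))
  formulation <- attr(drug_results[[1]], "formulation")
  sig <- lapply(drug_results, function(vl) {
    lapply(setNames(nm = names(vl)), function(lg)
      suppressWarnings(select_significant(vl, freq_threshold, sd_multiplier,
                                          ledger = lg)))
  })
  markers <- sort(unique(unlist(sig)))
  drugs <- names(drug_results)
  rows <- as.vector(t(outer(drugs, c("g", "c"), paste, sep = "_")))
  effects <- matrix(0, length(rows), length(markers),
                    dimnames = list(rows, markers))
  mask <- matrix(FALSE, length(rows), length(markers),
                 dimnames = list(rows, markers))
  if (length(markers) == 0L) {
    warning("no marker passed the inclusion rule for any drug")
    return(structure(list(effects = effects, mask = mask,
                          formulation = formulation),
                     class = "signature_matrix"))
  }
  avg_of <- function(vl, lg, mk) {
    i <- match(mk, vl[[lg]]$feature)
    ifelse(is.na(i), 0, vl[[lg]]$avg_coefficient[i])
  }
  for (d in drugs) {
    vl <- drug_results[[d]]
    b <- avg_of(vl, "beta", markers)
    if (formulation == "F1") {
      g_eff <- b
      c_eff <- b + avg_of(vl, "delta", markers)
      c_sig <- markers %in% c(sig[[d]]$beta, sig[[d]]$delta)
    } else {
      g_eff <- b + avg_of(vl, "delta_G", markers)
      c_eff <- b + avg_of(vl, "delta_C", markers)
      c_sig <- markers %in% c(sig[[d]]$beta, sig[[d]]$delta_G,
                              sig[[d]]$delta_C)
    }
    effects[paste0(d, "_g"), ] <- g_eff
    effects[paste0(d, "_c"), ] <- c_eff
    mask[paste0(d, "_g"), ] <- markers %in% sig[[d]]$beta
    mask[paste0(d, "_c"), ] <- c_sig
  }
  structure(list(effects = effects, mask = mask, formulation = formulation),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat(sprintf("<signature_matrix %s> %d drug-cohort rows x %d markers\n",
              x$formulation, nrow(x$effects), ncol(x$effects)))
  invisible(x)
}

#' Render a signature matrix as a heatmap
#'
#' Diverging palette centered at zero: blue for positive estimated effects,
#' red for negative, white for null.
#'
#' @param sig a [build_signature_matrix()] result.
#' @param file optional path; when given the heatmap is written there
#'   (format from the extension, e.g. `.png` or `.pdf`).
#' @param ... passed to [pheatmap::pheatmap()].
#' @return the pheatmap object, invisibly.
#' @export
plot_signature_matrix <- function(sig, file = NA, ...) {
  stopifnot(inherits(sig, "signature_matrix"))
  if (ncol(sig$effects) == 0L) stop("empty signature matrix")
  lim <- max(abs(sig$effects))
  if (lim == 0) lim <- 1
  breaks <- seq(-lim, lim, length.out = 101)
  pal <- grDevices::colorRampPalette(c("#b2182b", "white", "#2166ac"))(100)
  ph <- pheatmap::pheatmap(sig$effects, color = pal, breaks = breaks,
                           cluster_rows = FALSE, cluster_cols = FALSE,
                           filename = file, silent = TRUE, ...)
  invisible(ph)
}
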