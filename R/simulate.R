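#' Configuration of the synthetic cohort-pair generator
#'
#' Defaults are the conditions of the replicated comparison study: p = 1000
#' features with AR(1) correlation 0.75, nonzero shared coefficients in 16
#' blocks of 3 consecutive indices with values drawn from Normal(1.5,
#' variance 1), discrepancy support of 20 indices inside the shared support
#' plus 10 outside with values from Normal(0, variance 0.5), unit noise
#' variance, cohort sizes n_G = 100 (varied 100-400 in the study), n_C =
#' 300, a test set of 100 drawn from the G-side equation, and 200
#' replicates. `reduced = TRUE` switches to the desk-scale preset (p = 200,
#' 50 replicates) used for continuous testing.
#'
#' @param p feature count.
#' @param rho AR(1) correlation.
#' @param n_blocks,block_size shared-support block structure.
#' @param beta_mean,beta_var distribution of nonzero shared coefficients.
#' @param n_delta_on,n_delta_off discrepancy support sizes inside/outside
#'   the shared support.
#' @param delta_mean,delta_var distribution of nonzero discrepancies.
#' @param noise_variance error variance of both cohort equations.
#' @param n_G,n_C,n_test sample sizes.
#' @param n_replicates replicate count for [run_simulation_study()].
#' @param value_scale `"variance"` (default) reads the second Normal
#'   parameter as a variance; `"sd"` as a standard deviation.
#' @param block_placement `"random"` places the blocks at uniformly random
#'   non-overlapping positions; `"fixed"` spaces them evenly.
#' @param reduced logical; apply the desk-scale preset.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(p = 1000L, rho = 0.75, n_blocks = 16L, block_size = 3L,
                       beta_mean = 1.5, beta_var = 1,
                       n_delta_on = 20L, n_delta_off = 10L,
                       delta_mean = 0, delta_var = 0.5,
                       noise_variance = 1,
                       n_G = 100L, n_C = 300L, n_test = 100L,
                       n_replicates = 200L,
                       value_scale = c("variance", "sd"),
                       block_placement = c("random", "fixed"),
                       reduced = FALSE) {
  if (reduced) { p <- 200L; n_replicates <- 50L }
  value_scale <- match.arg(value_scale)
  block_placement <- match.arg(block_placement)
  support <- n_blocks * block_size
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (support > p) stop("n_blocks * block_size must not exceed p")
  if (n_delta_on > support)
    stop("n_delta_on exceeds the shared support size (", support, ")")
  if (n_delta_off > p - support)
    stop("n_delta_off exceeds the shared zero set (", p - support, ")")
  if (beta_var <= 0 || delta_var <= 0 || noise_variance <= 0)
    stop("all variances must be positive")
  structure(list(p = as.integer(p), rho = rho,
                 n_blocks = as.integer(n_blocks),
                 block_size = as.integer(block_size),
                 beta_mean = beta_mean, beta_var = beta_var,
                 n_delta_on = as.integer(n_delta_on),
                 n_delta_off = as.integer(n_delta_off),
                 delta_mean = delta_mean, delta_var = delta_var,
                 noise = noise_model(noise_variance),
                 n_G = as.integer(n_G), n_C = as.integer(n_C),
                 n_test = as.integer(n_test),
                 n_replicates = as.integer(n_replicates),
                 value_scale = value_scale,
                 block_placement = block_placement),
            class = "sim_config")
}

#' AR(1) covariance matrix
#'
#' Entries `rho^|i-j|` with unit diagonal. The attribute `"root"` carries an
#' upper-triangular Cholesky factor suitable for sampling.
#'
#' @param p dimension.
#' @param rho correlation parameter, `|rho| < 1`.
#' @return `p x p` covariance matrix with attribute `"root"`.
#' @export
ar1_covariance <- function(p, rho) {
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (p < 1) stop("p must be >= 1")
  S <- rho^abs(outer(seq_len(p), seq_len(p), "-"))
  attr(S, "root") <- chol(S)
  S
}

# Exact draw of n i.i.d. rows from N_p(0, AR1(rho)) via the autoregressive
# recursion (avoids a p x p factorization at large p).
ar1_draw <- function(n, p, rho) {
  Z <- matrix(stats::rnorm(n * p), n, p)
  X <- Z
  if (p > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:p) X[, j] <- rho * X[, j - 1] + s * Z[, j]
  }
  X
}

#' Draw the true coefficient vectors of a synthetic scenario
#'
#' The shared support is placed as `n_blocks` non-overlapping runs of
#' `block_size` consecutive indices (uniformly at random over all such
#' placements, or evenly spaced under `block_placement = "fixed"`); nonzero
#' shared values are Normal(`beta_mean`, `beta_var`). The discrepancy
#' support takes `n_delta_on` indices inside the shared support and
#' `n_delta_off` outside, with values Normal(`delta_mean`, `delta_var`).
#'
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @return An object of class `sim_truth`: `beta_true`, `delta_true`,
#'   `support_beta`, `support_delta`, `rho`, `covariance_root` (a function
#'   drawing `n` feature rows).
#' @export
draw_truth <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(seed, {
    p <- config$p; L <- config$block_size; B <- config$n_blocks
    if (config$block_placement == "random") {
      # uniform non-overlapping placement via the gap bijection
      picks <- sort(sample.int(p - B * (L - 1), B))
      starts <- picks + (seq_len(B) - 1L) * (L - 1L)
    } else {
      starts <- floor(seq(1, p - L + 1, length.out = B))
    }
    support_beta <- as.integer(outer(0:(L - 1), starts, "+"))
    rnorm2 <- function(n, mu, v) {
      s <- if (config$value_scale == "variance") sqrt(v) else v
      stats::rnorm(n, mu, s)
    }
    beta <- numeric(p)
    beta[support_beta] <- rnorm2(length(support_beta),
                                 config$beta_mean, config$beta_var)
    on_idx <- sample(support_beta, config$n_delta_on)
    off_idx <- sample(setdiff(seq_len(p), support_beta), config$n_delta_off)
    support_delta <- sort(c(on_idx, off_idx))
    delta <- numeric(p)
    delta[support_delta] <- rnorm2(length(support_delta),
                                   config$delta_mean, config$delta_var)
    rho <- config$rho
    structure(list(beta_true = beta, delta_true = delta,
                   support_beta = sort(support_beta),
                   support_delta = support_delta, rho = rho,
                   covariance_root = function(n) ar1_draw(n, p, rho)),
              class = "sim_truth")
  })
}

#' Generate a synthetic cohort pair plus test set
#'
#' Feature rows are i.i.d. `N_p(0, Sigma)` with the AR(1) covariance; G rows
#' follow `y = x' beta + e`, C rows `y = x' (beta + delta) + e`, and the
#' test set is drawn from the G-side equation, with
#' `e ~ Normal(0, noise_variance)`.
#'
#' @param truth a [draw_truth()] result.
#' @param config the matching [sim_config()].
#' @param seed integer seed.
#' @return list: `pair` (a [cohort_pair()]), `test` (list `X`, `y`).
#' @export
generate_cohorts <- function(truth, config, seed = NULL) {
  stopifnot(inherits(truth, "sim_truth"), inherits(config, "sim_config"))
  with_seed(seed, {
    p <- config$p
    sd_e <- sqrt(config$noise$variance)
    draw <- function(n, coefs) {
      X <- truth$covariance_root(n)
      y <- drop(X %*% coefs) + stats::rnorm(n, 0, sd_e)
      list(X = X, y = y)
    }
    g <- draw(config$n_G, truth$beta_true)
    c_ <- draw(config$n_C, truth$beta_true + truth$delta_true)
    te <- draw(config$n_test, truth$beta_true)
    nm <- sprintf("f%04d", seq_len(p))
    colnames(g$X) <- colnames(c_$X) <- colnames(te$X) <- nm
    list(pair = cohort_pair(g$X, g$y, c_$X, c_$y), test = te)
  })
}

# Safe correlation: NA when either argument is constant or all zero.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Replicated comparison study on synthetic cohort pairs
#'
#' For each replicate a fresh truth and datasets are drawn; the data-shared
#' model and three baselines (individual-G, individual-C, pooled G+C) are
#' fitted with cross-validated tuning, and the test mean squared prediction
#' error is recorded for five prediction rules: shared `beta` ("shared_G"),
#' shared `beta + delta` ("shared_C"), individual-G, individual-C, pooled.
#' Also recorded per replicate: `cor(delta_hat, delta_true)` from the shared
#' fit, `cor(beta_hat_C - beta_hat_G, delta_true)` from the difference of
#' the individual fits, `cor(beta_hat, beta_true)` (shared) and
#' `cor(beta_hat_G, beta_true)` (individual-G).
#'
#' @param config a [sim_config()].
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param options a [shared_options()] list used for every model.
#' @param progress print a line per replicate.
#' @return An object of class `sim_study`: `replicates` (long data.frame of
#'   per-replicate metrics), `mse_summaries` (five-number summary per
#'   method), `cor_summaries`, `config`.
#' @export
run_simulation_study <- function(config, seed = 1L,
                                 options = shared_options(),
                                 progress = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  R <- config$n_replicates
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 2L * R))
  methods <- c("shared_G", "shared_C", "individual_G", "individual_C",
               "pooled")
  rows <- vector("list", R)
  for (rr in seq_len(R)) {
    truth <- draw_truth(config, rep_seeds[2L * rr - 1L])
    dat <- generate_cohorts(truth, config, rep_seeds[2L * rr])
    fit_seed <- rep_seeds[2L * rr] %% 1000000L
    sh <- fit_shared(dat$pair, options = options, seed = fit_seed)
    iG <- fit_individual(dat$pair$X_G, dat$pair$y_G, options = options,
                         seed = fit_seed + 1L)
    iC <- fit_individual(dat$pair$X_C, dat$pair$y_C, options = options,
                         seed = fit_seed + 2L)
    po <- fit_individual(rbind(dat$pair$X_G, dat$pair$X_C),
                         c(dat$pair$y_G, dat$pair$y_C), options = options,
                         seed = fit_seed + 3L)
    mse <- c(
      shared_G = mean((dat$test$y - predict_shared(sh, dat$test$X, "as_G"))^2),
      shared_C = mean((dat$test$y - predict_shared(sh, dat$test$X, "as_C"))^2),
      individual_G = mean((dat$test$y - drop(dat$test$X %*% iG$coef))^2),
      individual_C = mean((dat$test$y - drop(dat$test$X %*% iC$coef))^2),
      pooled = mean((dat$test$y - drop(dat$test$X %*% po$coef))^2))
    rows[[rr]] <- data.frame(
      replicate = rr, method = methods, mse = unname(mse[methods]),
      cor_delta_shared = safe_cor(sh$delta, truth$delta_true),
      cor_delta_diff = safe_cor(iC$coef - iG$coef, truth$delta_true),
      cor_beta_shared = safe_cor(sh$beta, truth$beta_true),
      cor_beta_G = safe_cor(iG$coef, truth$beta_true),
      stringsAsFactors = FALSE)
    if (progress)
      message(sprintf("replicate %d/%d: shared_G mse = %.3f", rr, R,
                      mse["shared_G"]))
  }
  reps <- do.call(rbind, rows)
  mse_summaries <- lapply(split(reps$mse, reps$method), five_number_summary)
  firsts <- reps[reps$method == "shared_G", ]
  cor_summaries <- lapply(firsts[c("cor_delta_shared", "cor_delta_diff",
                                   "cor_beta_shared", "cor_beta_G")],
                          function(v) five_number_summary(v[!is.na(v)]))
  structure(list(replicates = reps, mse_summaries = mse_summaries,
                 cor_summaries = cor_summaries, config = config),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> p = %d, n_G = %d, n_C = %d, %d replicates\n",
              x$config$p, x$config$n_G, x$config$n_C,
              max(x$replicates$replicate)))
  med <- vapply(x$mse_summaries, function(s) s$median, numeric(1))
  cat("  median test MSE:",
      paste(sprintf("%s = %.3f", names(med), med), collapse = ", "), "\n")
  invisible(x)
}
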