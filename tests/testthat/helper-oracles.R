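# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths: plain loops, optim, and sort().

# Term-by-term objective evaluation with explicit loops.
oracle_objective <- function(data, beta, delta, lambda1, lambda2, r,
                             omega, psi, loss = "symmetric") {
  rss_G <- 0
  for (i in seq_along(data$y_G)) {
    pred <- 0
    for (j in seq_along(beta)) pred <- pred + data$X_G[i, j] * beta[j]
    rss_G <- rss_G + (data$y_G[i] - pred)^2
  }
  rss_C <- 0
  for (i in seq_along(data$y_C)) {
    pred <- 0
    for (j in seq_along(beta))
      pred <- pred + data$X_C[i, j] * (beta[j] + delta[j])
    rss_C <- rss_C + (data$y_C[i] - pred)^2
  }
  lo <- if (loss == "symmetric") 0.5 * (rss_G + rss_C) else
    0.5 * rss_G + rss_C
  l1 <- 0
  for (j in seq_along(beta)) {
    if (beta[j] != 0) l1 <- l1 + omega[j] * abs(beta[j])
    if (delta[j] != 0) l1 <- l1 + r * psi[j] * abs(delta[j])
  }
  l2 <- sum(beta^2) + r * sum(delta^2)
  as.numeric(unname(lo + lambda1 * l1 + lambda2 * l2))
}

# General-purpose minimizer oracle for the weighted elastic net: split each
# coefficient into positive and negative parts, making the objective smooth
# on the nonnegative orthant, and solve with L-BFGS-B.
oracle_enet <- function(X, y, l1w, l2w, lambda1, lambda2, obsw = NULL) {
  if (is.null(obsw)) obsw <- rep(1, nrow(X))
  keep <- is.finite(l1w)
  Xk <- X[, keep, drop = FALSE]
  w1 <- l1w[keep]; w2 <- l2w[keep]
  m <- ncol(Xk)
  fn <- function(par) {
    th <- par[1:m] - par[m + 1:m]
    r <- y - drop(Xk %*% th)
    0.5 * sum(obsw * r^2) + lambda1 * sum(w1 * (par[1:m] + par[m + 1:m])) +
      lambda2 * sum(w2 * th^2)
  }
  gr <- function(par) {
    th <- par[1:m] - par[m + 1:m]
    r <- y - drop(Xk %*% th)
    g <- -drop(crossprod(Xk, obsw * r)) + 2 * lambda2 * w2 * th
    c(g + lambda1 * w1, -g + lambda1 * w1)
  }
  o <- stats::optim(rep(0, 2 * m), fn, gr, method = "L-BFGS-B",
                    lower = 0, control = list(maxit = 5000, factr = 10))
  th <- numeric(ncol(X))
  th[keep] <- o$par[1:m] - o$par[m + 1:m]
  list(coef = th, objective = o$value)
}

# Quartiles by explicit linear interpolation between sorted order statistics.
oracle_five_numbers <- function(v) {
  s <- sort(v)
  n <- length(s)
  interp <- function(prob) {
    h <- (n - 1) * prob + 1
    lo <- floor(h); hi <- ceiling(h)
    s[lo] + (h - lo) * (s[hi] - s[lo])
  }
  c(s[1], interp(0.25), interp(0.5), interp(0.75), s[n])
}

# Small random cohort pair with planted coefficients.
make_test_pair <- function(seed, n_G = 30, n_C = 30, p = 10,
                           beta = NULL, delta = NULL, noise_sd = 0.5) {
  set.seed(seed)
  if (is.null(beta)) beta <- c(rep(1.5, min(3, p)), rep(0, p - min(3, p)))
  if (is.null(delta)) delta <- rep(0, p)
  X_G <- matrix(rnorm(n_G * p), n_G, p)
  X_C <- matrix(rnorm(n_C * p), n_C, p)
  y_G <- drop(X_G %*% beta) + rnorm(n_G, 0, noise_sd)
  y_C <- drop(X_C %*% (beta + delta)) + rnorm(n_C, 0, noise_sd)
  cohort_pair(X_G, y_G, X_C, y_C)
}

# Small options preset keeping CV affordable in unit tests.
fast_options <- function(...) {
  args <- list(n_lambda1 = 10L, lambda2_values = c(0.01, 0.1, 1),
               cv_folds = 5L)
  overrides <- list(...)
  args[names(overrides)] <- overrides
  do.call(shared_options, args)
}
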