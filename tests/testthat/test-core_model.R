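test_that("evaluate_objective: zero-coefficient and penalty-only cases", {
  # loss only: beta = delta = 0 -> 0.5 * (1^2 + 1^2 + 2^2) = 3
  pair <- cohort_pair(matrix(0, 2, 2), c(1, 1), matrix(0, 1, 2), 2)
  pen <- penalty_spec(5, 7, p = 2)
  expect_equal(as.numeric(evaluate_objective(pair, c(0, 0), c(0, 0), pen)), 3)

  # penalty only: zero design/response, beta = (1,0), delta = (0,1)
  zero_pair <- cohort_pair(matrix(0, 2, 2), c(0, 0), matrix(0, 1, 2), 0)
  r <- 1 / sqrt(2)
  pen <- penalty_spec(2, 1, r = r, omega = c(1, 1), psi = c(1, 1))
  val <- evaluate_objective(zero_pair, c(1, 0), c(0, 1), pen)
  expect_equal(as.numeric(val), 3 * (1 + r), tolerance = 1e-12)
  parts <- attr(val, "parts")
  expect_equal(parts$loss + parts$l1 + parts$l2, as.numeric(val))
})

test_that("evaluate_objective matches the brute-force oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    p <- 4
    pair <- make_test_pair(seed, n_G = 6, n_C = 6, p = p)
    beta <- rnorm(p); delta <- rnorm(p)
    omega <- runif(p, 0.5, 2); psi <- runif(p, 0.5, 2)
    l1 <- runif(1, 0, 2); l2 <- runif(1, 0, 2); r <- 1 / sqrt(2)
    pen <- penalty_spec(l1, l2, r, omega, psi)
    got <- as.numeric(unname(evaluate_objective(pair, beta, delta, pen)))
    want <- oracle_objective(pair, beta, delta, l1, l2, r, omega, psi)
    expect_equal(got, want, tolerance = 1e-12)
    # asymmetric loss reading agrees with the oracle too
    got_a <- as.numeric(unname(evaluate_objective(
      pair, beta, delta, pen, loss = "asymmetric_half")))
    want_a <- oracle_objective(pair, beta, delta, l1, l2, r, omega, psi,
                               loss = "asymmetric_half")
    expect_equal(got_a, want_a, tolerance = 1e-12)
  }
})

test_that("evaluate_objective rejects bad inputs", {
  pair <- make_test_pair(1, p = 4)
  pen <- penalty_spec(1, 1, p = 4)
  expect_error(evaluate_objective(pair, rep(0, 3), rep(0, 4), pen), "beta")
  expect_error(evaluate_objective(pair, rep(0, 4), rep(0, 5), pen), "delta")
  pen_inf <- penalty_spec(1, 1, omega = c(Inf, 1, 1, 1), psi = rep(1, 4))
  expect_error(evaluate_objective(pair, c(1, 0, 0, 0), rep(0, 4), pen_inf),
               "excluded")
})

test_that("build_stacked_design has the documented block structure", {
  pair <- cohort_pair(matrix(1:4, 2, 2), c(1, 2), matrix(c(5, 6), 1, 2), 3)
  st <- build_stacked_design(pair, "F1")
  expect_equal(dim(st$X), c(3L, 4L))
  expect_equal(unname(st$X[1:2, 3:4]), matrix(0, 2, 2)) # top-right zero block
  expect_equal(unname(st$X[3, ]), c(5, 6, 5, 6))     # bottom row repeats x_C
  expect_equal(st$y, c(1, 2, 3))
  expect_equal(st$roles$block, rep(c("beta", "delta"), each = 2))
  expect_equal(st$cohort, c("G", "G", "C"))

  st2 <- build_stacked_design(pair, "F2")
  expect_equal(dim(st2$X), c(3L, 6L))
  expect_equal(st2$roles$block, rep(c("beta", "delta_G", "delta_C"), each = 2))

  # delta = 0 collapses F1 predictions to the pooled single-model design
  theta <- c(0.3, -0.7)
  pooled <- rbind(pair$X_G, pair$X_C) %*% theta
  expect_equal(drop(st$X %*% c(theta, 0, 0)), drop(pooled))
})

test_that("F2 stacked fit reproduces F1 fitted responses after transform", {
  pair <- make_test_pair(11, n_G = 40, n_C = 40, p = 6,
                         delta = c(1, rep(0, 5)))
  opts <- fast_options(pilot_lambda = c(0.5, 0.01))
  f1 <- fit_shared(pair, lambda1 = 0.5, lambda2 = 0.01, options = opts,
                   seed = 1)
  f2 <- fit_shared(pair, lambda1 = 0.5, lambda2 = 0.01, formulation = "F2",
                   options = opts, seed = 1)
  tr <- transform_formulations(f2)
  for (mode in c("as_G", "as_C")) {
    X <- if (mode == "as_G") pair$X_G else pair$X_C
    expect_equal(predict_shared(tr, X, mode), predict_shared(f2, X, mode),
                 tolerance = 1e-10)
    # the two formulations' fitted surfaces agree closely at shared penalties
    expect_equal(predict_shared(tr, X, mode), predict_shared(f1, X, mode),
                 tolerance = 1e-2)
  }
})

test_that("solver: one-dimensional closed form", {
  # X = (1,1)', y = (3,1), lambda1 = 1, lambda2 = 0.5:
  # beta = soft(x'y, 1) / (x'x + 2*0.5) = (4 - 1) / 3 = 1
  sol <- solve_weighted_enet(matrix(c(1, 1)), c(3, 1), 1, 1, 1, 0.5)
  expect_equal(unname(sol$coef), 1, tolerance = 1e-10)
  expect_true(sol$converged)
})

test_that("solver: full shrinkage at lambda_max and NaN rejection", {
  set.seed(42)
  X <- matrix(rnorm(60), 20, 3); y <- rnorm(20)
  w1 <- c(1, 2, 0.5)
  lmax <- lambda_max_weighted(X, y, w1)
  sol <- solve_weighted_enet(X, y, w1, rep(1, 3), lmax, 0.1)
  expect_equal(unname(sol$coef), rep(0, 3))
  sol2 <- solve_weighted_enet(X, y, w1, rep(1, 3), lmax * 0.99, 0.1)
  expect_gt(sum(sol2$coef != 0), 0)
  expect_error(solve_weighted_enet(X, c(y[-1], NaN), w1, rep(1, 3), 1, 0.1),
               "NaN")
})

test_that("solver matches the L-BFGS-B oracle and passes KKT (spot check)", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30; m <- 8
    X <- matrix(rnorm(n * m), n, m)
    y <- drop(X %*% c(2, -1, rep(0, m - 2))) + rnorm(n)
    w1 <- runif(m, 0.5, 2); w2 <- runif(m, 0.5, 2)
    l1 <- runif(1, 0.1, 3); l2 <- runif(1, 0.01, 1)
    sol <- solve_weighted_enet(X, y, w1, w2, l1, l2, tol = 1e-9)
    ora <- oracle_enet(X, y, w1, w2, l1, l2)
    expect_lt(abs(sol$objective - ora$objective) / abs(ora$objective), 1e-6)
    expect_true(check_kkt(X, y, sol$coef, w1, w2, l1, l2, tol = 1e-6))
  }
})

test_that("solver objective is non-increasing across sweeps", {
  set.seed(3)
  n <- 25; m <- 6
  X <- matrix(rnorm(n * m), n, m)
  y <- drop(X %*% c(1.5, -1, 0.5, rep(0, 3))) + rnorm(n)
  w1 <- rep(1, m); w2 <- rep(1, m)
  objs <- vapply(1:12, function(s)
    solve_weighted_enet(X, y, w1, w2, 0.3, 0.05, max_sweeps = s)$objective,
    numeric(1))
  expect_true(all(diff(objs) <= 1e-10))
})

test_that("excluded coordinates stay at zero", {
  set.seed(9)
  X <- matrix(rnorm(80), 20, 4)
  y <- drop(X %*% c(3, 3, 0, 0)) + rnorm(20)
  sol <- solve_weighted_enet(X, y, c(1, Inf, 1, Inf), rep(1, 4), 0.5, 0.1)
  expect_equal(unname(sol$coef[c(2, 4)]), c(0, 0))
  ora <- oracle_enet(X, y, c(1, Inf, 1, Inf), rep(1, 4), 0.5, 0.1)
  expect_lt(abs(sol$objective - ora$objective) / ora$objective, 1e-6)
})

test_that("fit_shared: large lambda1 gives the all-zero fit", {
  pair <- make_test_pair(5, p = 6)
  fit <- fit_shared(pair, lambda1 = 1e6, lambda2 = 0.1,
                    options = fast_options(pilot_lambda = c(0.1, 0.01)))
  expect_equal(unname(fit$beta), rep(0, 6))
  expect_equal(unname(fit$delta), rep(0, 6))
})

test_that("fit_shared at zero penalties matches stacked least squares", {
  pair <- make_test_pair(7, n_G = 40, n_C = 40, p = 5,
                         delta = c(0.5, rep(0, 4)))
  # floor the weights so no coordinate is excluded; lambda = 0 exactly
  fit <- fit_shared(pair, lambda1 = 0, lambda2 = 0,
                    options = fast_options(pilot_lambda = c(0.01, 0.001),
                                           weight_floor = 1e-6, tol = 1e-10))
  st <- build_stacked_design(pair, "F1")
  ls <- qr.solve(st$X, st$y)
  expect_equal(unname(c(fit$beta, fit$delta)), unname(ls), tolerance = 1e-8)
})

test_that("fit_shared: concordant cohorts give small discrepancies", {
  # delta_true = 0, strong signal: ||delta||_1 / ||beta||_1 <= 0.1 (median)
  ratios <- vapply(1:7, function(seed) {
    pair <- make_test_pair(seed, n_G = 150, n_C = 150, p = 20,
                           beta = c(rep(2, 5), rep(0, 15)), noise_sd = 1)
    fit <- fit_shared(pair, options = fast_options(), seed = seed)
    sum(abs(fit$delta)) / max(sum(abs(fit$beta)), 1e-12)
  }, numeric(1))
  expect_lte(median(ratios), 0.1)
})

test_that("fit_shared degenerates gracefully on an empty cohort", {
  set.seed(21)
  X <- matrix(rnorm(200), 40, 5)
  y <- drop(X %*% c(2, -2, 0, 0, 0)) + rnorm(40, 0, 0.5)
  pair <- cohort_pair(X, y, matrix(numeric(0), 0, 5), numeric(0))
  expect_warning(fit <- fit_shared(pair, options = fast_options(), seed = 2),
                 "empty")
  expect_equal(unname(fit$delta), rep(0, 5))
  expect_true("empty_cohort" %in% fit$flags)
  expect_gt(sum(fit$beta != 0), 0)
})

test_that("transform_formulations identities and prediction invariance", {
  # forced by the printed identities
  f2 <- structure(list(beta = c(1, 0), delta_G = c(0.5, 0),
                       delta_C = c(0, 0.2), formulation = "F2",
                       flags = character(), feature_names = c("a", "b")),
                  class = "shared_fit")
  f1 <- transform_formulations(f2)
  expect_equal(unname(f1$beta), c(1.5, 0))
  expect_equal(unname(f1$delta), c(-0.5, 0.2))

  # identity case
  f2$delta_G <- c(0, 0); f2$delta_C <- c(0, 0)
  f1 <- transform_formulations(f2)
  expect_equal(f1$beta, f2$beta)
  expect_equal(unname(f1$delta), c(0, 0))

  # random F2 fits: per-observation predictions preserved to 1e-12,
  # and F1 -> F2 -> F1 roundtrips exactly
  set.seed(31)
  for (rep in 1:5) {
    p <- 6
    f2 <- structure(list(beta = rnorm(p), delta_G = rnorm(p),
                         delta_C = rnorm(p), formulation = "F2",
                         flags = character(),
                         feature_names = paste0("f", 1:p)),
                    class = "shared_fit")
    X <- matrix(rnorm(8 * p), 8, p)
    f1 <- transform_formulations(f2)
    expect_equal(predict_shared(f1, X, "as_G"), predict_shared(f2, X, "as_G"),
                 tolerance = 1e-12)
    expect_equal(predict_shared(f1, X, "as_C"), predict_shared(f2, X, "as_C"),
                 tolerance = 1e-12)
    back <- transform_formulations(f1)
    expect_equal(back$beta + back$delta_G, f1$beta)
    expect_equal(back$delta_C - back$delta_G, f1$delta)
  }
})

test_that("predict_shared basics", {
  fit <- structure(list(beta = c(1, -1), delta = c(0.5, 0),
                        formulation = "F1", flags = character(),
                        feature_names = c("a", "b")),
                   class = "shared_fit")
  expect_equal(predict_shared(fit, matrix(0, 3, 2), "as_G"), rep(0, 3))
  expect_error(predict_shared(fit, matrix(0, 3, 4)), "columns")
  fit$delta <- c(0, 0)
  X <- matrix(rnorm(10), 5, 2)
  expect_equal(predict_shared(fit, X, "as_G"), predict_shared(fit, X, "as_C"))
  # direct arithmetic oracle
  fit$delta <- c(0.3, -0.2)
  want <- numeric(5)
  for (i in 1:5) want[i] <- X[i, 1] * 1.3 + X[i, 2] * (-1.2)
  expect_equal(predict_shared(fit, X, "as_C"), want, tolerance = 1e-12)
})

test_that("shrinkage path: support size non-increasing in lambda1", {
  pair <- make_test_pair(13, n_G = 50, n_C = 50, p = 8,
                         delta = c(0, 0, 0, 0, 0, 0, 1, 0))
  st <- build_stacked_design(pair, "F1")
  m <- ncol(st$X)
  lmax <- lambda_max_weighted(st$X, st$y, rep(1, m))
  lams <- exp(seq(log(lmax), log(1e-3 * lmax), length.out = 20))
  nz <- vapply(lams, function(l) {
    sum(solve_weighted_enet(st$X, st$y, rep(1, m), rep(1, m), l, 0.1)$coef
        != 0)
  }, numeric(1))
  expect_true(all(diff(nz) >= 0)) # lams decreasing -> support grows
})
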