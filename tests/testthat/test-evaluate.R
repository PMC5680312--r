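test_that("mean_prediction_error identities", {
  fit <- structure(list(beta = c(1, 2), delta = c(0, 0), formulation = "F1",
                        flags = character(), feature_names = c("a", "b")),
                   class = "shared_fit")
  X <- matrix(rnorm(20), 10, 2)
  y <- drop(X %*% c(1, 2))
  expect_equal(mean_prediction_error(fit, X, y, "as_G"), 0)
  # null fit: error equals the (population-style) mean square of y
  fit0 <- fit; fit0$beta <- c(0, 0)
  expect_equal(mean_prediction_error(fit0, X, y, "as_G"), mean(y^2))
  expect_error(mean_prediction_error(fit, X[0, , drop = FALSE], numeric(0)),
               "empty")
  # direct arithmetic oracle
  set.seed(51)
  y2 <- rnorm(10)
  want <- sum((y2 - (X[, 1] + 2 * X[, 2]))^2) / 10
  expect_equal(mean_prediction_error(fit, X, y2, "as_G"), want,
               tolerance = 1e-12)
})

test_that("five_number_summary: worked cases and the sort-based oracle", {
  s <- five_number_summary(1:5)
  expect_equal(unlist(s, use.names = FALSE), c(1, 2, 3, 4, 5))
  s_const <- five_number_summary(rep(3.3, 7))
  expect_equal(unlist(s_const, use.names = FALSE), rep(3.3, 5))
  expect_error(five_number_summary(numeric(0)), "empty")

  set.seed(52)
  v <- rexp(200)
  s <- five_number_summary(v)
  expect_equal(unlist(s, use.names = FALSE), oracle_five_numbers(v),
               tolerance = 1e-12)
  expect_lte(s$min, s$q1); expect_lte(s$q1, s$median)
  expect_lte(s$median, s$q3); expect_lte(s$q3, s$max)
})

test_that("bdm_ovs: worked published row, symmetry, degenerate input", {
  shared <- c(0.392, 0.602, 0.726, 0.82, 1.12)   # Nutlin-3, shared model
  other <- c(0.747, 1.016, 1.144, 1.271, 1.644)  # CCLE-alone model
  b <- bdm_ovs(shared, other)
  expect_equal(b$dbm, 1.144 - 0.726)
  expect_equal(b$ovs, 1.271 - 0.602)
  expect_lte(abs(b$ratio - 0.624), 0.001 + 1e-12)
  expect_true(b$iqr_nonoverlap)

  same <- five_number_summary(c(1, 2, 3, 4, 5))
  b0 <- bdm_ovs(same, same)
  expect_equal(b0$ratio, 0)
  expect_false(b0$iqr_nonoverlap)

  # exact antisymmetry
  a <- c(0.1, 0.4, 0.6, 0.9, 1.4); c_ <- c(0.2, 0.5, 0.8, 1.1, 1.5)
  expect_equal(bdm_ovs(a, c_)$ratio_raw, -bdm_ovs(c_, a)$ratio_raw)
  expect_error(bdm_ovs(rep(1, 5), rep(1, 5)), "degenerate")
})

test_that("compare_methods: scenario training sizes follow the floor rule", {
  # n = 110: test floor(0.2*110) = 22; scenario 1 floor(0.7*88) = 61;
  # scenario 2 uses all 88
  pair <- make_test_pair(61, n_G = 110, n_C = 40, p = 6)
  opts <- fast_options(pilot_lambda = c(0.5, 0.1), n_lambda1 = 4L,
                       lambda2_values = 0.1, cv_folds = 4L)
  cmp1 <- compare_methods(pair, scenario = 1, n_splits = 1, seed = 5,
                          options = opts)
  expect_equal(cmp1$n_test, 22L)
  expect_equal(cmp1$n_train, 61L)
  cmp2 <- compare_methods(pair, scenario = 2, n_splits = 1, seed = 5,
                          options = opts)
  expect_equal(cmp2$n_train, 88L)
  expect_equal(colnames(cmp1$errors),
               c("shared_test", "shared_other", "individual_test",
                 "individual_other", "pooled"))
})

test_that("compare_methods: concordant vs discordant synthetic drugs", {
  opts <- fast_options(n_lambda1 = 6L, lambda2_values = c(0.01, 0.1),
                       cv_folds = 5L)
  # concordant (delta = 0): shared vs pooled shows no meaningful difference
  conc <- vapply(1:3, function(seed) {
    pair <- make_test_pair(seed + 70, n_G = 60, n_C = 60, p = 15,
                           beta = c(rep(1.5, 4), rep(0, 11)))
    cmp <- compare_methods(pair, n_splits = 8, seed = seed, options = opts)
    abs(cmp$bdm_ovs$pooled$ratio_raw)
  }, numeric(1))
  expect_lt(median(conc), 0.2)

  # discordant (large delta): the other-cohort-alone model is clearly worse
  disc <- vapply(1:3, function(seed) {
    pair <- make_test_pair(seed + 80, n_G = 60, n_C = 60, p = 15,
                           beta = c(rep(1.5, 4), rep(0, 11)),
                           delta = c(rep(-2.5, 4), rep(2, 2), rep(0, 9)))
    cmp <- compare_methods(pair, n_splits = 8, seed = seed, options = opts)
    cmp$bdm_ovs$individual_other$ratio_raw
  }, numeric(1))
  expect_gt(median(disc), 0.2)
})

test_that("summaries in a comparison re-derive from the stored errors", {
  pair <- make_test_pair(91, n_G = 50, n_C = 40, p = 5)
  opts <- fast_options(pilot_lambda = c(0.5, 0.1), n_lambda1 = 4L,
                       lambda2_values = 0.1, cv_folds = 4L)
  cmp <- compare_methods(pair, n_splits = 4, seed = 2, options = opts)
  for (m in colnames(cmp$errors))
    expect_equal(cmp$summaries[[m]], five_number_summary(cmp$errors[, m]))
})

test_that("stratified test draws respect tissue proportions", {
  set.seed(7)
  tissue <- factor(rep(c("lung", "breast", "skin"), times = c(50, 30, 20)))
  idx <- dsharenet:::draw_test_indices(100, 20, tissue)
  expect_equal(length(idx), 20L)
  tt <- table(tissue[idx])
  expect_equal(as.integer(tt[c("lung", "breast", "skin")]), c(10L, 6L, 4L))
})

test_that("published summaries table is complete and self-consistent", {
  tab <- published_error_summaries()
  expect_equal(nrow(tab), 60L) # 15 drugs x 2 directions x 2 models
  expect_true(all(tab$min <= tab$q1 & tab$q1 <= tab$median &
                    tab$median <= tab$q3 & tab$q3 <= tab$max))
  expect_equal(sort(unique(tab$model)), c("alone", "shared"))
})
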