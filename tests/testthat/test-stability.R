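# Construct a variable_list by hand (for rule/matrix logic tests).
mock_vlist <- function(beta_df, delta_df, n_runs = 200L,
                       formulation = "F1") {
  structure(list(beta = beta_df, delta = delta_df),
            class = "variable_list", n_runs = n_runs,
            formulation = formulation,
            feature_names = union(beta_df$feature, delta_df$feature))
}

vl_row <- function(feature, frequency, avg)
  data.frame(feature = feature, frequency = frequency,
             avg_coefficient = avg, stringsAsFactors = FALSE)

test_that("select_significant: the worked +/-2 s.d. example yields the empty set", {
  vl <- mock_vlist(
    vl_row(paste0("f", 1:5), c(0.9, 0.95, 0.85, 0.9, 0.99),
           c(5.0, 0.1, -0.1, 0.05, -0.05)),
    vl_row("d1", 0.5, 0.2))
  # m = 1.0, s ~ 2.24; 5.0 < m + 2s = 5.47, so nothing qualifies
  expect_equal(select_significant(vl), character(0))
  # but a genuinely extreme coefficient is picked up
  vl2 <- mock_vlist(
    vl_row(paste0("f", 1:6), rep(0.9, 6), c(8, 0.1, -0.1, 0.05, -0.05, 0)),
    vl_row("d1", 0.5, 0.2))
  expect_equal(select_significant(vl2), "f1")
})

test_that("select_significant: frequency gate and degenerate cases", {
  vl <- mock_vlist(
    vl_row(paste0("f", 1:6), c(0.7, rep(0.9, 5)),
           c(8, 0.1, -0.1, 0.05, -0.05, 0)),
    vl_row("d1", 0.5, 0.2))
  # extreme coefficient but frequency 0.7 < 0.8 -> excluded
  expect_equal(select_significant(vl), character(0))

  # all coefficients equal: s = 0 and the strict rule selects nothing
  vl_eq <- mock_vlist(vl_row(paste0("f", 1:4), rep(0.9, 4), rep(1.3, 4)),
                      vl_row("d1", 0.5, 0.2))
  expect_equal(select_significant(vl_eq), character(0))

  # fewer than two entries -> empty set with warning
  vl_1 <- mock_vlist(vl_row("f1", 0.9, 2), vl_row("d1", 0.5, 0.2))
  expect_warning(out <- select_significant(vl_1), "fewer than 2")
  expect_equal(out, character(0))
  expect_error(select_significant(vl_1, ledger = "nope"), "ledger")
})

test_that("select_significant is invariant to feature ordering", {
  set.seed(30)
  df <- vl_row(paste0("f", 1:20), runif(20, 0.5, 1), rnorm(20, 0, 1))
  df$avg_coefficient[3] <- 6
  vl_a <- mock_vlist(df, vl_row("d1", 0.5, 0.2))
  perm <- sample(20)
  vl_b <- mock_vlist(df[perm, ], vl_row("d1", 0.5, 0.2))
  expect_equal(sort(select_significant(vl_a)), sort(select_significant(vl_b)))
})

test_that("run_stability: counting, determinism, and ledger contract", {
  pair <- make_test_pair(41, n_G = 60, n_C = 60, p = 15,
                         beta = c(rep(2, 3), rep(0, 12)),
                         delta = c(rep(0, 14), 1.5))
  opts <- fast_options()
  vl <- run_stability(pair, n_runs = 8, seed = 17, options = opts)
  expect_named(vl, c("beta", "delta"))
  for (lg in names(vl)) {
    expect_true(all(vl[[lg]]$frequency > 0 & vl[[lg]]$frequency <= 1))
    expect_true(all(is.finite(vl[[lg]]$avg_coefficient)))
    # frequencies are multiples of 1/8 by construction
    expect_equal(vl[[lg]]$frequency * 8, round(vl[[lg]]$frequency * 8))
  }
  # strong planted features are always selected
  strong <- vl$beta[vl$beta$feature %in% c("f1", "f2", "f3"), ]
  expect_equal(strong$frequency, rep(1, 3))
  vl2 <- run_stability(pair, n_runs = 8, seed = 17, options = opts)
  expect_identical(vl, vl2)
})

test_that("pure-noise data produce no high-frequency feature", {
  hits <- vapply(1:3, function(seed) {
    set.seed(seed)
    n <- 40; p <- 20
    pair <- cohort_pair(matrix(rnorm(n * p), n, p), rnorm(n),
                        matrix(rnorm(n * p), n, p), rnorm(n))
    # the all-zero pilot warning is the expected behaviour on pure noise
    vl <- suppressWarnings(run_stability(pair, n_runs = 12, seed = seed,
                                         options = fast_options()))
    max(c(vl$beta$frequency, vl$delta$frequency, 0))
  }, numeric(1))
  expect_lt(median(hits), 0.8)
})

test_that("signature matrix: concordant drug has identical g and c rows", {
  # two strong markers of opposite sign among ten near-null entries: the
  # +/-2 s.d. rule needs the strong pair to be a small fraction of the list
  vl_conc <- mock_vlist(
    vl_row(c("m1", "m2", paste0("n", 1:10)),
           c(1, 1, rep(0.9, 10)),
           c(2.5, -2.5, 0.01, -0.02, 0.03, 0.01, -0.01, 0.02,
             -0.03, 0.02, 0.01, -0.01)),
    vl_row(c("n1", "n2"), c(0.3, 0.2), c(0.05, -0.04)))
  sig <- build_signature_matrix(list(drugX = vl_conc))
  expect_true(all(c("m1", "m2") %in% colnames(sig$effects)))
  expect_equal(sig$effects["drugX_g", c("m1", "m2")],
               sig$effects["drugX_c", c("m1", "m2")])
  expect_true(all(sig$mask["drugX_g", c("m1", "m2")]))

  # cell values equal the underlying coefficient sums exactly
  vl_disc <- mock_vlist(
    vl_row(c("m1", "n1", "n2", "n3", "n4", "n5", "n6", "n7"),
           c(1, rep(0.9, 7)),
           c(2.5, 0.01, -0.02, 0.03, 0.01, -0.01, 0.02, 0)),
    vl_row(c("m1", "n1", "n2", "n3", "n4", "n5", "n6", "n7"),
           c(1, rep(0.6, 7)),
           c(-2.4, 0.01, 0.02, -0.01, 0.03, -0.02, 0.01, 0)))
  sig2 <- build_signature_matrix(list(drugY = vl_disc))
  expect_equal(unname(sig2$effects["drugY_g", "m1"]), 2.5, tolerance = 1e-12)
  expect_equal(unname(sig2$effects["drugY_c", "m1"]), 2.5 - 2.4,
               tolerance = 1e-12)
})

test_that("planted discrepancy shows the washed-away g/c pattern", {
  # |delta_j| >> |beta_j|: strong in one cohort only
  pair <- make_test_pair(53, n_G = 80, n_C = 80, p = 20,
                         beta = c(rep(1.5, 2), 0.3, rep(0, 17)),
                         delta = c(0, 0, 2.2, rep(0, 17)),
                         noise_sd = 0.7)
  vl <- run_stability(pair, n_runs = 10, seed = 3, options = fast_options())
  b3 <- vl$beta$avg_coefficient[vl$beta$feature == "f3"]
  d3 <- vl$delta$avg_coefficient[vl$delta$feature == "f3"]
  g_eff <- if (length(b3)) b3 else 0
  c_eff <- g_eff + if (length(d3)) d3 else 0
  expect_gt(abs(c_eff - g_eff), 1)   # the two cohorts' effects disagree
  expect_gt(abs(c_eff), abs(g_eff))  # strong only on the discrepant side
})

test_that("empty marker union warns and returns empty matrices", {
  vl <- mock_vlist(vl_row(c("a", "b"), c(0.5, 0.4), c(0.1, -0.1)),
                   vl_row("a", 0.2, 0.05))
  expect_warning(sig <- build_signature_matrix(list(d1 = vl)), "no marker")
  expect_equal(ncol(sig$effects), 0L)
})
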