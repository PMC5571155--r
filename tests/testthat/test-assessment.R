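test_that("RMSE and MAE match hand computations", {
  expect_equal(rmse_mae(c(1, 2), c(1, 2)), tibble::tibble(rmse = 0, mae = 0))
  r <- rmse_mae(c(0, 0), c(1, -1))
  expect_equal(r$rmse, 1); expect_equal(r$mae, 1)
  r2 <- rmse_mae(c(0, 0), c(0, 3))
  expect_equal(r2$rmse, sqrt(4.5)); expect_equal(r2$mae, 1.5)
  expect_error(rmse_mae(1:3, 1:2), "aligned")
})

test_that("ARIL, coverage and ILTC follow their definitions", {
  r <- aril_coverage_iltc(rep(0.9, 5), rep(1.1, 5), rep(1, 5))
  expect_equal(r$aril, 0.2)
  expect_equal(r$coverage, 1)
  expect_equal(r$iltc, 0.2)  # ILTC equals ARIL at full coverage

  r0 <- aril_coverage_iltc(rep(2, 4), rep(3, 4), rep(1, 4))
  expect_equal(r0$coverage, 0)
  expect_true(is.infinite(r0$iltc))

  rz <- aril_coverage_iltc(c(1, 2), c(1, 2), c(1, 2))  # zero width, exact
  expect_equal(rz$aril, 0); expect_equal(rz$coverage, 1); expect_equal(rz$iltc, 0)

  expect_error(aril_coverage_iltc(0.5, 1.5, 0), "positive")
  # boundary points count as covered (closed interval)
  rb <- aril_coverage_iltc(1, 2, 2)
  expect_equal(rb$coverage, 1)
})

test_that("collinearity matrix flags duplicated and anti-correlated pairs only", {
  set.seed(21)
  n <- 10000
  s <- tibble::tibble(a = runif(n), b = runif(n))
  r <- lcc_matrix(s)
  expect_lt(abs(r$lcc["a", "b"]), 0.05)
  expect_equal(nrow(r$flagged), 0L)
  expect_equal(diag(r$lcc), c(a = 1, b = 1))
  expect_equal(r$lcc, t(r$lcc))

  s$dup <- s$a
  r2 <- lcc_matrix(s)
  expect_equal(r2$lcc["a", "dup"], 1)
  expect_true(any(r2$flagged$lcc == 1))

  # invariant to affine rescaling
  s3 <- tibble::tibble(a = 5 * s$a + 2, b = -3 * s$b)
  r3 <- lcc_matrix(s3)
  expect_equal(abs(r3$lcc["a", "b"]), abs(r$lcc["a", "b"]), tolerance = 1e-12)

  expect_error(lcc_matrix(s[, 1, drop = FALSE]), "at least 2")
  expect_error(lcc_matrix(s[1:50, ]), "100")
  s$z <- 1
  expect_error(lcc_matrix(s), "zero-variance")
})

test_that("relative-CI identifiability applies the 50% rule on the worse side", {
  expect_true(relative_ci_check(c(1.0, 0.6, 1.4))$identifiable)   # 40%
  expect_false(relative_ci_check(c(1.0, 0.4, 1.2))$identifiable)  # 60% low side
  expect_error(relative_ci_check(c(0, -1, 1)), "positive")
})

test_that("standardized regression coefficients rank an additive linear model", {
  set.seed(31)
  n <- 4000
  th <- tibble::tibble(t1 = runif(n), t2 = runif(n))
  y <- 2 * th$t1 + rnorm(n, 0, 0.1)
  g <- src_gsa(th, y)
  expect_equal(unname(g$src$src[g$src$param == "t1"]), stats::cor(th$t1, y),
               tolerance = 0.02)
  expect_lt(abs(g$src$src[g$src$param == "t2"]), 0.05)
  expect_equal(sum(g$src$src^2), g$r_squared, tolerance = 0.02)
  expect_gt(g$r_squared, 0.9)

  th$t3 <- th$t1
  expect_error(src_gsa(th, y), "collinear")
  expect_warning(src_gsa(th[, 1:2], rnorm(n)), "unreliable")
})

test_that("Monte Carlo bands respond to posterior width and degenerate cleanly", {
  net <- two_branch_network()
  times <- c(0.2, 0.5, 1, 2)
  pt <- tibble::as_tibble(as.list(two_branch_truth))[rep(1, 250), ]
  b0 <- mc_prediction_bands(net, pt, times, phase = "abiotic", seed = 2)
  expect_equal(b0$lo, b0$hi, tolerance = 1e-12)
  ref <- simulate_pathway(net, two_branch_truth, times, phase = "abiotic")
  expect_equal(b0$median[b0$compound == "X"],
               ref$concentration_ugL[ref$compound == "X"], tolerance = 1e-9)

  set.seed(5)
  jitter1 <- purrr::map_dfc(as.list(two_branch_truth),
                            ~ .x * exp(rnorm(400, 0, 0.05)))
  jitter2 <- purrr::map_dfc(as.list(two_branch_truth),
                            ~ .x * exp(rnorm(400, 0, 0.10)))
  b1 <- mc_prediction_bands(net, jitter1, times, phase = "abiotic", seed = 2)
  b2 <- mc_prediction_bands(net, jitter2, times, phase = "abiotic", seed = 2)
  w1 <- b1$hi - b1$lo; w2 <- b2$hi - b2$lo
  expect_gte(mean(w2 >= w1 - 1e-9), 0.95)

  expect_error(mc_prediction_bands(net, pt, times, n_draws = 10), "200")
})

test_that("an assessment report aggregates metrics per compound and phase", {
  m1 <- test_m1()
  fx <- test_fixture()
  rep_ <- assessment_report(m1, fx$dataset, n_draws = 200, seed = 3)
  expect_setequal(unique(rep_$metrics$phase), c("abiotic", "biotic"))
  expect_equal(nrow(rep_$metrics), 12L)  # 6 compounds x 2 phases
  expect_true(all(rep_$metrics$rmse >= 0))
  expect_true(all(rep_$metrics$coverage >= 0 & rep_$metrics$coverage <= 1))
  expect_true(all(rep_$metrics$iltc >= rep_$metrics$aril - 1e-12))
})
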