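test_that("uniform and point priors validate their arguments", {
  sp <- uniform_prior("k_abio_HER", 0, 100)
  expect_identical(sp$role, "primary")
  expect_equal(spec_logd_exposed(sp, 50), -log(100))
  expect_equal(spec_logd_exposed(sp, 101), -Inf)
  expect_error(uniform_prior("k", 1, 1), "lo < hi")
  expect_error(uniform_prior("k", -1, 1), "non-negative")
  expect_error(uniform_prior("k", 0, 50, member_ids = "only_one"), ">= 2")

  comb <- uniform_prior("k_bio_COE", 0, 50,
                        member_ids = c("k_bio_COE_1", "k_bio_COE_2"))
  expect_identical(comb$role, "combinatorial")
  expect_length(comb$member_ids, 2L)

  pt <- point_prior("k", 0.7)
  expect_identical(pt$prior$kind, "point")
})

test_that("distribution fitting selects the generating family by BIC", {
  set.seed(42)
  x_norm <- rnorm(10000, 5, 1)
  fit_n <- fit_distribution(x_norm)
  expect_identical(fit_n$family, "normal")

  set.seed(43)
  x_ln <- rlnorm(10000, 0, 0.5)
  fit_l <- fit_distribution(x_ln)
  sc <- fit_l$scores
  expect_lt(sc$bic[sc$family == "lognormal"], sc$bic[sc$family == "normal"])

  expect_error(fit_distribution(rep(1, 200)), "degenerate")
  expect_error(fit_distribution(rnorm(50)), "at least 100")
})

test_that("location-scale fits are scale-equivariant", {
  set.seed(7)
  x <- rnorm(2000, 3, 0.5)
  f1 <- fit_distribution(x, families = "normal")
  f2 <- fit_distribution(10 * x, families = "normal")
  expect_equal(unname(f2$params["mean"]), 10 * unname(f1$params["mean"]),
               tolerance = 1e-4)
  expect_equal(unname(f2$params["sd"]), 10 * unname(f1$params["sd"]),
               tolerance = 1e-4)
})

test_that("posterior summaries match the brute-force percentile oracle", {
  s <- as.numeric(1:1000)
  ps <- summarize_posterior(s, "k", fit = FALSE)
  expect_equal(ps$median, 500.5)
  expect_equal(ps$cri95, c(25.975, 975.025))
  expect_equal(ps$cri95, c(oracle_percentile(s, 0.025), oracle_percentile(s, 0.975)))

  set.seed(1)
  x <- rnorm(5001)
  ps2 <- summarize_posterior(x, "k", fit = FALSE)
  expect_equal(ps2$cri95,
               c(oracle_percentile(x, 0.025), oracle_percentile(x, 0.975)))
  expect_equal(ps2$median, mean(x), tolerance = 0.05)  # symmetric samples

  expect_error(summarize_posterior(numeric(0)), "empty")
  expect_error(summarize_posterior(rep(2, 50)), "degenerate")
})

test_that("propagation truncates the fitted distribution to the credibility interval", {
  set.seed(11)
  ps <- summarize_posterior(rnorm(5000, 0.5, 0.15), "k")
  expect_identical(ps$fitted$family, "normal")
  sub <- propagate_posterior(ps)
  expect_identical(sub$role, "subsidiary")
  expect_identical(sub$prior$kind, "trunc")
  # support never widens beyond the CrI
  expect_equal(c(sub$prior$lo, sub$prior$hi), ps$cri95)
  expect_equal(spec_logd_exposed(sub, ps$cri95[2] + 0.01), -Inf)
  # truncated density integrates to one on the interval
  z <- stats::integrate(function(x) exp(spec_logd_exposed(sub, x)),
                        sub$prior$lo, sub$prior$hi)$value
  expect_equal(z, 1, tolerance = 1e-4)
  # and inverse-CDF sampling stays inside the support
  set.seed(2)
  draws <- spec_sample_exposed(sub, 500)
  expect_true(all(draws >= sub$prior$lo & draws <= sub$prior$hi))

  pt <- propagate_posterior(ps, point = TRUE)
  expect_identical(pt$prior$kind, "point")
  expect_equal(pt$prior$value, ps$median)
})

test_that("combinatorial splits bound members by the total's upper CrI", {
  set.seed(3)
  ps <- summarize_posterior(runif(2000, 1.4, 2.0), "k_abio_COE", fit = FALSE)
  sc <- split_combinatorial(ps, c("k_abio_COE_1", "k_abio_COE_2"))
  expect_length(sc$specs, 2L)
  for (sp in sc$specs) {
    expect_equal(sp$prior$lo, 0)
    expect_equal(sp$prior$hi, ps$cri95[2])
  }
  expect_equal(sc$constraint$lo, ps$cri95[1])
  expect_equal(sc$constraint$hi, ps$cri95[2])
})
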