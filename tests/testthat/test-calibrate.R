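test_that("sequential calibration recovers a two-branch system", {
  m1 <- test_branch_m1()
  tab <- tidy(m1)
  est <- tab[tab$param_id %in% names(two_branch_truth), ]
  inside <- two_branch_truth[est$param_id] >= est$cri_lo &
    two_branch_truth[est$param_id] <= est$cri_hi
  expect_gte(mean(inside), 0.75)
  # every parameter resolved
  expect_setequal(tab$param_id,
                  c(names(two_branch_truth), "k_abio_X"))
})

test_that("soft sum-constraint keeps branch totals inside the combinatorial CrI", {
  m1 <- test_branch_m1()
  total <- m1$store[["k_abio_X"]]
  s <- m1$levels[["2(A)"]]$result$samples
  sums <- s$k_abio_X_1 + s$k_abio_X_2
  expect_true(all(sums >= total$cri95[1] - 1e-9 & sums <= total$cri95[2] + 1e-9))
})

test_that("fixed-total reparameterization makes branch pairs perfectly anti-correlated", {
  m3 <- test_branch_m3()
  s <- m3$levels[["2(A)"]]$result$samples
  expect_equal(stats::cor(s$k_abio_X_1, s$k_abio_X_2), -1, tolerance = 1e-12)
  total <- m3$store[["k_abio_X"]]
  expect_equal(s$k_abio_X_1 + s$k_abio_X_2, rep(total$median, nrow(s)),
               tolerance = 1e-12)
})

test_that("a member sampled at the frozen total forces its partner to zero", {
  # direct check of the reparameterization arithmetic via the theta map
  net <- two_branch_network()
  specs <- list(uniform_prior("k_abio_X_1", 0, 1.8),
                point_prior("k_abio_P1", 0.4), point_prior("k_abio_P2", 0.15))
  tm <- pathkin:::make_theta_map(net, specs, list(),
                                 reparam = list(list(sampled = "k_abio_X_1",
                                                     partner = "k_abio_X_2",
                                                     total = 1.8)))
  full <- tm(c(1.8, 0.4, 0.15))
  expect_equal(unname(full["k_abio_X_2"]), 0)
})

test_that("run_level demands its subsidiaries and warns on empty levels", {
  fx <- test_fixture()
  plan <- plan_levels(fx$network)
  cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 600))
  expect_error(
    run_level(plan[plan$label == "2(A)", ], fx$network, fx$dataset$data,
              store = list(), cfg, seed = 1),
    "missing.*k_abio"
  )
  empty <- plan[1, ]
  empty$primary <- list(character(0))
  empty$combinatorial <- list(list())
  expect_warning(
    run_level(empty, fx$network, fx$dataset$data, store = list(), cfg, seed = 1),
    "no parameters"
  )
})

test_that("a one-parameter network degenerates to a single-level fit for all schemes", {
  net <- build_network(data.frame(id = "A", c0_abiotic = 10, c0_biotic = 10),
                       data.frame(source = "A", product = "TP",
                                  phase = "abiotic", param_id = "k"))
  ds <- generate_dataset(net, c(k = 0.9), times = c(0, 0.3, 0.7, 1.2, 2, 3),
                         seed = 3, phases = "abiotic")
  cfg <- pk_calibration_config(method2_widen = 1,
                               sampler = pk_sampler_config(max_evals = 1500))
  m1 <- calibrate_method1(net, ds, cfg, seed = 5)
  m2 <- calibrate_method2(net, ds, cfg, seed = 5)
  m3 <- calibrate_method3(net, ds, cfg, seed = 5)
  expect_equal(length(m1$levels), 1L)
  expect_equal(length(m2$levels), 1L)
  # identical estimation problem: same prior, same data
  meds <- c(tidy(m1)$median, tidy(m2)$median, tidy(m3)$median)
  expect_lt(max(meds) - min(meds), 0.1 * 0.9)
  for (m in list(m1, m2, m3)) {
    expect_true(0.9 >= tidy(m)$cri_lo[1] && 0.9 <= tidy(m)$cri_hi[1])
  }
})

test_that("zero-width upstream posteriors freeze the lumped biotic stage", {
  net <- build_network(
    data.frame(id = c("A", "B"), c0_abiotic = c(10, 0), c0_biotic = c(10, 0)),
    data.frame(source = c("A", "A", "B"), product = c("B", "B2", "TP"),
               phase = c("abiotic", "biotic", "biotic"),
               param_id = c("k_abio_A", "k_bio_A", "k_bio_B"))
  )
  truth <- c(k_abio_A = 0.8, k_bio_A = 1.2, k_bio_B = 0.5)
  ds <- generate_dataset(net, truth, times = c(0, 0.3, 0.7, 1.2, 2, 3), seed = 4)
  cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 3000))
  m2 <- calibrate_method2(net, ds, cfg, seed = 6)
  # inject a zero-width abiotic posterior and re-run the biotic stage
  ps <- m2$store[["k_abio_A"]]
  ps$cri95 <- c(ps$median, ps$median)
  sub <- propagate_posterior(ps)
  expect_identical(sub$prior$kind, "point")
})

test_that("broom-style accessors and plots work on calibration objects", {
  m1 <- test_branch_m1()
  tab <- tidy(m1)
  expect_true(all(c("param_id", "median", "cri_lo", "cri_hi") %in% names(tab)))
  expect_true(all(tab$cri_lo <= tab$median & tab$median <= tab$cri_hi))
  g <- glance(m1)
  expect_equal(nrow(g), 1L)
  expect_gt(g$n_evals, 0)
  p <- autoplot(m1)
  expect_s3_class(p, "ggplot")
})

test_that("parameter draws cover every edge parameter and respect frozen values", {
  m1 <- test_m1()
  dr <- parameter_draws(m1, n = 250, seed = 9)
  expect_equal(nrow(dr), 250L)
  expect_setequal(names(dr), m1$network$edges$param_id)
  expect_true(all(dr$k_abio_MORG == 0))
})
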