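test_that("noise-free generation reproduces the trajectory exactly", {
  net <- two_branch_network()
  ds <- generate_dataset(net, two_branch_truth, times = c(0, 0.5, 1, 2),
                         noise = noise_model(sigma = 0, floor = 0),
                         seed = 1, phases = "abiotic")
  expect_equal(ds$data$concentration_ugL, ds$truth$clean$concentration_ugL)
})

test_that("generation is bit-identical under the same seed", {
  a <- heroin_codeine_fixture(seed = 17)
  b <- heroin_codeine_fixture(seed = 17)
  expect_identical(a$dataset$data, b$dataset$data)
  c <- heroin_codeine_fixture(seed = 18)
  expect_false(identical(a$dataset$data, c$dataset$data))
})

test_that("proportional noise has the declared coefficient of variation", {
  net <- build_network(data.frame(id = "A", c0_abiotic = 100),
                       data.frame(source = "A", product = "TP",
                                  phase = "abiotic", param_id = "k"))
  ds <- generate_dataset(net, c(k = 1e-6), times = seq(0.001, 1, length.out = 1000),
                         noise = noise_model(sigma = 0.1, floor = 0),
                         seed = 12, phases = "abiotic")
  v <- ds$data$concentration_ugL[ds$data$compound == "A"]
  expect_equal(stats::sd(v) / mean(v), 0.1, tolerance = 0.1)
})

test_that("excessive flooring warns", {
  net <- build_network(data.frame(id = "A", c0_abiotic = 0.001),
                       data.frame(source = "A", product = "TP",
                                  phase = "abiotic", param_id = "k"))
  expect_warning(
    generate_dataset(net, c(k = 1), times = c(0.1, 1), phases = "abiotic",
                     noise = noise_model(sigma = 0, floor = 0.01), seed = 1),
    "detection floor"
  )
})

test_that("the fixture reproduces the reference pathway topology", {
  fx <- heroin_codeine_fixture(seed = 1)
  net <- fx$network
  ep <- enumerate_rate_parameters(net)
  expect_length(ep$abiotic, 7L)
  expect_length(ep$biotic, 9L)
  expect_equal(max(plan_levels(net)$level), 4L)

  edge_key <- paste(net$edges$source, net$edges$product, net$edges$phase)
  expect_true(all(c("HER 6MAM abiotic", "6MAM MOR abiotic", "MORG MOR abiotic",
                    "COE MOR abiotic", "COE NCOE abiotic",
                    "HER 6MAM biotic", "HER TP_B biotic",
                    "MORG MOR biotic", "MORG TP_B biotic",
                    "COE MOR biotic", "COE NCOE biotic") %in% edge_key))
  expect_equal(net$edges$fixed[net$edges$param_id == "k_abio_MORG"], 0)
  # the two discovery branches distinguish the full from the human network
  human <- heroin_codeine_network(branches = FALSE)
  expect_setequal(setdiff(net$edges$param_id, human$edges$param_id),
                  c("k_bio_HER_2", "k_bio_MORG_2"))

  # unit stoichiometry conserves total mass along the fixture trajectories
  traj <- simulate_pathway(net, fx$true_params, times = c(0.5, 1.5, 3),
                           phase = "combined")
  for (t in unique(traj$time_d)) {
    expect_equal(sum(traj$concentration_ugL[traj$time_d == t]),
                 sum(net$compounds$c0_biotic), tolerance = 1e-6)
  }
})
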