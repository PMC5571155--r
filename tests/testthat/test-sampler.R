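test_that("range-normalized SSE matches brute-force evaluation", {
  expect_equal(normalized_sse(c(0, 1, 2), c(0, 1, 2)), 0)
  expect_equal(normalized_sse(c(0, 1, 2), c(0.5, 1.5, 2.5)), 0.1875)
  # brute-force loop oracle over two series
  m <- c(0, 1, 2, 10, 30)
  p <- c(0.2, 1.1, 1.8, 12, 28)
  ser <- c(1, 1, 1, 2, 2)
  brute <- 0
  for (s in unique(ser)) {
    i <- ser == s
    brute <- brute + sum(((m[i] - p[i]) / (max(m[i]) - min(m[i])))^2)
  }
  expect_equal(normalized_sse(m, p, ser), brute)
  expect_error(normalized_sse(c(1, 1, 1), c(1, 2, 3)), "constant measured")
  expect_error(normalized_sse(1:3, 1:2), "aligned")
})

test_that("normalized SSE is invariant to affine rescaling of a series' units", {
  m <- c(2, 5, 9, 4)
  p <- c(2.5, 4.5, 8, 5)
  expect_equal(normalized_sse(100 * m + 7, 100 * p + 7), normalized_sse(m, p))
})

test_that("Theil inequality coefficient matches hand computation and stays in [0,1]", {
  expect_equal(tic(c(3, 1, 4), c(3, 1, 4)), 0)
  expect_equal(tic(c(1, 1, 1, 1), c(0, 0, 0, 0)), 1)
  # independent brute-force evaluation of the formula for (2,4) vs (3,3)
  brute <- sqrt(mean(c(-1, 1)^2)) / (sqrt(mean(c(2, 4)^2)) + sqrt(mean(c(3, 3)^2)))
  expect_equal(tic(c(2, 4), c(3, 3)), brute)
  expect_equal(brute, 0.1622777, tolerance = 1e-6)
  expect_error(tic(c(0, 0), c(0, 0)), "zero")
  set.seed(9)
  for (i in 1:20) {
    a <- rnorm(10); b <- rnorm(10)
    v <- tic(a, b)
    expect_gte(v, 0); expect_lte(v, 1)
  }
})

test_that("the DE-MC sampler recovers a known 2-d Gaussian target", {
  mu <- c(1, -2); sig <- c(0.5, 2)
  lp <- function(th) -0.5 * sum((th - mu)^2 / sig^2)
  mk <- function(id) {
    s <- uniform_prior(id, 0, 1)
    s$prior <- list(kind = "uniform", lo = -15, hi = 15)
    s
  }
  ch <- demc_sample(lp, list(mk("a"), mk("b")),
                    pk_sampler_config(max_evals = 12000, seed = 42))
  expect_lt(max(ch$rhat), 1.05)
  for (j in 1:2) {
    x <- ch$samples[[c("a", "b")[j]]]
    # MC standard error via batch means over each chain
    bm <- tapply(x, ch$samples$.chain, function(v) {
      nb <- length(v) %/% 50
      colMeans(matrix(v[seq_len(nb * 50)], nrow = 50))
    })
    batch_means <- unlist(bm)
    mcse <- stats::sd(batch_means) / sqrt(length(batch_means))
    expect_lt(abs(mean(x) - mu[j]), 3 * mcse + 0.02)
    expect_equal(stats::sd(x), sig[j], tolerance = 0.15)
  }
})

test_that("with a flat likelihood the sampler reproduces the uniform prior", {
  sp <- uniform_prior("u", 2, 5)
  lp <- function(th) if (th >= 2 && th <= 5) 0 else -Inf
  ch <- demc_sample(lp, list(sp), pk_sampler_config(max_evals = 10000, seed = 7))
  x <- ch$samples$u
  thin <- x[seq(1, length(x), by = 20)]
  ks <- suppressWarnings(stats::ks.test(thin, "punif", 2, 5))
  expect_gt(ks$p.value, 0.01)
  expect_gte(min(x), 2); expect_lte(max(x), 5)
})

test_that("a 1-d decay-rate fit on noise-free data pins the true constant", {
  net <- build_network(data.frame(id = "A", c0_abiotic = 10),
                       data.frame(source = "A", product = "TP",
                                  phase = "abiotic", param_id = "k"))
  k_true <- 0.8
  times <- c(0.25, 0.5, 1, 2, 3)
  traj <- simulate_pathway(net, c(k = k_true), times, phase = "abiotic")
  meas <- traj$concentration_ugL[traj$compound == "A"]
  lp <- function(th) {
    pred <- 10 * exp(-th * times)
    sse <- sum(((meas - pred) / diff(range(meas)))^2)
    -(length(meas) / 2) * log(max(sse, 1e-300) / length(meas))
  }
  ch <- demc_sample(lp, list(uniform_prior("k", 0, 10)),
                    pk_sampler_config(max_evals = 5000, seed = 3))
  expect_lt(abs(stats::median(ch$samples$k) - k_true) / k_true, 0.01)
})

test_that("point-mass parameters stay constant across all draws", {
  lp <- function(th) -0.5 * th[1]^2
  mk <- uniform_prior("a", 0, 1)
  mk$prior <- list(kind = "uniform", lo = -5, hi = 5)
  ch <- demc_sample(lp, list(mk, point_prior("frozen", 0.33)),
                    pk_sampler_config(max_evals = 1000, seed = 1))
  expect_true(all(ch$samples$frozen == 0.33))
})

test_that("sampler configuration invariants are enforced", {
  lp <- function(th) 0
  expect_error(demc_sample(lp, list(uniform_prior("a", 0, 1)),
                           pk_sampler_config(n_chains = 2, max_evals = 1000)),
               "3 chains")
  expect_error(demc_sample(lp, purrr::map(paste0("p", 1:3), uniform_prior, lo = 0, hi = 1),
                           pk_sampler_config(max_evals = 200)),
               "100 per free parameter")
})

test_that("TIC filtering keeps good samples and rejects hopeless thresholds", {
  ds <- two_branch_dataset()
  net <- two_branch_network()
  good <- tibble::as_tibble(as.list(two_branch_truth))[rep(1, 5), ]
  res <- filter_by_tic(good, net, ds$data, threshold = 1)
  expect_equal(nrow(res$samples), 5L)
  expect_equal(res$rejected_fraction, 0)
  expect_error(filter_by_tic(good, net, ds$data, threshold = 1e-6),
               "re-evaluate the model structure")
})
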