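# Independent oracles and shared fixtures for the test suite.

# Matrix-exponential reference simulator, written independently of the
# package internals: builds the rate matrix by looping over the edge table
# and evaluates C(t) = expm(A t) C0 with Matrix::expm.
oracle_expm_simulate <- function(net, params, times, phase = "combined") {
  ids <- net$compounds$id
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  ed <- net$edges
  if (phase != "combined") ed <- ed[ed$phase == phase, , drop = FALSE]
  for (j in seq_len(nrow(ed))) {
    k <- if (!is.na(ed$fixed[j])) ed$fixed[j] else unname(params[[ed$param_id[j]]])
    mult <- if (ed$phase[j] == "biotic") net$tss else 1
    A[ed$product[j], ed$source[j]] <- A[ed$product[j], ed$source[j]] +
      ed$stoich[j] * mult * k
    A[ed$source[j], ed$source[j]] <- A[ed$source[j], ed$source[j]] - mult * k
  }
  c0 <- if (phase == "abiotic") net$compounds$c0_abiotic else net$compounds$c0_biotic
  sapply(times, function(t) as.vector(Matrix::expm(A * t) %*% c0)) |>
    matrix(nrow = length(ids), dimnames = list(ids, NULL))
}

# Two-compartment Bateman closed form for A -> B -> sink, first order.
oracle_bateman <- function(kA, kB, c0A, t) {
  cA <- c0A * exp(-kA * t)
  cB <- if (abs(kA - kB) < 1e-12) {
    c0A * kA * t * exp(-kA * t)
  } else {
    c0A * kA / (kB - kA) * (exp(-kA * t) - exp(-kB * t))
  }
  list(A = cA, B = cB)
}

# Brute-force type-7 percentile (linear interpolation between order stats).
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h)
  s[lo] + (h - lo) * (s[pmin(lo + 1, length(s))] - s[lo])
}

# Random acyclic first-order network over n compounds: every edge points
# from a lower to a higher topological index (or to a sink).
random_acyclic_network <- function(seed, n = 4L) {
  set.seed(seed)
  ids <- paste0("C", seq_len(n))
  edges <- list()
  for (i in seq_len(n)) {
    n_out <- sample(0:2, 1)
    targets <- c(if (i < n) ids[(i + 1):n], "SINK")
    for (tg in utils::head(sample(targets), n_out)) {
      ph <- sample(c("abiotic", "biotic"), 1)
      edges[[length(edges) + 1L]] <- data.frame(
        source = ids[i], product = tg, phase = ph,
        param_id = sprintf("k_%s_%s_%s", substr(ph, 1, 4), ids[i], tg),
        stoich = 1, fixed = NA_real_
      )
    }
  }
  if (!length(edges)) {
    edges[[1]] <- data.frame(source = ids[1], product = "SINK", phase = "abiotic",
                             param_id = "k_abio_C1_SINK", stoich = 1, fixed = NA_real_)
  }
  edges <- do.call(rbind, edges)
  edges <- edges[!duplicated(edges$param_id), ]
  net <- build_network(
    data.frame(id = ids, observed = TRUE,
               c0_abiotic = runif(n, 1, 10), c0_biotic = runif(n, 1, 10)),
    edges, tss = 0.4
  )
  params <- stats::setNames(runif(nrow(edges), 0.05, 2), edges$param_id)
  list(net = net, params = params)
}

# Two-branch test system: X -> P1 / X -> P2 (abiotic), products decay.
two_branch_network <- function() {
  build_network(
    data.frame(id = c("X", "P1", "P2"), c0_abiotic = c(10, 0, 0),
               c0_biotic = c(10, 0, 0)),
    data.frame(source = c("X", "X", "P1", "P2"),
               product = c("P1", "P2", "TP", "TP"),
               phase = "abiotic",
               param_id = c("k_abio_X_1", "k_abio_X_2", "k_abio_P1", "k_abio_P2")),
    tss = 0.4
  )
}

two_branch_truth <- c(k_abio_X_1 = 1.2, k_abio_X_2 = 0.6,
                      k_abio_P1 = 0.4, k_abio_P2 = 0.15)

two_branch_dataset <- function(seed = 7) {
  generate_dataset(two_branch_network(), two_branch_truth,
                   times = c(0, 0.1, 0.25, 0.5, 0.75, 1, 1.5, 2, 3),
                   seed = seed, phases = "abiotic")
}

# internal prior helpers, exposed for direct testing
spec_logd_exposed <- function(...) pathkin:::spec_logd(...)
spec_sample_exposed <- function(...) pathkin:::spec_sample(...)

# ---------------------------------------------------------------------------
# Memoized expensive calibrations shared across test files. Budgets are
# reduced relative to full-scale runs; the study conditions (fixture,
# noise, seeds) stay fixed.

.pk_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .pk_test_cache)) {
    assign(key, force(expr), envir = .pk_test_cache)
  }
  get(key, envir = .pk_test_cache)
}

test_fixture <- function() cached("fixture", heroin_codeine_fixture(seed = 101))

test_m1 <- function() cached("m1", {
  fx <- test_fixture()
  cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 5000))
  calibrate_method1(fx$network, fx$dataset, cfg, seed = 11)
})

test_m2 <- function() cached("m2", {
  fx <- test_fixture()
  cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 30000))
  calibrate_method2(fx$network, fx$dataset, cfg, seed = 11)
})

test_branch_m1 <- function() cached("branch_m1", {
  cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 4000))
  calibrate_method1(two_branch_network(), two_branch_dataset(), cfg, seed = 11)
})

test_branch_m3 <- function() cached("branch_m3", {
  cfg <- pk_calibration_config(sampler = pk_sampler_config(max_evals = 4000))
  calibrate_method3(two_branch_network(), two_branch_dataset(), cfg, seed = 11)
})

test_misspec <- function() cached("misspec", {
  fx <- heroin_codeine_fixture(seed = 5)
  net_human <- heroin_codeine_network(branches = FALSE)
  dd <- fx$dataset$data[fx$dataset$data$phase == "biotic", ]
  fit <- fit_min_sse(net_human, fx$dataset$data, phase = "biotic", seed = 2)
  diag <- residual_diagnostics(net_human, fit$trajectory, dd, fit$params,
                               phase = "combined")
  list(fx = fx, net_human = net_human, dd = dd, fit = fit, diag = diag)
})
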