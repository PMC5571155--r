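#' Range-normalized sum of squared errors
#'
#' The calibration objective: each measurement series is normalized by its
#' measured range, so series with different concentration scales contribute
#' comparably (equal weights):
#' `SSE = sum_i sum_j ((yhat_ij - y_ij) / (yhat_i,max - yhat_i,min))^2`,
#' with `yhat` the measured data and `y` the model prediction.
#'
#' @param measured,predicted aligned numeric vectors.
#' @param series optional grouping vector marking which measurement series
#'   each point belongs to (default: one single series).
#' @return non-negative scalar; 0 iff the fit is perfect.
#' @export
normalized_sse <- function(measured, predicted, series = NULL) {
  if (length(measured) != length(predicted) || length(measured) == 0L) {
    stop("`measured` and `predicted` must be non-empty and aligned", call. = FALSE)
  }
  if (is.null(series)) series <- rep(1L, length(measured))
  groups <- split(seq_along(measured), series)
  total <- 0
  for (idx in groups) {
    rng <- max(measured[idx]) - min(measured[idx])
    if (rng <= 0) stop("constant measured series: range normalization undefined", call. = FALSE)
    total <- total + sum(((measured[idx] - predicted[idx]) / rng)^2)
  }
  total
}

#' Theil inequality coefficient
#'
#' A bounded goodness-of-fit statistic,
#' `TIC = rmse(y, yhat) / (rms(yhat) + rms(y))`, equal to 0 for a perfect
#' fit and at most 1. Used to filter posterior parameter samples: only
#' samples whose simulations agree with the measurements (TIC below an
#' acceptance threshold, 0.3 by default) are retained for analysis.
#'
#' @param measured,predicted aligned non-empty numeric vectors.
#' @return scalar in `[0, 1]`.
#' @export
tic <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) == 0L) {
    stop("`measured` and `predicted` must be non-empty and aligned", call. = FALSE)
  }
  denom <- sqrt(mean(measured^2)) + sqrt(mean(predicted^2))
  if (denom == 0) stop("TIC undefined: both series identically zero", call. = FALSE)
  sqrt(mean((measured - predicted)^2)) / denom
}

#' Sampler configuration
#'
#' Settings for the differential-evolution MCMC sampler. The defaults
#' mirror common practice for DE-MC with a past-state archive: 5 parallel
#' chains, jump scale `2.38/sqrt(2d)` with 10% of jumps at scale 1 (to
#' enable mode jumps), snooker updates with probability 0.1, archive
#' extension every 10 generations, and the first half of each chain
#' discarded as burn-in.
#'
#' @param n_chains number of parallel chains (>= 3).
#' @param max_evals total objective-evaluation budget (>= 100 per free
#'   parameter). Full-scale calibrations use 20000-50000.
#' @param snooker_p probability of a snooker update.
#' @param gamma_one_p probability of a unit jump factor.
#' @param archive_every generations between archive extensions.
#' @param burnin_frac fraction of generations discarded.
#' @param jitter standard deviation of the additive proposal jitter.
#' @param seed optional integer seed.
#' @export
pk_sampler_config <- function(n_chains = 5L, max_evals = 20000L,
                              snooker_p = 0.1, gamma_one_p = 0.1,
                              archive_every = 10L, burnin_frac = 0.5,
                              jitter = 1e-6, seed = NULL) {
  structure(list(n_chains = as.integer(n_chains), max_evals = as.integer(max_evals),
                 snooker_p = snooker_p, gamma_one_p = gamma_one_p,
                 archive_every = as.integer(archive_every),
                 burnin_frac = burnin_frac, jitter = jitter, seed = seed),
            class = "pk_sampler_config")
}

#' Differential-evolution MCMC with a past-state archive
#'
#' Adaptive MCMC in the DE-MC(ZS) family: proposals are differences of two
#' random states from an archive of past states, scaled by
#' `gamma = 2.38/sqrt(2d)` (occasionally 1), with occasional snooker
#' updates along the direction towards an archived state. The archive is
#' extended with the current chain states every few generations, which
#' makes the sampler adaptive while preserving the target distribution.
#'
#' @param logp log posterior density function over the free parameters
#'   (vector argument, in the order of `specs`); must be `-Inf` outside the
#'   support and finite somewhere.
#' @param specs list of [uniform_prior()]/[propagate_posterior()] parameter
#'   specifications; point-mass specs are held fixed and reported as
#'   constant columns.
#' @param config a [pk_sampler_config()].
#' @return object of class `pk_chains`: list with `samples` (post-burn-in
#'   tibble: `.chain`, `.gen`, one column per parameter, `.logp`),
#'   `acceptance`, `rhat` (split Gelman-Rubin per free parameter),
#'   `n_evals`.
#' @export
demc_sample <- function(logp, specs, config = pk_sampler_config()) {
  ids <- purrr::map_chr(specs, "param_id")
  is_free <- purrr::map_lgl(specs, ~ .x$prior$kind != "point")
  free <- specs[is_free]
  d <- length(free)
  if (d == 0L) stop("no free parameters to sample", call. = FALSE)
  if (config$n_chains < 3L) stop("need at least 3 chains", call. = FALSE)
  if (config$max_evals < 100L * d) {
    stop("max_evals must be >= 100 per free parameter", call. = FALSE)
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  N <- config$n_chains
  G <- max(2L, as.integer(config$max_evals %/% N))
  free_ids <- ids[is_free]

  draw_prior <- function(n) {
    vapply(free, spec_sample, numeric(n), n = n)
  }
  # archive of past states
  Z <- matrix(draw_prior(max(10L * d, 20L)), ncol = d)
  # chain initialisation: prior draws with finite density
  X <- matrix(NA_real_, N, d)
  LP <- rep(-Inf, N)
  for (i in seq_len(N)) {
    for (try in seq_len(200L)) {
      x <- as.numeric(draw_prior(1L))
      lp <- logp(x)
      if (is.finite(lp)) { X[i, ] <- x; LP[i] <- lp; break }
    }
    if (!is.finite(LP[i])) stop("could not find a finite-density starting point", call. = FALSE)
  }

  S <- array(NA_real_, c(G, N, d))
  SL <- matrix(NA_real_, G, N)
  n_accept <- 0L
  n_evals <- 0L

  for (g in seq_len(G)) {
    for (i in seq_len(N)) {
      x <- X[i, ]
      snooker <- stats::runif(1) < config$snooker_p && nrow(Z) >= 3L
      log_corr <- 0
      if (snooker) {
        pick <- sample.int(nrow(Z), 3L)
        z <- Z[pick[1L], ]
        dx <- x - z
        nrm <- sqrt(sum(dx^2))
        if (nrm < 1e-300) {
          snooker <- FALSE
        } else {
          u <- dx / nrm
          gs <- stats::runif(1, 1.2, 2.2)
          proj <- sum((Z[pick[2L], ] - Z[pick[3L], ]) * u)
          xp <- x + gs * proj * u
          nrm_p <- sqrt(sum((xp - z)^2))
          log_corr <- (d - 1) * (log(nrm_p) - log(nrm))
        }
      }
      if (!snooker) {
        pick <- sample.int(nrow(Z), 2L)
        # crossover: update a random subspace of dimensions, with the jump
        # factor scaled to the number of updated dimensions
        cr <- sample(c(0.1, 1 / 3, 2 / 3, 1), 1L)
        upd <- stats::runif(d) < cr
        if (!any(upd)) upd[sample.int(d, 1L)] <- TRUE
        d_eff <- sum(upd)
        gam <- if (stats::runif(1) < config$gamma_one_p) 1 else 2.38 / sqrt(2 * d_eff)
        e <- stats::runif(1, -0.05, 0.05)
        xp <- x
        xp[upd] <- x[upd] + gam * (1 + e) * (Z[pick[1L], upd] - Z[pick[2L], upd]) +
          stats::rnorm(d_eff, 0, config$jitter)
      }
      lpp <- logp(xp)
      n_evals <- n_evals + 1L
      if (is.finite(lpp) && log(stats::runif(1)) < lpp - LP[i] + log_corr) {
        X[i, ] <- xp
        LP[i] <- lpp
        n_accept <- n_accept + 1L
      }
      S[g, i, ] <- X[i, ]
      SL[g, i] <- LP[i]
    }
    if (g %% config$archive_every == 0L) Z <- rbind(Z, X)
  }
  if (n_accept == 0L) stop("sampler accepted no proposals; check the objective", call. = FALSE)

  burn <- as.integer(floor(config$burnin_frac * G))
  keep <- seq.int(burn + 1L, G)
  rhat <- vapply(seq_len(d), function(j) split_rhat(S[keep, , j, drop = FALSE]), numeric(1))
  names(rhat) <- free_ids

  post <- do.call(rbind, lapply(seq_len(N), function(i) {
    matrix(S[keep, i, ], ncol = d)
  }))
  colnames(post) <- free_ids
  out <- tibble::as_tibble(post)
  out <- tibble::add_column(out,
                            .chain = rep(seq_len(N), each = length(keep)),
                            .gen = rep(keep, times = N),
                            .before = 1L)
  out$.logp <- as.vector(SL[keep, ])
  # fixed (point-mass) parameters reported as constant columns
  for (sp in specs[!is_free]) out[[sp$param_id]] <- sp$prior$value

  structure(
    list(samples = out, acceptance = n_accept / n_evals, rhat = rhat,
         n_evals = n_evals, n_generations = G, d = d),
    class = "pk_chains"
  )
}

# Split-chain Gelman-Rubin potential scale reduction factor.
split_rhat <- function(mat) {
  mat <- drop(mat)
  if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1L)
  G <- nrow(mat)
  half <- G %/% 2L
  if (half < 2L) return(NA_real_)
  pieces <- cbind(mat[seq_len(half), , drop = FALSE],
                  mat[seq.int(G - half + 1L, G), , drop = FALSE])
  m <- ncol(pieces)
  n <- nrow(pieces)
  means <- colMeans(pieces)
  vars <- apply(pieces, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
print.pk_chains <- function(x, ...) {
  cat(sprintf("<pk_chains> %d draws of %d parameter(s), acceptance %.2f, max Rhat %.3f\n",
              nrow(x$samples), x$d, x$acceptance, max(x$rhat, na.rm = TRUE)))
  invisible(x)
}

#' Filter posterior samples by Theil inequality coefficient
#'
#' Re-simulates the pathway for each posterior parameter sample and keeps
#' only samples whose simulated series agree with the measurements: the
#' per-series [tic()] is aggregated (maximum over series by default; the
#' strictest choice) and compared with the acceptance threshold.
#'
#' @param samples data frame of posterior samples whose columns cover the
#'   network's free edge parameters.
#' @param net a [build_network()] object.
#' @param data tidy measured data (`time_d`, `compound`, `phase`,
#'   `concentration_ugL`).
#' @param threshold TIC acceptance threshold (default 0.3).
#' @param compounds series to include (default: observed compounds present
#'   in `data`).
#' @param aggregate `"max"` or `"mean"` over series.
#' @return list with `samples` (retained rows), `tic` (aggregated TIC per
#'   input row) and `rejected_fraction`. Errors when every sample is
#'   rejected, which signals that the model structure (not only its
#'   parameters) should be re-evaluated.
#' @export
filter_by_tic <- function(samples, net, data, threshold = 0.3,
                          compounds = NULL, aggregate = c("max", "mean")) {
  aggregate <- match.arg(aggregate)
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0L) stop("no samples to filter", call. = FALSE)
  if (is.null(compounds)) {
    compounds <- intersect(net$compounds$id[net$compounds$observed],
                           unique(data$compound))
  }
  tfun <- make_tic_fun(net, data, compounds)
  param_cols <- intersect(net$edges$param_id, names(samples))
  vals <- vapply(seq_len(nrow(samples)), function(r) {
    th <- unlist(samples[r, param_cols])
    tfun(th, aggregate)
  }, numeric(1))
  keep <- vals <= threshold
  if (!any(keep)) {
    stop("all posterior samples rejected by the TIC filter; ",
         "re-evaluate the model structure (missing pathway?)", call. = FALSE)
  }
  list(samples = samples[keep, , drop = FALSE], tic = vals,
       rejected_fraction = mean(!keep))
}

# Internal: closure computing aggregated TIC across compound x phase series
# for a full named edge-parameter vector.
make_tic_fun <- function(net, data, compounds) {
  phases <- unique(data$phase)
  parts <- lapply(phases, function(ph) {
    dd <- data[data$phase == ph & data$compound %in% compounds, , drop = FALSE]
    times <- sort(unique(dd$time_d))
    sim_phase <- if (ph == "abiotic") "abiotic" else "combined"
    sim <- make_simulator(net, sim_phase, times)
    series <- split(dd, dd$compound)
    idx <- lapply(series, function(s) match(s$time_d, times))
    list(sim = sim, series = series, idx = idx)
  })
  function(params, aggregate = "max") {
    vals <- unlist(lapply(parts, function(p) {
      k <- edge_rate_values(net, params)
      mat <- p$sim(k)
      purrr::map2_dbl(p$series, p$idx, function(s, ix) {
        tic(s$concentration_ugL, mat[s$compound[1L], ix])
      })
    }))
    if (aggregate == "max") max(vals) else mean(vals)
  }
}
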