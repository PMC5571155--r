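#' Goodness-of-fit metrics
#'
#' Root mean squared error and mean absolute error of a predicted series
#' against measurements.
#'
#' @param measured,predicted aligned non-empty numeric vectors.
#' @return one-row tibble with `rmse` and `mae`.
#' @export
rmse_mae <- function(measured, predicted) {
  if (length(measured) != length(predicted) || length(measured) == 0L) {
    stop("`measured` and `predicted` must be non-empty and aligned", call. = FALSE)
  }
  e <- predicted - measured
  tibble::tibble(rmse = sqrt(mean(e^2)), mae = mean(abs(e)))
}

#' Monte Carlo prediction bands
#'
#' Propagates posterior parameter uncertainty to model outputs: simulates
#' the pathway for each of `n_draws` joint parameter draws and returns the
#' pointwise 2.5th/97.5th percentile envelope (and median) per compound.
#'
#' @param net a [build_network()] object.
#' @param draws data frame of parameter draws covering all free edge
#'   parameters (e.g. from [parameter_draws()]); at least 200 rows are
#'   required for a stable 95% envelope.
#' @param times output times (days).
#' @param phase simulation phase.
#' @param seed seed (used only to subsample rows when `draws` has more
#'   rows than `n_draws`).
#' @param n_draws number of Monte Carlo simulations.
#' @return tibble of class `pk_bands`: `compound`, `time_d`, `lo`, `hi`,
#'   `median`.
#' @export
mc_prediction_bands <- function(net, draws, times, phase = "combined",
                                n_draws = nrow(draws), seed = 1L) {
  draws <- tibble::as_tibble(draws)
  if (n_draws < 200L) stop("need at least 200 draws for 95% prediction bands", call. = FALSE)
  set.seed(as.integer(seed))
  ix <- if (nrow(draws) > n_draws) sample.int(nrow(draws), n_draws) else
    sample.int(nrow(draws), n_draws, replace = nrow(draws) < n_draws)
  sim <- make_simulator(net, phase, times)
  ids <- net$compounds$id
  arr <- array(NA_real_, c(length(ids), length(times), n_draws))
  failures <- 0L
  for (r in seq_len(n_draws)) {
    k <- edge_rate_values(net, unlist(draws[ix[r], , drop = FALSE]))
    mat <- tryCatch(sim(k), error = function(e) NULL)
    if (is.null(mat)) failures <- failures + 1L else arr[, , r] <- mat
  }
  if (failures > 0.01 * n_draws) {
    stop("more than 1% of Monte Carlo simulations failed", call. = FALSE)
  }
  qs <- apply(arr, c(1, 2), stats::quantile, probs = c(0.025, 0.5, 0.975),
              na.rm = TRUE, type = 7)
  out <- tibble::tibble(
    compound = rep(ids, times = length(times)),
    time_d = rep(times, each = length(ids)),
    lo = as.vector(qs[1, , ]),
    median = as.vector(qs[2, , ]),
    hi = as.vector(qs[3, , ])
  )
  structure(out, class = c("pk_bands", class(out)))
}

#' Interval length, coverage and their ratio
#'
#' Prediction-uncertainty metrics of a 95% band against measurements:
#' `ARIL` is the average relative interval length,
#' `mean((hi - lo) / measured)`; `coverage` the fraction of measurements
#' inside the closed band; `ILTC = ARIL / coverage` (lower is better:
#' narrow bands that still cover the data). A zero-coverage band yields an
#' infinite ILTC.
#'
#' @param lo,hi band bounds at the measurement points.
#' @param measured measured values (must be positive: they normalize the
#'   interval length).
#' @return one-row tibble with `aril`, `coverage`, `iltc`.
#' @export
aril_coverage_iltc <- function(lo, hi, measured) {
  if (!(length(lo) == length(hi) && length(hi) == length(measured)) ||
      length(measured) == 0L) {
    stop("`lo`, `hi`, `measured` must be non-empty and aligned", call. = FALSE)
  }
  if (any(measured <= 0)) {
    stop("ARIL undefined: measured values must be positive", call. = FALSE)
  }
  aril <- mean((hi - lo) / measured)
  coverage <- mean(measured >= lo & measured <= hi)
  tibble::tibble(aril = aril, coverage = coverage,
                 iltc = if (coverage == 0) Inf else aril / coverage)
}

#' Linear correlation (collinearity) matrix of posterior samples
#'
#' Pearson correlations between posterior parameter samples; pairs whose
#' absolute correlation exceeds the collinearity threshold (0.7 by
#' default) are flagged as non-identifiable: the data cannot separate
#' them.
#'
#' @param samples data frame or matrix of joint posterior samples, at
#'   least 2 columns and 100 rows.
#' @param threshold collinearity threshold.
#' @return list with `lcc` (correlation matrix) and `flagged` (tibble of
#'   non-identifiable pairs with their correlation).
#' @export
lcc_matrix <- function(samples, threshold = 0.7) {
  m <- as.matrix(samples)
  if (ncol(m) < 2L) stop("need at least 2 parameters", call. = FALSE)
  if (nrow(m) < 100L) stop("need at least 100 joint samples", call. = FALSE)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    stop("zero-variance parameter column: ",
         paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
  }
  lcc <- stats::cor(m)
  pairs <- which(upper.tri(lcc) & abs(lcc) > threshold, arr.ind = TRUE)
  flagged <- tibble::tibble(
    param_a = colnames(lcc)[pairs[, 1]],
    param_b = colnames(lcc)[pairs[, 2]],
    lcc = lcc[pairs]
  )
  list(lcc = lcc, flagged = flagged)
}

#' Relative credibility-interval identifiability check
#'
#' A parameter is considered identifiable when its 95% credibility
#' interval deviates from the estimate by less than 50% on both sides.
#'
#' @param post a `pk_posterior`, or a numeric `c(median, lo, hi)`.
#' @param threshold relative half-width threshold (default 0.5).
#' @return one-row tibble: `median`, `rel_error` (worst side),
#'   `identifiable`.
#' @export
relative_ci_check <- function(post, threshold = 0.5) {
  if (inherits(post, "pk_posterior")) {
    med <- post$median; lo <- post$cri95[1L]; hi <- post$cri95[2L]
  } else {
    med <- post[1L]; lo <- post[2L]; hi <- post[3L]
  }
  if (!is.finite(med) || med <= 0) stop("median must be positive", call. = FALSE)
  rel <- max(abs(hi - med), abs(med - lo)) / med
  tibble::tibble(median = med, rel_error = rel, identifiable = rel < threshold)
}

#' Global sensitivity by standardized regression coefficients
#'
#' Linear-regression-based global sensitivity of a scalar model output to
#' parameter samples: `SRC_j = b_j * sd(theta_j) / sd(y)`. The coefficient
#' of determination is reported; when the linear surrogate explains less
#' than 70% of the output variance the SRC ranking is unreliable and a
#' warning is raised. For uncorrelated inputs `sum(SRC^2)` approximates
#' `R^2`.
#'
#' @param params data frame of parameter samples.
#' @param output numeric vector of the scalar output per sample.
#' @return list with `src` (tibble `param`, `src`) and `r_squared`.
#' @export
src_gsa <- function(params, output) {
  X <- as.matrix(params)
  if (nrow(X) != length(output)) stop("parameter rows and outputs must align", call. = FALSE)
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant parameter column", call. = FALSE)
  if (kappa(scale(X)) > 1e8) {
    stop("collinear parameter design: SRC regression is singular", call. = FALSE)
  }
  fit <- stats::lm(output ~ X)
  b <- stats::coef(fit)[-1L]
  src <- unname(b) * sds / stats::sd(output)
  r2 <- summary(fit)$r.squared
  if (r2 < 0.7) {
    warning(sprintf("linear surrogate weak (R^2 = %.2f < 0.7); SRC ranking unreliable", r2),
            call. = FALSE)
  }
  list(src = tibble::tibble(param = colnames(X), src = src), r_squared = r2)
}

#' Assemble a model-assessment report
#'
#' Per compound and phase: RMSE/MAE of the posterior-median prediction,
#' prediction-band ARIL/coverage/ILTC, plus per-level collinearity
#' matrices and relative-CI identifiability flags.
#'
#' @param result a `pk_calibration`.
#' @param data tidy measurements or a [generate_dataset()] object.
#' @param n_draws Monte Carlo draws for the bands.
#' @param seed integer seed.
#' @param lcc_threshold,rel_ci_threshold identifiability thresholds.
#' @return list of class `pk_assessment` with `metrics` (tibble compound x
#'   phase), `identifiability` (tibble per parameter), `lcc` (per level).
#' @export
assessment_report <- function(result, data, n_draws = 300L, seed = 1L,
                              lcc_threshold = 0.7, rel_ci_threshold = 0.5) {
  if (inherits(data, "pk_dataset")) data <- data$data
  net <- result$network
  draws <- parameter_draws(result, n = max(n_draws, 200L), seed = seed)
  med <- stats::setNames(result$table$median, result$table$param_id)
  med <- med[names(med) %in% net$edges$param_id]

  metrics <- purrr::map_dfr(unique(data$phase), function(ph) {
    sim_phase <- if (ph == "abiotic") "abiotic" else "combined"
    dd <- data[data$phase == ph, , drop = FALSE]
    times <- sort(unique(dd$time_d))
    traj <- simulate_pathway(net, med, times, phase = sim_phase)
    bands <- mc_prediction_bands(net, draws, times, phase = sim_phase,
                                 n_draws = max(n_draws, 200L), seed = seed)
    purrr::map_dfr(split(dd, dd$compound), function(s) {
      cmp <- s$compound[1L]
      pred <- traj$concentration_ugL[traj$compound == cmp][match(s$time_d, times)]
      bnd <- bands[bands$compound == cmp, ][match(s$time_d, times), ]
      dplyr::bind_cols(
        tibble::tibble(compound = cmp, phase = ph),
        rmse_mae(s$concentration_ugL, pred),
        aril_coverage_iltc(bnd$lo, bnd$hi, s$concentration_ugL)
      )
    })
  })

  ident <- purrr::map_dfr(
    purrr::keep(result$store, ~ .x$median > 0),
    function(ps) {
      dplyr::bind_cols(tibble::tibble(param_id = ps$param_id),
                       relative_ci_check(ps, rel_ci_threshold))
    })

  lcc <- purrr::compact(purrr::map(result$levels, function(lv) {
    res <- lv$result
    if (is.null(res) || length(res$free_ids) < 2L || nrow(res$samples) < 100L) return(NULL)
    tryCatch(lcc_matrix(res$samples[, res$free_ids], lcc_threshold),
             error = function(e) NULL)
  }))

  structure(list(metrics = metrics, identifiability = ident, lcc = lcc),
            class = "pk_assessment")
}

#' @export
print.pk_assessment <- function(x, ...) {
  cat("<pk_assessment>\n")
  print(x$metrics, n = Inf)
  n_flag <- sum(purrr::map_int(x$lcc, ~ nrow(.x$flagged)))
  cat(sprintf("identifiable by relative CI: %d/%d; collinear pairs flagged: %d\n",
              sum(x$identifiability$identifiable), nrow(x$identifiability), n_flag))
  invisible(x)
}

#' @rdname autoplot.pk_calibration
#' @param data measured points overlaid on the bands (optional tibble).
#' @export
autoplot.pk_bands <- function(object, data = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$time_d)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median)) +
    ggplot2::facet_wrap(ggplot2::vars(.data$compound), scales = "free_y") +
    ggplot2::labs(x = "time (d)",
                  y = expression("concentration (" * mu * "g " * L^-1 * ")")) +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    p <- p + ggplot2::geom_point(
      data = data,
      mapping = ggplot2::aes(.data$time_d, .data$concentration_ugL),
      inherit.aes = FALSE, size = 1
    )
  }
  p
}
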