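#' Wald-Wolfowitz runs test for residual sign patterns
#'
#' Tests whether the signs of a residual series alternate randomly. Few
#' runs (long one-signed stretches) indicate a systematic model-data
#' deviation. Normal approximation to the null distribution of the run
#' count; degenerate sign patterns (all one sign) return `NA` - the bias
#' statistic catches those.
#'
#' @param x numeric residuals (zeros dropped).
#' @return one-row tibble: `runs`, `expected`, `p_value`.
#' @export
runs_test <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  n1 <- sum(s > 0)
  n2 <- sum(s < 0)
  n <- n1 + n2
  if (n1 == 0L || n2 == 0L || n < 2L) {
    return(tibble::tibble(runs = NA_integer_, expected = NA_real_, p_value = NA_real_))
  }
  runs <- 1L + sum(diff(s) != 0)
  mu <- 2 * n1 * n2 / n + 1
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  z <- (runs - mu) / sqrt(v)
  tibble::tibble(runs = runs, expected = mu, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Residual diagnostics for systematic model-structure deviation
#'
#' The evaluation step between calibration levels: given a converged
#' best-fit trajectory, decides per compound whether the remaining
#' model-data deviation looks systematic (a structure problem: e.g. a
#' missing transformation branch) rather than random. Three declared
#' triggers, any of which flags the compound:
#'
#' 1. bias: `|mean(residual) / sd(residual)| > 2` (residual = predicted -
#'    measured);
#' 2. runs: Wald-Wolfowitz runs test of residual signs, p < 0.05;
#' 3. mass balance: the model-implied net flux persistently exceeds (or
#'    falls short of) the observed accumulation rate - at least 90% of
#'    the interior time points deficit-signed one way and a mean absolute
#'    deficit above 15% of the compound's flux scale.
#'
#' @param net fitted network structure.
#' @param fit_traj predicted trajectory at the measurement times (tidy:
#'   `time_d`, `compound`, `concentration_ugL`).
#' @param data measured series of one experiment phase (tidy, same
#'   columns).
#' @param params best-fit rate constants (for the mass-balance check).
#' @param phase edge set that generated the data.
#' @param alpha runs-test significance level.
#' @return tibble of class `pk_diagnostics`: per compound the bias
#'   statistic, runs-test p, mass-balance deficit summaries, individual
#'   triggers and the `verdict` (`"ok"` or `"systematic"`).
#' @export
residual_diagnostics <- function(net, fit_traj, data, params,
                                 phase = "combined", alpha = 0.05) {
  mb <- mass_balance_flux(net, data, params, phase = phase)
  flux_scale <- max(abs(c(mb$accum_fd, mb$implied)))

  out <- purrr::map_dfr(split(data, data$compound), function(s) {
    cmp <- s$compound[1L]
    pred <- fit_traj$concentration_ugL[fit_traj$compound == cmp]
    pred <- pred[match(s$time_d, fit_traj$time_d[fit_traj$compound == cmp])]
    res <- pred - s$concentration_ugL
    if (length(res) < 5L) stop("need at least 5 residuals per compound", call. = FALSE)
    bias <- mean(res) / stats::sd(res)
    rt <- runs_test(res)
    dmb <- mb$deficit[mb$compound == cmp]
    dom <- sign(sum(sign(dmb)))
    sign_frac <- if (length(dmb) && dom != 0) mean(sign(dmb) == dom) else 0
    rel_mag <- if (length(dmb)) mean(abs(dmb)) / flux_scale else 0
    trigger_bias <- abs(bias) > 2
    trigger_runs <- !is.na(rt$p_value) && rt$p_value < alpha
    trigger_mb <- sign_frac >= 0.9 && rel_mag > 0.15
    tibble::tibble(
      compound = cmp, bias = bias, runs_p = rt$p_value,
      mb_sign_frac = sign_frac, mb_rel_magnitude = rel_mag,
      mb_sign = dom,
      trigger_bias = trigger_bias, trigger_runs = trigger_runs,
      trigger_mb = trigger_mb,
      verdict = if (trigger_bias || trigger_runs || trigger_mb) "systematic" else "ok"
    )
  })
  structure(out, class = c("pk_diagnostics", class(out)))
}

#' Propose pathway branches that explain systematic deviations
#'
#' Turns flagged diagnostics into candidate structure modifications, each
#' adding a single branch to an unknown transformation-product sink:
#'
#' * a compound whose prediction deviates systematically (typically a
#'   downstream product that the model over-predicts because the fit
#'   funnels all precursor flux into it) implicates its precursors - each
#'   precursor gains a candidate `precursor -> TP` branch, ranked by that
#'   precursor's fitted flux into the compound;
#' * a compound whose own mass balance shows a persistent positive
#'   deficit (unexplained removal) gains a direct `compound -> TP`
#'   candidate.
#'
#' Re-fitting the modified networks is left to the caller; since each
#' candidate nests the original structure, the minimal attainable SSE can
#' only decrease, and the size of the decrease ranks the hypotheses.
#'
#' @param net the (mis-specified) network that was fitted.
#' @param diagnostics a [residual_diagnostics()] table.
#' @param params best-fit rate constants used for flux ranking.
#' @param data measured data (for mean concentrations in the ranking).
#' @param phase phase of the proposed branches.
#' @return tibble of candidates (`source`, `phase`, `param_id`, `score`,
#'   `because`) with the modified network in the `network` list-column,
#'   ranked by score.
#' @export
propose_branches <- function(net, diagnostics, params, data,
                             phase = "biotic") {
  flagged <- diagnostics[diagnostics$verdict == "systematic", , drop = FALSE]
  if (nrow(flagged) == 0L) {
    stop("no systematic deviations: nothing to propose", call. = FALSE)
  }
  ed <- active_edges(net, if (phase == "biotic") "combined" else "abiotic")
  k <- edge_rate_values(net, params)
  mean_conc <- data |>
    dplyr::group_by(.data$compound) |>
    dplyr::summarise(cbar = mean(.data$concentration_ugL), .groups = "drop")
  cbar <- stats::setNames(mean_conc$cbar, mean_conc$compound)

  cand <- list()
  for (i in seq_len(nrow(flagged))) {
    cmp <- flagged$compound[i]
    {
      # deviation in a product: some formation flux may need diverting
      # before it reaches the compound
      fin <- ed[ed$product == cmp, , drop = FALSE]
      for (j in seq_len(nrow(fin))) {
        src <- fin$source[j]
        mult <- if (fin$phase[j] == "biotic") net$tss else 1
        flux <- mult * k[[fin$param_id[j]]] * (if (src %in% names(cbar)) cbar[[src]] else 0)
        cand[[length(cand) + 1L]] <- tibble::tibble(
          source = src, score = flux,
          because = sprintf("systematic deviation in %s (bias %.2f)", cmp, flagged$bias[i])
        )
      }
    }
    if (isTRUE(flagged$trigger_mb[i]) && flagged$mb_sign[i] > 0) {
      # unexplained removal of the compound itself
      cand[[length(cand) + 1L]] <- tibble::tibble(
        source = cmp, score = flagged$mb_rel_magnitude[i] * max(1, cbar[[cmp]]),
        because = sprintf("%s shows unexplained removal", cmp)
      )
    }
  }
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0L) stop("no branch candidates derivable from diagnostics", call. = FALSE)
  cand <- cand |>
    dplyr::group_by(.data$source) |>
    dplyr::slice_max(.data$score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(dplyr::desc(.data$score))
  cand$phase <- phase
  cand$param_id <- sprintf("k_%s_%s_new", if (phase == "biotic") "bio" else "abio", cand$source)
  cand$network <- purrr::map2(cand$source, cand$param_id, function(src, pid) {
    edges <- dplyr::bind_rows(
      net$edges,
      tibble::tibble(source = src, product = "TP_new", phase = phase,
                     param_id = pid, stoich = 1, fixed = NA_real_)
    )
    build_network(net$compounds[net$compounds$observed, ], edges, tss = net$tss)
  })
  cand[, c("source", "phase", "param_id", "score", "because", "network")]
}

#' Best-fit rate constants by direct objective minimization
#'
#' Deterministic minimization of the range-normalized SSE over all free
#' edge parameters (multi-start L-BFGS-B). Used by structure-evaluation
#' workflows that need a converged point fit rather than a posterior,
#' e.g. comparing nested pathway structures by their minimal SSE.
#'
#' @param net a [build_network()] object.
#' @param data tidy measured data.
#' @param phase experiment phase to fit (`"abiotic"` or `"biotic"`).
#' @param upper upper parameter bound for the search.
#' @param n_starts random multi-starts.
#' @param seed integer seed for the starts.
#' @return list with `params` (named vector), `sse`, `trajectory` (at the
#'   measurement times).
#' @export
fit_min_sse <- function(net, data, phase = "biotic", upper = 25,
                        n_starts = 5L, seed = 1L) {
  dd <- data[data$phase == phase, , drop = FALSE]
  sim_phase <- if (phase == "abiotic") "abiotic" else "combined"
  edp <- if (phase == "abiotic") {
    net$edges[net$edges$phase == "abiotic", , drop = FALSE]
  } else net$edges
  ids <- edp$param_id[is.na(edp$fixed)]
  times <- sort(unique(dd$time_d))
  sim <- make_simulator(net, sim_phase, times)
  series <- split(dd, dd$compound)
  idx <- purrr::map(series, ~ match(.x$time_d, times))

  obj <- function(th) {
    k <- edge_rate_values(net, stats::setNames(pmax(th, 0), ids))
    mat <- tryCatch(sim(k), error = function(e) NULL)
    if (is.null(mat)) return(1e10)
    tot <- 0
    for (s in seq_along(series)) {
      m <- series[[s]]$concentration_ugL
      tot <- tot + sum(((m - mat[series[[s]]$compound[1L], idx[[s]]]) / diff(range(m)))^2)
    }
    tot
  }
  set.seed(as.integer(seed))
  best <- NULL
  for (s in seq_len(n_starts)) {
    th0 <- stats::runif(length(ids), 0, upper / 5)
    opt <- stats::optim(th0, obj, method = "L-BFGS-B",
                        lower = rep(0, length(ids)), upper = rep(upper, length(ids)))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  params <- stats::setNames(best$par, ids)
  traj <- simulate_pathway(net, params, times, phase = sim_phase)
  list(params = params, sse = best$value, trajectory = traj)
}
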