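#' Calibration configuration
#'
#' Settings shared by the three calibration schemes. The uniform prior
#' upper bounds for primary parameters are deliberately generous relative
#' to plausible in-sewer transformation rates; the lumped benchmark scheme
#' (Method 2) widens them further by `method2_widen`, reflecting the
#' common practice of imposing as little prior restriction as possible
#' when everything is estimated at once.
#'
#' @param prior_upper_abiotic upper uniform-prior bound for abiotic rates
#'   (1/d).
#' @param prior_upper_biotic upper bound for biotic rate constants
#'   (L/gTSS/d).
#' @param method2_widen widening factor applied to the bounds in the
#'   lumped scheme.
#' @param tic_threshold Theil-inequality-coefficient acceptance threshold
#'   for posterior filtering.
#' @param tic_aggregate aggregate TIC over series by `"max"` (strictest)
#'   or `"mean"`.
#' @param n_filter number of (evenly thinned) posterior samples carried
#'   into TIC filtering, summarization and distribution fitting per level.
#' @param families candidate distribution families for posterior fits.
#' @param sampler a [pk_sampler_config()].
#' @export
pk_calibration_config <- function(prior_upper_abiotic = 10,
                                  prior_upper_biotic = 25,
                                  method2_widen = 5,
                                  tic_threshold = 0.3,
                                  tic_aggregate = c("max", "mean"),
                                  n_filter = 500L,
                                  families = pk_dist_families(),
                                  sampler = pk_sampler_config()) {
  structure(list(
    prior_upper_abiotic = prior_upper_abiotic,
    prior_upper_biotic = prior_upper_biotic,
    method2_widen = method2_widen,
    tic_threshold = tic_threshold,
    tic_aggregate = match.arg(tic_aggregate),
    n_filter = as.integer(n_filter),
    families = families,
    sampler = sampler
  ), class = "pk_calibration_config")
}

## ---------------------------------------------------------------------------
## Internal fit engine: one sampler run over a set of parameter specs
## against the series of one experiment phase.

# Build the theta -> full-edge-parameter mapping. `total_members` maps a
# combinatorial/total id to its member edge params (the first member
# carries the total while the split is pending; the others stay 0, which
# only affects compounds outside the objective). `reparam` implements the
# fixed-total hard constraint: the last member equals total minus the
# sampled members.
make_theta_map <- function(net, specs, total_members, reparam = NULL) {
  edge_ids <- net$edges$param_id
  base <- stats::setNames(ifelse(is.na(net$edges$fixed), 0, net$edges$fixed), edge_ids)
  ids <- purrr::map_chr(specs, "param_id")
  function(theta) {
    full <- base
    for (j in seq_along(ids)) {
      id <- ids[[j]]
      if (id %in% edge_ids) {
        full[[id]] <- theta[[j]]
      } else if (!is.null(total_members[[id]])) {
        full[[total_members[[id]][1L]]] <- theta[[j]]
      }
    }
    if (!is.null(reparam)) {
      for (rp in reparam) {
        full[[rp$partner]] <- rp$total - sum(full[rp$sampled])
      }
    }
    full
  }
}

run_fit <- function(net, data, phase_exp, compounds, specs, config,
                    constraints = list(), total_members = list(),
                    reparam = NULL, seed = NULL) {
  sim_phase <- if (phase_exp == "abiotic") "abiotic" else "combined"
  dd <- data[data$phase == phase_exp & data$compound %in% compounds, , drop = FALSE]
  if (nrow(dd) == 0L) stop("no measurement series for phase ", phase_exp, call. = FALSE)
  times <- sort(unique(dd$time_d))
  sim <- make_simulator(net, sim_phase, times)
  series <- split(dd, dd$compound)
  s_comp <- purrr::map_chr(series, ~ .x$compound[1L])
  s_idx <- purrr::map(series, ~ match(.x$time_d, times))
  s_meas <- purrr::map(series, "concentration_ugL")
  s_rng <- purrr::map_dbl(s_meas, ~ diff(range(.x)))
  if (any(s_rng <= 0)) stop("constant measured series in objective", call. = FALSE)
  n_obs <- sum(lengths(s_meas))

  theta_map <- make_theta_map(net, specs, total_members, reparam)
  is_free <- purrr::map_lgl(specs, ~ .x$prior$kind != "point")
  free_specs <- specs[is_free]
  free_ids <- purrr::map_chr(free_specs, "param_id")
  spec_ids <- purrr::map_chr(specs, "param_id")
  fixed_theta <- purrr::map_dbl(specs, ~ if (.x$prior$kind == "point") .x$prior$value else NA_real_)

  assemble <- function(theta_free) {
    th <- fixed_theta
    th[is_free] <- theta_free
    th
  }

  predict_mat <- function(theta_free) {
    full <- theta_map(assemble(theta_free))
    if (any(full < 0)) return(NULL)
    tryCatch(sim(full), error = function(e) NULL)
  }

  sse_of <- function(mat) {
    total <- 0
    for (s in seq_along(series)) {
      pred <- mat[s_comp[[s]], s_idx[[s]]]
      total <- total + sum(((s_meas[[s]] - pred) / s_rng[[s]])^2)
    }
    total
  }

  logp <- function(theta_free) {
    lp <- 0
    for (j in seq_along(free_specs)) {
      lp <- lp + spec_logd(free_specs[[j]], theta_free[[j]])
      if (!is.finite(lp)) return(-Inf)
    }
    th <- assemble(theta_free)
    for (cs in constraints) {
      s <- sum(th[match(cs$member_ids, spec_ids)])
      if (s < cs$lo || s > cs$hi) return(-Inf)
    }
    mat <- predict_mat(theta_free)
    if (is.null(mat)) return(-Inf)
    sse <- sse_of(mat)
    lp - (n_obs / 2) * log(max(sse, 1e-300) / n_obs)
  }

  chains <- demc_sample(logp, specs, utils::modifyList(config$sampler, list(seed = seed)))

  # thin, then filter by TIC over the included series
  samp <- chains$samples
  take <- unique(round(seq(1L, nrow(samp), length.out = min(config$n_filter, nrow(samp)))))
  samp <- samp[take, , drop = FALSE]
  tic_vals <- vapply(seq_len(nrow(samp)), function(r) {
    theta_free <- as.numeric(samp[r, free_ids])
    mat <- predict_mat(theta_free)
    if (is.null(mat)) return(Inf)
    v <- vapply(seq_along(series), function(s) {
      tic(s_meas[[s]], mat[s_comp[[s]], s_idx[[s]]])
    }, numeric(1))
    if (config$tic_aggregate == "max") max(v) else mean(v)
  }, numeric(1))
  keep <- tic_vals <= config$tic_threshold
  if (!any(keep)) {
    stop("all posterior samples rejected by the TIC filter at level objective; ",
         "re-evaluate the model structure", call. = FALSE)
  }
  kept <- samp[keep, , drop = FALSE]

  # derived partner columns under the fixed-total reparameterization
  if (!is.null(reparam)) {
    for (rp in reparam) {
      kept[[rp$partner]] <- rp$total - rowSums(kept[, rp$sampled, drop = FALSE])
    }
  }

  list(samples = kept, tic = tic_vals[keep], rejected_fraction = mean(!keep),
       acceptance = chains$acceptance, rhat = chains$rhat,
       n_evals = chains$n_evals, free_ids = free_ids)
}

## ---------------------------------------------------------------------------

#' Execute one calibration level
#'
#' Runs the three-step estimation of a single level: assemble priors
#' (uniform for primary and combinatorial parameters, propagated posteriors
#' for subsidiary ones, branch-split bounds and sum constraints where an
#' upstream combinatorial estimate exists), sample the posterior, filter it
#' by TIC, and summarize/fit each newly estimated parameter into the
#' posterior store.
#'
#' @param level one row of a [plan_levels()] plan (data frame slice).
#' @param net,data network and tidy measured data.
#' @param store named list of `pk_posterior` objects from earlier levels
#'   (updated copy is returned).
#' @param config a [pk_calibration_config()].
#' @param method 1 (propagate distributions), or 3 (freeze upstream at
#'   medians; hard fixed-total branch constraint).
#' @param seed integer seed for this level's sampler.
#' @return list with `store` (updated), `result` (sampler/filter output)
#'   and `summaries`.
#' @export
run_level <- function(level, net, data, store, config = pk_calibration_config(),
                      method = 1, seed = NULL) {
  lv <- as.list(level)
  lv$primary <- lv$primary[[1]]; lv$combinatorial <- lv$combinatorial[[1]]
  lv$split_of <- lv$split_of[[1]]; lv$subsidiary <- lv$subsidiary[[1]]
  lv$frozen <- lv$frozen[[1]]; lv$data_compounds <- lv$data_compounds[[1]]
  phase_exp <- if (lv$phase == "A") "abiotic" else "biotic"
  upper <- if (phase_exp == "abiotic") config$prior_upper_abiotic else config$prior_upper_biotic

  if (!length(lv$primary) && !length(lv$combinatorial)) {
    warning("level ", lv$label, " has no parameters to estimate; skipping", call. = FALSE)
    return(list(store = store, result = NULL, summaries = list()))
  }
  missing_sub <- setdiff(lv$subsidiary, names(store))
  if (length(missing_sub)) {
    stop("missing subsidiary posterior(s) at level ", lv$label, ": ",
         paste(missing_sub, collapse = ", "), call. = FALSE)
  }

  total_members <- list()
  for (cb in lv$combinatorial) total_members[[cb$id]] <- cb$members
  # totals estimated earlier but entering here as subsidiary or split
  for (id in c(lv$subsidiary, lv$split_of)) {
    ps <- store[[id]]
    if (!is.null(ps) && !is.null(attr(ps, "members"))) {
      total_members[[id]] <- attr(ps, "members")
    }
  }

  specs <- list()
  constraints <- list()
  reparam <- list()
  split_members <- unlist(purrr::map(lv$split_of, ~ total_members[[.x]]))

  # split-branch primaries
  for (tid in lv$split_of) {
    post <- store[[tid]]
    if (is.null(post)) stop("missing combinatorial posterior ", tid, call. = FALSE)
    members <- total_members[[tid]]
    if (method == 3) {
      sampled <- members[-length(members)]
      for (m in sampled) specs <- c(specs, list(uniform_prior(m, 0, post$median)))
      reparam <- c(reparam, list(list(sampled = sampled,
                                      partner = members[length(members)],
                                      total = post$median)))
    } else {
      sc <- split_combinatorial(post, members)
      specs <- c(specs, sc$specs)
      constraints <- c(constraints, list(sc$constraint))
    }
  }
  # plain primaries
  for (p in setdiff(lv$primary, split_members)) {
    specs <- c(specs, list(uniform_prior(p, 0, upper)))
  }
  # combinatorial totals introduced here
  for (cb in lv$combinatorial) {
    specs <- c(specs, list(uniform_prior(cb$id, 0, upper, member_ids = cb$members)))
  }
  # subsidiaries
  for (id in lv$subsidiary) {
    specs <- c(specs, list(propagate_posterior(store[[id]], point = (method == 3))))
  }

  res <- run_fit(net, data, phase_exp, lv$data_compounds, specs, config,
                 constraints = constraints, total_members = total_members,
                 reparam = reparam, seed = seed)

  new_ids <- c(setdiff(lv$primary, unlist(purrr::map(reparam, "partner"))),
               purrr::map_chr(lv$combinatorial, "id"))
  summaries <- list()
  for (id in new_ids) {
    ps <- summarize_posterior(res$samples[[id]], id, families = config$families)
    if (!is.null(total_members[[id]])) attr(ps, "members") <- total_members[[id]]
    summaries[[id]] <- ps
    store[[id]] <- ps
  }
  # derived partners (fixed-total reparameterization) are summarized from
  # their derived samples but not distribution-fitted
  for (rp in reparam) {
    id <- rp$partner
    ps <- summarize_posterior(res$samples[[id]], id, fit = FALSE)
    summaries[[id]] <- ps
    store[[id]] <- ps
  }
  list(store = store, result = res, summaries = summaries, label = lv$label)
}

## ---------------------------------------------------------------------------
## The three calibration schemes

calibrate_engine <- function(net, data, config, seed, method) {
  if (inherits(data, "pk_dataset")) data <- data$data
  plan <- plan_levels(net)
  set.seed(as.integer(seed))
  level_seeds <- sample.int(.Machine$integer.max - 1L, nrow(plan))
  store <- list()
  levels <- list()
  for (i in seq_len(nrow(plan))) {
    out <- run_level(plan[i, ], net, data, store, config, method = method,
                     seed = level_seeds[i])
    store <- out$store
    levels[[plan$label[i]]] <- out
  }
  new_calibration(method, plan, levels, store, net, config)
}

#' Calibrate a pathway model
#'
#' The three calibration schemes benchmarked against each other:
#'
#' * **Method 1** (sequential with uncertainty propagation) walks the
#'   [plan_levels()] plan; upstream posteriors re-enter later levels as
#'   truncated fitted distributions over their 95% credibility intervals,
#'   and branch pairs are sampled freely under a soft constraint keeping
#'   their sum inside the combinatorial total's interval.
#' * **Method 2** (lumped) estimates all abiotic parameters at once
#'   against the abiotic data under widened uniform priors, then all
#'   biotic parameters at once against the biotic data, with the abiotic
#'   estimates carried as uniform priors over their credibility intervals.
#' * **Method 3** (fixed upstream) is sequential like Method 1 but freezes
#'   already-estimated parameters at their posterior medians and splits
#'   branch totals by a hard constraint: one member is sampled and the
#'   other is the frozen total minus it, which makes the pair perfectly
#'   anti-correlated by construction.
#'
#' @param net a [build_network()] object.
#' @param data tidy measurements (`time_d`, `compound`, `phase`,
#'   `concentration_ugL`) or a [generate_dataset()] object.
#' @param config a [pk_calibration_config()].
#' @param seed integer seed; fans out to per-level sampler seeds.
#' @return an object of class `pk_calibration`; see [tidy.pk_calibration()].
#' @export
calibrate_method1 <- function(net, data, config = pk_calibration_config(), seed = 1L) {
  calibrate_engine(net, data, config, seed, method = 1)
}

#' @rdname calibrate_method1
#' @export
calibrate_method3 <- function(net, data, config = pk_calibration_config(), seed = 1L) {
  calibrate_engine(net, data, config, seed, method = 3)
}

#' @rdname calibrate_method1
#' @export
calibrate_method2 <- function(net, data, config = pk_calibration_config(), seed = 1L) {
  if (inherits(data, "pk_dataset")) data <- data$data
  set.seed(as.integer(seed))
  seeds <- sample.int(.Machine$integer.max - 1L, 2L)
  ed <- net$edges
  obs <- net$compounds$id[net$compounds$observed]
  store <- list()
  levels <- list()

  free_a <- ed$param_id[ed$phase == "abiotic" & is.na(ed$fixed)]
  free_b <- ed$param_id[ed$phase == "biotic" & is.na(ed$fixed)]

  if (length(free_a) && any(data$phase == "abiotic")) {
    specs_a <- purrr::map(free_a, uniform_prior, lo = 0,
                          hi = config$method2_widen * config$prior_upper_abiotic)
    comp_a <- intersect(obs, unique(data$compound[data$phase == "abiotic"]))
    res_a <- run_fit(net, data, "abiotic", comp_a, specs_a, config, seed = seeds[1])
    sums_a <- list()
    for (id in free_a) {
      ps <- summarize_posterior(res_a$samples[[id]], id, families = config$families)
      sums_a[[id]] <- ps
      store[[id]] <- ps
    }
    levels[["lump(A)"]] <- list(result = res_a, summaries = sums_a, label = "lump(A)")
  }

  if (length(free_b) && any(data$phase == "biotic")) {
    specs_b <- purrr::map(free_b, uniform_prior, lo = 0,
                          hi = config$method2_widen * config$prior_upper_biotic)
    # abiotic parameters as subsidiary: uniform over their 95% CrI
    for (id in free_a) {
      ps <- store[[id]]
      w <- ps$cri95[2L] - ps$cri95[1L]
      specs_b <- c(specs_b, list(
        if (w <= .Machine$double.eps * max(1, ps$median)) point_prior(id, ps$median)
        else {
          sp <- uniform_prior(id, ps$cri95[1L], ps$cri95[2L])
          sp$role <- "subsidiary"
          sp
        }
      ))
    }
    comp_b <- intersect(obs, unique(data$compound[data$phase == "biotic"]))
    res_b <- run_fit(net, data, "biotic", comp_b, specs_b, config, seed = seeds[2])
    sums_b <- list()
    for (id in free_b) {
      ps <- summarize_posterior(res_b$samples[[id]], id, families = config$families)
      sums_b[[id]] <- ps
      store[[id]] <- ps
    }
    levels[["lump(B)"]] <- list(result = res_b, summaries = sums_b, label = "lump(B)")
  }

  plan <- tibble::tibble(
    level = seq_along(levels),
    phase = c("A", "B")[seq_along(levels)],
    label = names(levels),
    primary = list(free_a, free_b)[seq_along(levels)],
    combinatorial = rep(list(list()), length(levels)),
    split_of = rep(list(character(0)), length(levels)),
    subsidiary = list(character(0), free_a)[seq_along(levels)],
    frozen = rep(list(stats::setNames(numeric(0), character(0))), length(levels)),
    data_compounds = list(intersect(obs, unique(data$compound)),
                          intersect(obs, unique(data$compound)))[seq_along(levels)]
  )
  new_calibration(2, plan, levels, store, net, config)
}

## ---------------------------------------------------------------------------
## Result container + broom-style methods

new_calibration <- function(method, plan, levels, store, net, config) {
  ed <- net$edges
  level_of <- function(id) {
    for (lv in levels) {
      if (!is.null(lv$summaries[[id]])) return(lv$label)
    }
    NA_character_
  }
  rows <- purrr::map(names(store), function(id) {
    ps <- store[[id]]
    role <- if (!is.null(attr(ps, "members"))) "combinatorial"
      else if (id %in% ed$param_id) "primary" else "combinatorial"
    tibble::tibble(
      param_id = id,
      phase = if (id %in% ed$param_id) ed$phase[match(id, ed$param_id)]
        else if (grepl("abio", id)) "abiotic" else "biotic",
      level = level_of(id), role = role,
      median = ps$median, cri_lo = ps$cri95[1L], cri_hi = ps$cri95[2L],
      family = if (is.null(ps$fitted)) NA_character_ else ps$fitted$family
    )
  })
  frozen <- ed[!is.na(ed$fixed), , drop = FALSE]
  if (nrow(frozen)) {
    rows <- c(rows, list(tibble::tibble(
      param_id = frozen$param_id, phase = frozen$phase, level = NA_character_,
      role = "frozen", median = frozen$fixed, cri_lo = frozen$fixed,
      cri_hi = frozen$fixed, family = NA_character_
    )))
  }
  table <- dplyr::bind_rows(rows)
  structure(
    list(method = method, plan = plan, levels = levels, store = store,
         table = table, network = net, config = config),
    class = "pk_calibration"
  )
}

#' @export
print.pk_calibration <- function(x, ...) {
  cat(sprintf("<pk_calibration> Method %d: %d parameters over %d sub-levels\n",
              x$method, nrow(x$table), length(x$levels)))
  print(x$table, n = Inf)
  invisible(x)
}

#' Tidy and summarize calibration results
#'
#' `tidy()` returns the parameter table (one row per resolved parameter:
#' posterior median, 95% credibility interval, fitted family, role and
#' level); `glance()` a one-row model summary.
#'
#' @param x a `pk_calibration` object.
#' @param ... unused.
#' @export
tidy.pk_calibration <- function(x, ...) x$table

#' @rdname tidy.pk_calibration
#' @export
glance.pk_calibration <- function(x, ...) {
  res <- purrr::compact(purrr::map(x$levels, "result"))
  est <- dplyr::filter(x$table, .data$role != "frozen")
  tibble::tibble(
    method = x$method,
    n_levels = length(x$levels),
    n_parameters = nrow(x$table),
    n_evals = sum(purrr::map_dbl(res, "n_evals")),
    mean_acceptance = mean(purrr::map_dbl(res, "acceptance")),
    max_rhat = max(purrr::map_dbl(res, ~ max(.x$rhat, na.rm = TRUE))),
    mean_tic_rejected = mean(purrr::map_dbl(res, "rejected_fraction")),
    mean_ci_width = mean(est$cri_hi - est$cri_lo)
  )
}

#' Plot calibration results
#'
#' `autoplot()` on a calibration shows posterior medians with 95%
#' credibility-interval error bars per parameter, faceted by phase; on a
#' trajectory it draws the simulated concentration curves.
#'
#' @param object a `pk_calibration` or `pk_trajectory`.
#' @param ... unused.
#' @export
autoplot.pk_calibration <- function(object, ...) {
  tab <- dplyr::filter(object$table, .data$role != "frozen")
  ggplot2::ggplot(tab, ggplot2::aes(.data$median, .data$param_id)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$cri_lo, xmax = .data$cri_hi),
                            height = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$phase), scales = "free") +
    ggplot2::labs(x = "rate constant (median, 95% CrI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Joint parameter draws from a calibration
#'
#' Assembles full-parameter Monte Carlo draws for uncertainty analysis:
#' rows are drawn jointly within each level's filtered posterior (so
#' within-level correlations are preserved) and independently across
#' levels (marginal propagation, as in the level-wise scheme itself).
#' Frozen parameters enter as constants.
#'
#' @param result a `pk_calibration`.
#' @param n number of draws.
#' @param seed integer seed.
#' @return tibble with `n` rows and one column per edge parameter.
#' @export
parameter_draws <- function(result, n = 500L, seed = 1L) {
  set.seed(as.integer(seed))
  ed <- result$network$edges
  out <- tibble::tibble(.rows = n)
  for (lv in result$levels) {
    res <- lv$result
    if (is.null(res)) next
    cols <- intersect(names(lv$summaries), names(res$samples))
    cols <- intersect(cols, ed$param_id)
    if (!length(cols)) next
    ix <- sample.int(nrow(res$samples), n, replace = TRUE)
    for (cl in cols) out[[cl]] <- res$samples[[cl]][ix]
  }
  for (j in which(!is.na(ed$fixed))) out[[ed$param_id[j]]] <- ed$fixed[j]
  miss <- setdiff(ed$param_id, names(out))
  if (length(miss)) {
    stop("parameters without draws: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  out[, ed$param_id]
}
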