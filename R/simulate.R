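#' Simulate concentration trajectories of a pathway network
#'
#' Integrates the linear kinetic system `dC_i/dt = sum(formation) - sum(removal)`
#' with first-order abiotic rates `r = k_abio * C` and pseudo-second-order
#' biotic rates `r = k_bio * X_TSS * C`. The phase selects which edge set is
#' active; `"combined"` activates both, which is how biotic batch
#' experiments are modelled (abiotic processes do not stop in presence of
#' biomass).
#'
#' Because the system is linear with constant coefficients, the default
#' solver is an eigendecomposition of the rate matrix (exact up to numerical
#' round-off); ill-conditioned or defective cases fall back to a stiff ODE
#' integrator (`deSolve::lsoda`, rtol 1e-8 / atol 1e-10).
#'
#' @param net a [build_network()] object.
#' @param params named numeric vector of rate constants covering every free
#'   edge parameter (`k_abio` in 1/d, `k_bio` in L/gTSS/d). Frozen edge
#'   values from the network are filled in automatically.
#' @param times numeric vector of output times in days, strictly increasing,
#'   all `>= 0`.
#' @param phase `"abiotic"`, `"biotic"` or `"combined"`.
#' @param c0 optional named initial-concentration override; defaults to the
#'   network's phase-matching initial concentrations (sinks start at 0).
#' @param method `"auto"` (eigen fast path with `lsoda` fallback),
#'   `"eigen"`, or `"lsoda"`.
#'
#' @return a tibble of class `pk_trajectory` with columns `time_d`,
#'   `compound`, `concentration_ugL` and `phase`.
#' @export
simulate_pathway <- function(net, params, times,
                             phase = c("combined", "abiotic", "biotic"),
                             c0 = NULL, method = c("auto", "eigen", "lsoda")) {
  phase <- match.arg(phase)
  method <- match.arg(method)
  check_times(times)
  k <- edge_rate_values(net, params)
  if (any(k < 0)) stop("negative rate constant", call. = FALSE)
  sim <- make_simulator(net, phase, times, c0 = c0, method = method)
  mat <- sim(k)
  tibble::tibble(
    time_d = rep(times, each = nrow(mat)),
    compound = rep(rownames(mat), times = length(times)),
    concentration_ugL = as.vector(mat),
    phase = phase
  ) |> structure(class = c("pk_trajectory", "tbl_df", "tbl", "data.frame"))
}

check_times <- function(times) {
  if (!is.numeric(times) || length(times) < 1L || any(times < 0)) {
    stop("`times` must be non-negative numbers (days)", call. = FALSE)
  }
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  invisible(times)
}

# Resolve a user-supplied named parameter vector against the network's edge
# table: frozen values win, all remaining edges must be covered.
edge_rate_values <- function(net, params) {
  ids <- net$edges$param_id
  k <- net$edges$fixed
  need <- is.na(k)
  hit <- match(ids[need], names(params))
  if (anyNA(hit)) {
    stop("missing parameter value(s): ",
         paste(ids[need][is.na(hit)], collapse = ", "), call. = FALSE)
  }
  k[need] <- as.numeric(params[hit])
  stats::setNames(k, ids)
}

# Closure factory used by the calibration hot loop: precomputes index
# structure once, then maps a full edge-ordered rate vector to a
# states x times concentration matrix.
make_simulator <- function(net, phase, times, c0 = NULL,
                           method = "auto") {
  ids <- net$compounds$id
  n <- length(ids)
  ed <- active_edges(net, phase)
  src <- match(ed$source, ids)
  prd <- match(ed$product, ids)
  mult <- ifelse(ed$phase == "biotic", net$tss, 1) * ed$stoich
  rem_mult <- ifelse(ed$phase == "biotic", net$tss, 1)
  epos <- match(ed$param_id, net$edges$param_id)
  form_idx <- cbind(prd, src)

  if (is.null(c0)) {
    c0 <- if (phase == "abiotic") net$compounds$c0_abiotic else net$compounds$c0_biotic
  } else {
    full <- stats::setNames(numeric(n), ids)
    full[names(c0)] <- c0
    c0 <- full
  }
  c0 <- as.numeric(c0)
  tmax <- max(times)

  function(k_edges) {
    ke <- k_edges[epos]
    A <- matrix(0, n, n)
    # accumulate formation entries (multiple edges may share a cell)
    for (j in seq_along(ke)) {
      A[prd[j], src[j]] <- A[prd[j], src[j]] + mult[j] * ke[j]
    }
    diag_loss <- numeric(n)
    for (j in seq_along(ke)) {
      diag_loss[src[j]] <- diag_loss[src[j]] + rem_mult[j] * ke[j]
    }
    diag(A) <- diag(A) - diag_loss
    out <- NULL
    if (method != "lsoda") {
      out <- sim_eigen(A, c0, times)
    }
    if (is.null(out)) {
      if (method == "eigen") stop("eigendecomposition solver failed", call. = FALSE)
      out <- sim_lsoda(A, c0, times)
    }
    rownames(out) <- ids
    out
  }
}

# Exact solution C(t) = V exp(L t) V^-1 C0 for the linear system; returns
# NULL when the decomposition is unusable so the caller can fall back.
sim_eigen <- function(A, c0, times) {
  eg <- tryCatch(eigen(A), error = function(e) NULL)
  if (is.null(eg)) return(NULL)
  lam <- eg$values
  V <- eg$vectors
  if (is.complex(lam)) {
    if (max(abs(Im(lam))) > 1e-9 * max(1, max(abs(lam)))) return(NULL)
    lam <- Re(lam)
  }
  coef <- tryCatch(solve(V, c0), error = function(e) NULL)
  if (is.null(coef) || !all(is.finite(Mod(coef)))) return(NULL)
  # reconstruction check guards near-defective matrices
  r0 <- V %*% coef
  if (max(Mod(r0 - c0)) > 1e-8 * max(1, max(abs(c0)))) return(NULL)
  E <- exp(outer(lam, times))
  C <- V %*% (as.vector(coef) * E)
  if (is.complex(C)) C <- Re(C)
  pmax(C, 0)
}

sim_lsoda <- function(A, c0, times, rtol = 1e-8, atol = 1e-10) {
  t_in <- times
  prepend <- t_in[1L] > 0
  if (prepend) t_in <- c(0, t_in)
  sol <- deSolve::lsoda(
    y = c0, times = t_in,
    func = function(t, y, p) list(as.vector(A %*% y)),
    parms = NULL, rtol = rtol, atol = atol
  )
  if (attr(sol, "istate")[1L] < 0) stop("ODE integration failed", call. = FALSE)
  C <- t(unname(sol[, -1L, drop = FALSE]))
  if (prepend) C <- C[, -1L, drop = FALSE]
  pmax(C, 0)
}

#' Mass-balance flux residuals of a trajectory under a network
#'
#' Compares the observed net accumulation rate of each compound (central
#' finite differences of the concentration series) with the model-implied
#' formation-minus-removal rate evaluated at the same concentrations. When
#' the data were generated by the same network and rate constants the
#' residuals vanish; a persistent one-signed `deficit = implied - observed`
#' indicates flux unaccounted for by the model (e.g. a missing branch to an
#' unknown transformation product).
#'
#' @param net a [build_network()] object.
#' @param traj a tidy concentration table (`time_d`, `compound`,
#'   `concentration_ugL`) covering all compounds of `net` that carry flux;
#'   typically measured data or a simulated trajectory.
#' @param params named rate-constant vector (frozen values filled in).
#' @param phase which edge set generated `traj` (default `"combined"`).
#' @return a tibble with columns `compound`, `time_d`, `accum_fd`
#'   (finite-difference accumulation rate), `implied` (model rate),
#'   `residual` (= accum_fd - implied) and `deficit` (= implied - accum_fd).
#' @export
mass_balance_flux <- function(net, traj, params, phase = "combined") {
  stopifnot(inherits(net, "pk_network"))
  wide <- tidyr::pivot_wider(
    dplyr::arrange(traj[, c("time_d", "compound", "concentration_ugL")], .data$time_d),
    names_from = "compound", values_from = "concentration_ugL"
  )
  tt <- wide$time_d
  if (length(tt) < 3L) stop("need at least 3 time points for mass-balance fluxes", call. = FALSE)
  present <- intersect(net$compounds$id, names(wide))
  Cm <- t(as.matrix(wide[, present, drop = FALSE]))

  ed <- active_edges(net, phase)
  ed <- ed[ed$source %in% present, , drop = FALSE]
  k <- edge_rate_values(net, params)[ed$param_id]
  mult <- ifelse(ed$phase == "biotic", net$tss, 1)

  # model-implied dC/dt at measured concentrations
  implied <- matrix(0, nrow(Cm), ncol(Cm), dimnames = dimnames(Cm))
  for (j in seq_len(nrow(ed))) {
    r <- mult[j] * k[j] * Cm[ed$source[j], ]
    implied[ed$source[j], ] <- implied[ed$source[j], ] - r
    if (ed$product[j] %in% present) {
      implied[ed$product[j], ] <- implied[ed$product[j], ] + ed$stoich[j] * r
    }
  }

  mid <- 2:(length(tt) - 1L)
  fd <- (Cm[, mid + 1L, drop = FALSE] - Cm[, mid - 1L, drop = FALSE]) /
    rep(tt[mid + 1L] - tt[mid - 1L], each = nrow(Cm))

  tibble::tibble(
    compound = rep(rownames(Cm), times = length(mid)),
    time_d = rep(tt[mid], each = nrow(Cm)),
    accum_fd = as.vector(fd),
    implied = as.vector(implied[, mid, drop = FALSE]),
  ) |>
    dplyr::mutate(residual = .data$accum_fd - .data$implied,
                  deficit = -.data$residual)
}

#' @rdname autoplot.pk_calibration
#' @export
autoplot.pk_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_d, .data$concentration_ugL,
                                       colour = .data$compound)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (d)", y = expression("concentration (" * mu * "g " * L^-1 * ")"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}
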