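#' Fit a parametric distribution to posterior samples
#'
#' Fits a set of candidate families by maximum likelihood and selects the
#' best one by BIC. Candidate shapes cover the skewed, bounded and
#' heavy-tailed posteriors that arise for rate constants: normal, lognormal,
#' gamma, Weibull, exponential, logistic, log-logistic, generalized extreme
#' value and a beta rescaled to the sample range. Positive-support families
#' are skipped when the samples contain non-positive values; families whose
#' optimisation fails are skipped silently.
#'
#' Standard families are fitted with [fitdistrplus::fitdist()]; the
#' log-logistic, GEV and rescaled beta (not shipped by base R) use an
#' internal L-BFGS-B maximum-likelihood fit with the same BIC definition,
#' so scores are comparable across all families.
#'
#' @param samples numeric vector, at least 100 non-degenerate values.
#' @param families subset of [pk_dist_families()] to try.
#' @return an object of class `pk_dist`: list with `family`, named `params`,
#'   `loglik`, `bic`, `n`, and the per-family score table in `scores`.
#' @export
fit_distribution <- function(samples, families = pk_dist_families()) {
  samples <- as.numeric(samples)
  if (length(samples) < 100L) stop("need at least 100 samples to fit a distribution", call. = FALSE)
  if (!all(is.finite(samples))) stop("samples must be finite", call. = FALSE)
  if (stats::sd(samples) == 0) stop("degenerate (constant) samples", call. = FALSE)
  registry <- family_registry()
  families <- match.arg(families, pk_dist_families(), several.ok = TRUE)
  n <- length(samples)

  fits <- purrr::map(families, function(famname) {
    fam <- registry[[famname]]
    if (fam$positive && any(samples <= 0)) return(NULL)
    tryCatch({
      if (isTRUE(fam$custom)) {
        fixed <- NULL
        if (isTRUE(fam$rescaled)) {
          rng <- range(samples)
          pad <- 0.01 * diff(rng)
          fixed <- c(lo = rng[1L] - pad, hi = rng[2L] + pad)
        }
        fit <- mle_fit(samples, fam, fixed)
      } else {
        fd <- suppressWarnings(
          fitdistrplus::fitdist(samples, fam$distname,
                                start = fam$start(samples), method = "mle")
        )
        fit <- list(params = fd$estimate, loglik = fd$loglik, bic = fd$bic)
      }
      if (!is.finite(fit$bic)) return(NULL)
      tibble::tibble(family = famname, bic = fit$bic, loglik = fit$loglik,
                     params = list(fit$params))
    }, error = function(e) NULL)
  })
  scores <- dplyr::bind_rows(fits)
  if (nrow(scores) == 0L) stop("no distribution family could be fitted", call. = FALSE)
  scores <- dplyr::arrange(scores, .data$bic)
  best <- scores[1L, ]
  structure(
    list(family = best$family, params = unlist(best$params[[1L]]),
         loglik = best$loglik, bic = best$bic, n = n,
         scores = scores[, c("family", "bic", "loglik")]),
    class = "pk_dist"
  )
}

# L-BFGS-B maximum likelihood for families without base-R densities.
mle_fit <- function(x, fam, fixed = NULL) {
  start <- unlist(fam$start(x))
  nm <- names(start)
  nll <- function(par) {
    p <- c(stats::setNames(par, nm), fixed)
    v <- -sum(fam$d(x, p, log = TRUE))
    if (!is.finite(v)) 1e10 else v
  }
  lower <- if (!is.null(fam$lower)) fam$lower[nm] else rep(-Inf, length(start))
  opt <- stats::optim(start, nll, method = "L-BFGS-B", lower = lower)
  k <- length(start)
  list(params = c(stats::setNames(opt$par, nm), fixed),
       loglik = -opt$value,
       bic = 2 * opt$value + k * log(length(x)))
}

#' @export
print.pk_dist <- function(x, ...) {
  cat(sprintf("<pk_dist> %s(%s), BIC %.1f on %d samples\n", x$family,
              paste(sprintf("%s=%.4g", names(x$params), x$params), collapse = ", "),
              x$bic, x$n))
  invisible(x)
}

#' Summarize filtered posterior samples of one rate constant
#'
#' Computes the posterior median and central 95% credibility interval
#' (2.5th and 97.5th percentiles, linear-interpolation type-7 quantiles)
#' and, optionally, the best-fitting parametric distribution, which later
#' levels re-use as a subsidiary prior.
#'
#' @param samples numeric vector of (TIC-filtered) posterior draws.
#' @param param_id identifier carried along in the summary.
#' @param fit fit a distribution via [fit_distribution()]? Fit failures
#'   degrade gracefully to `fitted = NULL` (a uniform prior is then used
#'   downstream).
#' @param families candidate families for the fit.
#' @return object of class `pk_posterior` with fields `param_id`, `samples`,
#'   `median`, `cri95` (length-2), `fitted`.
#' @export
summarize_posterior <- function(samples, param_id = NA_character_, fit = TRUE,
                                families = pk_dist_families()) {
  samples <- as.numeric(samples)
  if (length(samples) == 0L) stop("empty posterior sample set", call. = FALSE)
  if (length(unique(samples)) == 1L) {
    stop("degenerate posterior: all samples identical", call. = FALSE)
  }
  cri <- unname(stats::quantile(samples, c(0.025, 0.975), type = 7))
  fitted <- NULL
  if (fit && length(samples) >= 100L) {
    fitted <- tryCatch(fit_distribution(samples, families), error = function(e) NULL)
  }
  structure(
    list(param_id = param_id, samples = samples,
         median = stats::median(samples), cri95 = cri, fitted = fitted),
    class = "pk_posterior"
  )
}

#' @export
print.pk_posterior <- function(x, ...) {
  cat(sprintf("<pk_posterior> %s: median %.4g, 95%% CrI [%.4g, %.4g] (%d samples%s)\n",
              x$param_id, x$median, x$cri95[1L], x$cri95[2L], length(x$samples),
              if (is.null(x$fitted)) "" else paste0(", ", x$fitted$family, " fit")))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Parameter specifications (priors + roles)

#' Construct prior specifications for rate parameters
#'
#' `uniform_prior()` builds a primary (or, with `member_ids`, combinatorial)
#' parameter with a flat prior on `[lo, hi]`. A combinatorial parameter
#' stands for the total removal rate of a compound with two or more
#' transformation branches and equals the sum of the member rates.
#' `point_prior()` freezes a parameter at a fixed value (used by the
#' fixed-upstream benchmark scheme, and for structurally frozen rates).
#'
#' @param param_id parameter name.
#' @param lo,hi prior bounds, `0 <= lo < hi`.
#' @param member_ids for a combinatorial parameter, the two or more branch
#'   parameter ids whose sum it represents.
#' @param value frozen value for `point_prior()`.
#' @return an object of class `pk_spec`.
#' @export
uniform_prior <- function(param_id, lo, hi, member_ids = NULL) {
  if (!is.numeric(lo) || !is.numeric(hi) || lo < 0 || hi < 0) {
    stop("prior bounds must be non-negative numbers", call. = FALSE)
  }
  if (lo >= hi) stop("prior requires lo < hi", call. = FALSE)
  role <- "primary"
  if (!is.null(member_ids)) {
    if (length(member_ids) < 2L) stop("a combinatorial parameter needs >= 2 members", call. = FALSE)
    role <- "combinatorial"
  }
  structure(
    list(param_id = param_id, role = role,
         prior = list(kind = "uniform", lo = lo, hi = hi),
         member_ids = member_ids),
    class = "pk_spec"
  )
}

#' @rdname uniform_prior
#' @export
point_prior <- function(param_id, value) {
  stopifnot(is.numeric(value), length(value) == 1L, value >= 0)
  structure(
    list(param_id = param_id, role = "subsidiary",
         prior = list(kind = "point", value = value), member_ids = NULL),
    class = "pk_spec"
  )
}

#' Propagate a level posterior into a subsidiary prior
#'
#' The central uncertainty-propagation step: the 95% credibility interval
#' estimated at an upstream level becomes the support of the parameter at
#' all later levels, carrying both the range and the fitted distribution
#' shape (truncated and renormalized on the interval). When no distribution
#' could be fitted, or the fitted mass on the interval is negligible, the
#' prior degrades to uniform on the interval. With `point = TRUE` the
#' parameter is instead frozen at the posterior median (the fixed-upstream
#' benchmark; no uncertainty is propagated).
#'
#' @param post a [summarize_posterior()] object.
#' @param point freeze at the median instead of propagating the interval.
#' @return a subsidiary `pk_spec`.
#' @export
propagate_posterior <- function(post, point = FALSE) {
  stopifnot(inherits(post, "pk_posterior"))
  if (point) return(point_prior(post$param_id, post$median))
  lo <- post$cri95[1L]
  hi <- post$cri95[2L]
  if (hi - lo <= .Machine$double.eps * max(1, abs(hi))) {
    return(point_prior(post$param_id, post$median))
  }
  prior <- NULL
  if (!is.null(post$fitted)) {
    Z <- dist_p(post$fitted, hi) - dist_p(post$fitted, lo)
    if (is.finite(Z) && Z > 1e-10) {
      prior <- list(kind = "trunc", dist = post$fitted, lo = lo, hi = hi, logZ = log(Z))
    }
  }
  if (is.null(prior)) prior <- list(kind = "uniform", lo = lo, hi = hi)
  structure(
    list(param_id = post$param_id, role = "subsidiary", prior = prior,
         member_ids = NULL),
    class = "pk_spec"
  )
}

#' Split a combinatorial posterior into branch-member priors
#'
#' After the total removal rate of a branching compound has been estimated,
#' each branch member becomes a primary parameter with a uniform prior on
#' `[0, upper bound of the total's 95% CrI]`, plus a soft constraint keeping
#' the member sum inside the total's credibility interval (enforced in the
#' sampler's prior).
#'
#' @param post posterior of the combinatorial total.
#' @param member_ids the branch parameter ids.
#' @return list with `specs` (one uniform `pk_spec` per member) and
#'   `constraint` (`member_ids`, `lo`, `hi`).
#' @export
split_combinatorial <- function(post, member_ids) {
  stopifnot(inherits(post, "pk_posterior"), length(member_ids) >= 2L)
  hi <- post$cri95[2L]
  list(
    specs = purrr::map(member_ids, uniform_prior, lo = 0, hi = hi),
    constraint = list(member_ids = member_ids,
                      lo = post$cri95[1L], hi = post$cri95[2L])
  )
}

## log prior density, sampling, and support for a spec --------------------

spec_logd <- function(spec, x) {
  pr <- spec$prior
  switch(pr$kind,
    uniform = ifelse(x >= pr$lo & x <= pr$hi, -log(pr$hi - pr$lo), -Inf),
    trunc = ifelse(x >= pr$lo & x <= pr$hi,
                   dist_logd(pr$dist, x) - pr$logZ, -Inf),
    point = ifelse(x == pr$value, 0, -Inf)
  )
}

spec_sample <- function(spec, n) {
  pr <- spec$prior
  switch(pr$kind,
    uniform = stats::runif(n, pr$lo, pr$hi),
    trunc = {
      plo <- dist_p(pr$dist, pr$lo)
      phi <- dist_p(pr$dist, pr$hi)
      u <- stats::runif(n, plo, phi)
      pmin(pmax(dist_q(pr$dist, u), pr$lo), pr$hi)
    },
    point = rep(pr$value, n)
  )
}

spec_support <- function(spec) {
  pr <- spec$prior
  if (pr$kind == "point") c(pr$value, pr$value) else c(pr$lo, pr$hi)
}
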