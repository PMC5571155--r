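## Density/CDF/quantile functions for the posterior-shape families that
## base R does not ship. Parameterizations follow the usual conventions.

#' Log-logistic, generalized extreme value and range-rescaled beta
#' distributions
#'
#' Helper distributions used when fitting posterior parameter samples.
#' `llogis` is the log-logistic with `shape` b and `scale` a
#' (cdf `1/(1 + (x/a)^-b)`); `gev` the generalized extreme value with
#' location/scale/shape (`shape = 0` is Gumbel); `betasc` a beta
#' distribution affinely rescaled to a fixed support `[lo, hi]`.
#'
#' @param x,q,p numeric vectors.
#' @param shape,scale,loc,shape1,shape2,lo,hi distribution parameters.
#' @param log,lower.tail as in base R distribution functions.
#' @name pk-distributions
NULL

#' @rdname pk-distributions
#' @export
dllogis <- function(x, shape, scale, log = FALSE) {
  ld <- ifelse(
    x > 0,
    log(shape) - log(scale) + (shape - 1) * (log(x) - log(scale)) -
      2 * log1p((x / scale)^shape),
    -Inf
  )
  if (log) ld else exp(ld)
}

#' @rdname pk-distributions
#' @export
pllogis <- function(q, shape, scale, lower.tail = TRUE) {
  p <- ifelse(q > 0, 1 / (1 + (q / scale)^(-shape)), 0)
  if (lower.tail) p else 1 - p
}

#' @rdname pk-distributions
#' @export
qllogis <- function(p, shape, scale) {
  ifelse(p <= 0, 0, ifelse(p >= 1, Inf, scale * (p / (1 - p))^(1 / shape)))
}

#' @rdname pk-distributions
#' @export
dgev <- function(x, loc, scale, shape, log = FALSE) {
  z <- (x - loc) / scale
  if (abs(shape) < 1e-12) {
    ld <- -log(scale) - z - exp(-z)
  } else {
    t <- 1 + shape * z
    ld <- ifelse(t > 0,
                 -log(scale) - (1 / shape + 1) * log(pmax(t, 1e-300)) -
                   pmax(t, 1e-300)^(-1 / shape),
                 -Inf)
  }
  if (log) ld else exp(ld)
}

#' @rdname pk-distributions
#' @export
pgev <- function(q, loc, scale, shape, lower.tail = TRUE) {
  z <- (q - loc) / scale
  if (abs(shape) < 1e-12) {
    p <- exp(-exp(-z))
  } else {
    t <- 1 + shape * z
    p <- ifelse(t > 0, exp(-t^(-1 / shape)), as.numeric(shape > 0) * 0 + (shape < 0))
    # below lower endpoint (shape > 0): 0; above upper endpoint (shape < 0): 1
    p <- ifelse(t <= 0, ifelse(shape > 0, 0, 1), p)
  }
  if (lower.tail) p else 1 - p
}

#' @rdname pk-distributions
#' @export
qgev <- function(p, loc, scale, shape) {
  if (abs(shape) < 1e-12) return(loc - scale * log(-log(p)))
  loc + scale * ((-log(p))^(-shape) - 1) / shape
}

#' @rdname pk-distributions
#' @export
dbetasc <- function(x, shape1, shape2, lo, hi, log = FALSE) {
  z <- (x - lo) / (hi - lo)
  ld <- ifelse(z > 0 & z < 1,
               stats::dbeta(pmin(pmax(z, 1e-300), 1 - 1e-16), shape1, shape2, log = TRUE) -
                 log(hi - lo),
               -Inf)
  if (log) ld else exp(ld)
}

#' @rdname pk-distributions
#' @export
pbetasc <- function(q, shape1, shape2, lo, hi, lower.tail = TRUE) {
  stats::pbeta(pmin(pmax((q - lo) / (hi - lo), 0), 1), shape1, shape2,
               lower.tail = lower.tail)
}

#' @rdname pk-distributions
#' @export
qbetasc <- function(p, shape1, shape2, lo, hi) {
  lo + (hi - lo) * stats::qbeta(p, shape1, shape2)
}

## ---------------------------------------------------------------------------
## Family registry. Each entry: whether fitdistrplus handles it directly
## ("fitdist"), moment-based starting values, support requirement, and
## d/p/q accessors taking a named parameter vector.

pk_dist_families <- function() {
  c("normal", "lognormal", "gamma", "weibull", "exponential", "logistic",
    "loglogistic", "gev", "beta")
}

family_registry <- function() {
  list(
    normal = list(
      distname = "norm", positive = FALSE,
      start = function(x) list(mean = mean(x), sd = stats::sd(x)),
      d = function(x, p, log = FALSE) stats::dnorm(x, p[["mean"]], p[["sd"]], log = log),
      p = function(q, p) stats::pnorm(q, p[["mean"]], p[["sd"]]),
      q = function(pr, p) stats::qnorm(pr, p[["mean"]], p[["sd"]])
    ),
    lognormal = list(
      distname = "lnorm", positive = TRUE,
      start = function(x) list(meanlog = mean(log(x)), sdlog = stats::sd(log(x))),
      d = function(x, p, log = FALSE) stats::dlnorm(x, p[["meanlog"]], p[["sdlog"]], log = log),
      p = function(q, p) stats::plnorm(q, p[["meanlog"]], p[["sdlog"]]),
      q = function(pr, p) stats::qlnorm(pr, p[["meanlog"]], p[["sdlog"]])
    ),
    gamma = list(
      distname = "gamma", positive = TRUE,
      start = function(x) {
        m <- mean(x); v <- stats::var(x)
        list(shape = m^2 / v, rate = m / v)
      },
      d = function(x, p, log = FALSE) stats::dgamma(x, p[["shape"]], p[["rate"]], log = log),
      p = function(q, p) stats::pgamma(q, p[["shape"]], p[["rate"]]),
      q = function(pr, p) stats::qgamma(pr, p[["shape"]], p[["rate"]])
    ),
    weibull = list(
      distname = "weibull", positive = TRUE,
      start = function(x) list(shape = 1.2, scale = mean(x)),
      d = function(x, p, log = FALSE) stats::dweibull(x, p[["shape"]], p[["scale"]], log = log),
      p = function(q, p) stats::pweibull(q, p[["shape"]], p[["scale"]]),
      q = function(pr, p) stats::qweibull(pr, p[["shape"]], p[["scale"]])
    ),
    exponential = list(
      distname = "exp", positive = TRUE,
      start = function(x) list(rate = 1 / mean(x)),
      d = function(x, p, log = FALSE) stats::dexp(x, p[["rate"]], log = log),
      p = function(q, p) stats::pexp(q, p[["rate"]]),
      q = function(pr, p) stats::qexp(pr, p[["rate"]])
    ),
    logistic = list(
      distname = "logis", positive = FALSE,
      start = function(x) list(location = mean(x), scale = stats::sd(x) * sqrt(3) / pi),
      d = function(x, p, log = FALSE) stats::dlogis(x, p[["location"]], p[["scale"]], log = log),
      p = function(q, p) stats::plogis(q, p[["location"]], p[["scale"]]),
      q = function(pr, p) stats::qlogis(pr, p[["location"]], p[["scale"]])
    ),
    loglogistic = list(
      distname = "llogis", positive = TRUE, custom = TRUE,
      start = function(x) {
        lx <- log(x)
        list(shape = pi / (sqrt(3) * stats::sd(lx)), scale = exp(stats::median(lx)))
      },
      lower = c(shape = 1e-6, scale = 1e-12),
      d = function(x, p, log = FALSE) dllogis(x, p[["shape"]], p[["scale"]], log = log),
      p = function(q, p) pllogis(q, p[["shape"]], p[["scale"]]),
      q = function(pr, p) qllogis(pr, p[["shape"]], p[["scale"]])
    ),
    gev = list(
      distname = "gev", positive = FALSE, custom = TRUE,
      start = function(x) {
        s <- stats::sd(x)
        list(loc = mean(x) - 0.45 * s, scale = 0.78 * s, shape = 0.1)
      },
      lower = c(loc = -Inf, scale = 1e-12, shape = -0.95),
      d = function(x, p, log = FALSE) dgev(x, p[["loc"]], p[["scale"]], p[["shape"]], log = log),
      p = function(q, p) pgev(q, p[["loc"]], p[["scale"]], p[["shape"]]),
      q = function(pr, p) qgev(pr, p[["loc"]], p[["scale"]], p[["shape"]])
    ),
    beta = list(
      distname = "betasc", positive = FALSE, custom = TRUE, rescaled = TRUE,
      start = function(x) list(shape1 = 2, shape2 = 2),
      lower = c(shape1 = 1e-3, shape2 = 1e-3),
      d = function(x, p, log = FALSE)
        dbetasc(x, p[["shape1"]], p[["shape2"]], p[["lo"]], p[["hi"]], log = log),
      p = function(q, p) pbetasc(q, p[["shape1"]], p[["shape2"]], p[["lo"]], p[["hi"]]),
      q = function(pr, p) qbetasc(pr, p[["shape1"]], p[["shape2"]], p[["lo"]], p[["hi"]])
    )
  )
}

# Evaluate a fitted distribution's log-density / cdf / quantile.
dist_logd <- function(dist, x) {
  fam <- family_registry()[[dist$family]]
  fam$d(x, dist$params, log = TRUE)
}
dist_p <- function(dist, q) {
  fam <- family_registry()[[dist$family]]
  fam$p(q, dist$params)
}
dist_q <- function(dist, p) {
  fam <- family_registry()[[dist$family]]
  fam$q(p, dist$params)
}
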