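#' Build a validated transformation-pathway network
#'
#' A pathway network is a directed acyclic graph of compounds connected by
#' abiotic (chemical, first-order, `k_abio * C`) and biotic (microbially
#' mediated, pseudo-second-order, `k_bio * X_TSS * C`) transformation edges.
#' Edges may point to unknown transformation-product sinks: any `product`
#' that is not a declared compound is registered automatically as an
#' unobserved sink state with zero initial concentration. Sinks are tracked
#' as state variables (so mass balances close) but never enter calibration
#' objectives.
#'
#' @param compounds a data frame with columns `id` (unique short name),
#'   and optionally `observed` (logical, default `TRUE`), `c0_abiotic`,
#'   `c0_biotic` (initial concentrations, ug/L, default 0).
#' @param edges a data frame with columns `source`, `product`, `phase`
#'   (`"abiotic"` or `"biotic"`), `param_id` (unique rate-constant name),
#'   and optionally `stoich` (yield factor, default 1) and `fixed`
#'   (a frozen rate-constant value, `NA` when the parameter is free).
#' @param tss total suspended solids, gTSS/L; multiplies all biotic rates.
#'
#' @return an object of class `pk_network`: a list with tibbles `compounds`
#'   and `edges`, the scalar `tss`, and a topological ordering of states.
#' @examples
#' net <- build_network(
#'   compounds = data.frame(id = c("A", "B"), c0_abiotic = c(1, 0)),
#'   edges = data.frame(source = "A", product = "B",
#'                      phase = "abiotic", param_id = "k_abio_A"),
#'   tss = 0.4
#' )
#' @export
build_network <- function(compounds, edges, tss = 0.4) {
  compounds <- tibble::as_tibble(compounds)
  edges <- tibble::as_tibble(edges)
  stopifnot(is.numeric(tss), length(tss) == 1L)
  if (tss <= 0) stop("`tss` must be > 0 (gTSS/L)", call. = FALSE)
  if (!"id" %in% names(compounds)) stop("`compounds` needs an `id` column", call. = FALSE)
  if (anyDuplicated(compounds$id)) {
    stop("duplicate compound id: ",
         paste(unique(compounds$id[duplicated(compounds$id)]), collapse = ", "),
         call. = FALSE)
  }
  if (!"observed" %in% names(compounds)) compounds$observed <- TRUE
  if (!"c0_abiotic" %in% names(compounds)) compounds$c0_abiotic <- 0
  if (!"c0_biotic" %in% names(compounds)) compounds$c0_biotic <- 0
  if (any(compounds$c0_abiotic < 0) || any(compounds$c0_biotic < 0)) {
    stop("initial concentrations must be >= 0", call. = FALSE)
  }

  req <- c("source", "product", "phase", "param_id")
  miss <- setdiff(req, names(edges))
  if (length(miss)) stop("`edges` is missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"stoich" %in% names(edges)) edges$stoich <- 1
  if (!"fixed" %in% names(edges)) edges$fixed <- NA_real_
  if (!all(edges$phase %in% c("abiotic", "biotic"))) {
    stop("edge `phase` must be 'abiotic' or 'biotic'", call. = FALSE)
  }
  if (any(edges$stoich <= 0)) stop("`stoich` must be > 0", call. = FALSE)
  if (any(edges$source == edges$product)) {
    stop("self-loop edge detected (source == product)", call. = FALSE)
  }
  if (anyDuplicated(edges$param_id)) {
    stop("duplicate param_id: ",
         paste(unique(edges$param_id[duplicated(edges$param_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad_src <- setdiff(edges$source, compounds$id)
  if (length(bad_src)) {
    stop("edge source not among declared compounds: ", paste(bad_src, collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.na(edges$fixed) & edges$fixed < 0)) {
    stop("fixed rate constants must be >= 0", call. = FALSE)
  }

  # auto-register unknown transformation-product sinks
  sinks <- setdiff(edges$product, compounds$id)
  if (length(sinks)) {
    compounds <- dplyr::bind_rows(
      compounds,
      tibble::tibble(id = sinks, observed = FALSE, c0_abiotic = 0, c0_biotic = 0)
    )
  }

  net <- structure(
    list(
      compounds = compounds[, c("id", "observed", "c0_abiotic", "c0_biotic")],
      edges = edges[, c("source", "product", "phase", "param_id", "stoich", "fixed")],
      tss = as.numeric(tss)
    ),
    class = "pk_network"
  )
  net$topo <- topo_sort(net)  # errors on cycles
  net
}

# Kahn topological sort over all edges (both phases); errors on cycles.
topo_sort <- function(net) {
  ids <- net$compounds$id
  indeg <- stats::setNames(integer(length(ids)), ids)
  tab <- table(net$edges$product)
  indeg[names(tab)] <- as.integer(tab)
  order <- character(0)
  queue <- ids[indeg == 0L]
  indeg_work <- indeg
  edges <- net$edges
  while (length(queue)) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    order <- c(order, v)
    out <- edges$product[edges$source == v]
    for (w in out) {
      indeg_work[[w]] <- indeg_work[[w]] - 1L
      if (indeg_work[[w]] == 0L) queue <- c(queue, w)
    }
    edges <- edges[edges$source != v, , drop = FALSE]
  }
  if (length(order) != length(ids)) {
    stop("cycle detected in pathway network", call. = FALSE)
  }
  order
}

#' @export
print.pk_network <- function(x, ...) {
  n_obs <- sum(x$compounds$observed)
  n_sink <- sum(!x$compounds$observed)
  cat(sprintf("<pk_network> %d observed compounds + %d sinks, %d abiotic / %d biotic edges, TSS = %g gTSS/L\n",
              n_obs, n_sink,
              sum(x$edges$phase == "abiotic"), sum(x$edges$phase == "biotic"),
              x$tss))
  invisible(x)
}

#' List the free rate parameters of a network by phase
#'
#' Returns the rate-constant identifiers of all edges, split by phase and
#' sorted, including frozen parameters (e.g. an abiotic rate pinned to zero
#' because no abiotic loss was observed): they are part of the model even
#' though they are not sampled.
#'
#' @param net a [build_network()] object.
#' @return a list with character vectors `abiotic` and `biotic`.
#' @export
enumerate_rate_parameters <- function(net) {
  stopifnot(inherits(net, "pk_network"))
  list(
    abiotic = sort(net$edges$param_id[net$edges$phase == "abiotic"]),
    biotic = sort(net$edges$param_id[net$edges$phase == "biotic"])
  )
}

# Edges active in an experimental phase. Biotic batch experiments also
# undergo abiotic transformation, hence "combined" activates both edge sets.
active_edges <- function(net, phase) {
  phase <- match.arg(phase, c("abiotic", "biotic", "combined"))
  if (phase == "combined") net$edges else net$edges[net$edges$phase == phase, , drop = FALSE]
}

# Precursors (formation sources) of a compound under a set of edges.
precursors_of <- function(edges, id) unique(edges$source[edges$product == id])

# products of a compound
products_of <- function(edges, id) unique(edges$product[edges$source == id])
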