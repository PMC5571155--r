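#' Read and write tidy concentration time series
#'
#' The on-disk format is a plain CSV with columns `time_d`, `compound`,
#' `phase` (`abiotic`/`biotic`) and `concentration_ugL`, optionally with a
#' constant `tss_gL` column. Units are pinned by the column names: days,
#' micrograms per litre, gTSS per litre.
#'
#' @param path CSV file path.
#' @return a tibble sorted by phase, compound and time, with the TSS (if
#'   present) in attribute `tss`.
#' @export
read_timeseries <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  req <- c("time_d", "compound", "phase", "concentration_ugL")
  miss <- setdiff(req, names(dat))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(dat$concentration_ugL < 0)
  if (length(bad)) {
    stop("negative concentration in row(s): ", paste(utils::head(bad, 5), collapse = ", "),
         call. = FALSE)
  }
  key <- paste(dat$time_d, dat$compound, dat$phase)
  if (anyDuplicated(key)) {
    stop("duplicate (time, compound, phase) row(s): row ",
         which(duplicated(key))[1L], call. = FALSE)
  }
  unsorted <- dat |>
    dplyr::group_by(.data$phase, .data$compound) |>
    dplyr::summarise(bad = is.unsorted(.data$time_d), .groups = "drop")
  if (any(unsorted$bad)) {
    warning("input times were unsorted within a series; re-sorted", call. = FALSE)
  }
  sorted <- dplyr::arrange(dat, .data$phase, .data$compound, .data$time_d)
  tss <- if ("tss_gL" %in% names(sorted)) unique(sorted$tss_gL)[1L] else NULL
  out <- sorted[, req]
  attr(out, "tss") <- tss
  out
}

#' @rdname read_timeseries
#' @param data tidy series tibble (or a `pk_dataset`).
#' @param tss optional TSS to record in a `tss_gL` column.
#' @export
write_timeseries <- function(data, path, tss = NULL) {
  if (inherits(data, "pk_dataset")) {
    if (is.null(tss)) tss <- data$tss
    data <- data$data
  }
  out <- data[, c("time_d", "compound", "phase", "concentration_ugL")]
  if (!is.null(tss)) out$tss_gL <- tss
  readr::write_csv(out, path)
  invisible(path)
}

#' Read and write pathway networks as YAML
#'
#' Schema (version 1): top-level `schema_version`, `tss_gL`, `compounds`
#' (list of `id`, `observed`, `c0_abiotic_ugL`, `c0_biotic_ugL`) and
#' `edges` (list of `source`, `product`, `phase`, `param_id`, `stoich`,
#' optional `fixed`).
#'
#' @param path YAML file path.
#' @return a `pk_network`.
#' @export
read_network <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$compounds) || is.null(doc$edges)) {
    stop("network file needs `compounds` and `edges`", call. = FALSE)
  }
  compounds <- purrr::map_dfr(doc$compounds, function(cp) {
    tibble::tibble(
      id = cp$id,
      observed = cp$observed %||% TRUE,
      c0_abiotic = cp$c0_abiotic_ugL %||% 0,
      c0_biotic = cp$c0_biotic_ugL %||% 0
    )
  })
  edges <- purrr::map_dfr(doc$edges, function(e) {
    tibble::tibble(
      source = e$source, product = e$product, phase = e$phase,
      param_id = e$param_id, stoich = e$stoich %||% 1,
      fixed = if (is.null(e$fixed)) NA_real_ else as.numeric(e$fixed)
    )
  })
  build_network(compounds, edges, tss = doc$tss_gL %||% 0.4)
}

#' @rdname read_network
#' @param net a `pk_network`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "pk_network"))
  doc <- list(
    schema_version = 1L,
    tss_gL = net$tss,
    compounds = purrr::pmap(net$compounds, function(id, observed, c0_abiotic, c0_biotic) {
      list(id = id, observed = observed,
           c0_abiotic_ugL = c0_abiotic, c0_biotic_ugL = c0_biotic)
    }),
    edges = purrr::pmap(net$edges, function(source, product, phase, param_id, stoich, fixed) {
      e <- list(source = source, product = product, phase = phase,
                param_id = param_id, stoich = stoich)
      if (!is.na(fixed)) e$fixed <- fixed
      e
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}
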