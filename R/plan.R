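#' Decompose a pathway network into sequential calibration levels
#'
#' Builds the level-wise estimation plan that the sequential calibration
#' scheme executes. The rules formalize the level structure of the method:
#'
#' * Abiotic: a compound's abiotic rate is scheduled at
#'   `1 + max(level of its abiotic precursors)`, roots at level 1. A
#'   compound with two or more free abiotic branches gets a combinatorial
#'   total (the sum of the branch rates) at its own level; the branch
#'   members become primary at the next level, together with the products'
#'   own parameters. Structurally frozen rates (e.g. an abiotic rate pinned
#'   to zero) are recorded at their compound's level but not estimated.
#' * Biotic: a compound's biotic rate (or combinatorial total) is scheduled
#'   one level after its abiotic level - the abiotic subsidiaries must
#'   exist first - and no earlier than one level after each of its biotic
#'   precursors' totals. A biotic branch split is scheduled at the earliest
#'   level at which an observed branch product's own biotic parameter is
#'   primary (never before the total's next level); when no branch product
#'   is observed, the split follows the total immediately.
#' * The objective of each level accumulates, within its experiment phase,
#'   the measurement series of every compound whose trajectory is fully
#'   determined by parameters resolved up to that level.
#'
#' Within a level index, the abiotic sub-level runs before the biotic one.
#' The planner is a pure function of the network: the same network always
#' yields the same plan.
#'
#' @param net a [build_network()] object (acyclic, validated).
#' @return a tibble of class `pk_plan`, one row per sub-level, with columns
#'   `level`, `phase` (`"A"`/`"B"`), `label`, and list-columns `primary`,
#'   `combinatorial` (each entry `list(id, members)`), `split_of` (totals
#'   whose members become primary here), `subsidiary`, `frozen` (named
#'   numeric) and `data_compounds`.
#' @export
plan_levels <- function(net) {
  stopifnot(inherits(net, "pk_network"))
  ed <- net$edges
  ed_a <- ed[ed$phase == "abiotic", , drop = FALSE]
  ed_b <- ed[ed$phase == "biotic", , drop = FALSE]
  topo <- net$topo

  free_out <- function(edges, id) edges[edges$source == id & is.na(edges$fixed), , drop = FALSE]
  out_all <- function(edges, id) edges[edges$source == id, , drop = FALSE]

  # ---- abiotic levels -----------------------------------------------------
  lev_a <- stats::setNames(rep(NA_integer_, length(topo)), topo)
  branching_a <- stats::setNames(logical(length(topo)), topo)
  for (id in topo) {
    pre <- precursors_of(ed_a, id)
    # a product is scheduled one level after its precursors; the members of
    # a branching precursor are split at that same level (co-estimated)
    resolved <- purrr::map_int(pre, function(p) lev_a[[p]])
    lev_a[[id]] <- if (length(resolved)) max(resolved) + 1L else 1L
    branching_a[[id]] <- nrow(free_out(ed_a, id)) >= 2L
  }

  # ---- biotic levels ------------------------------------------------------
  lev_b <- stats::setNames(rep(NA_integer_, length(topo)), topo)
  branching_b <- stats::setNames(logical(length(topo)), topo)
  for (id in topo) branching_b[[id]] <- nrow(free_out(ed_b, id)) >= 2L
  for (id in topo) {
    pre <- precursors_of(ed_b, id)
    pre_lev <- purrr::map_int(pre, function(p) lev_b[[p]])
    lev_b[[id]] <- max(lev_a[[id]] + 1L,
                       if (length(pre_lev)) max(pre_lev) + 1L else 0L)
  }
  obs <- stats::setNames(net$compounds$observed, net$compounds$id)
  split_b <- stats::setNames(rep(NA_integer_, length(topo)), topo)
  # biotic primary level of a non-branching compound is lev_b; for a
  # branching one it is its split level (computed in topological order,
  # so products may still be pending: resolve by fixpoint iteration)
  prim_b <- lev_b
  for (pass in 1:2) {
    for (id in topo) {
      if (!branching_b[[id]]) next
      prods <- products_of(ed_b, id)
      prods <- prods[obs[prods]]
      cand <- purrr::map_int(prods, function(q) prim_b[[q]])
      split_b[[id]] <- max(lev_b[[id]] + 1L,
                           if (length(cand)) min(cand) else lev_b[[id]] + 1L)
      prim_b[[id]] <- split_b[[id]]
    }
  }

  total_id <- function(members, compound, phase) {
    stems <- sub("_[0-9]+$", "", members)
    if (length(unique(stems)) == 1L && all(grepl("_[0-9]+$", members))) {
      unique(stems)
    } else {
      paste0("total_", substr(phase, 1, 4), "_", compound)
    }
  }

  has_a <- purrr::map_lgl(topo, ~ nrow(out_all(ed_a, .x)) > 0L)
  has_b <- purrr::map_lgl(topo, ~ nrow(out_all(ed_b, .x)) > 0L)
  max_lev <- max(c(lev_a[has_a], lev_b[has_b], split_b[branching_b & has_b], 0L), na.rm = TRUE)
  if (!is.finite(max_lev) || max_lev == 0L) stop("network has no transformation edges", call. = FALSE)

  rows <- list()
  member_rank <- stats::setNames(integer(0), character(0))  # rank of individual resolution
  total_of <- stats::setNames(character(0), character(0))   # member -> covering total
  total_rank <- stats::setNames(integer(0), character(0))   # total -> rank of its estimate
  rank <- 0L

  for (L in seq_len(max_lev)) {
    for (ph in c("A", "B")) {
      phase_long <- if (ph == "A") "abiotic" else "biotic"
      edp <- if (ph == "A") ed_a else ed_b
      levv <- if (ph == "A") lev_a else lev_b
      branching <- if (ph == "A") branching_a else branching_b
      splitv <- if (ph == "A") {
        stats::setNames(purrr::map_int(topo, ~ lev_a[[.x]] + 1L), topo)
      } else split_b

      primary <- character(0)
      combinatorial <- list()
      split_of <- character(0)
      frozen <- stats::setNames(numeric(0), character(0))

      for (id in topo) {
        oe <- out_all(edp, id)
        if (nrow(oe) == 0L) next
        fe <- oe[is.na(oe$fixed), , drop = FALSE]
        fx <- oe[!is.na(oe$fixed), , drop = FALSE]
        if (levv[[id]] == L && nrow(fx)) {
          frozen <- c(frozen, stats::setNames(fx$fixed, fx$param_id))
          member_rank[fx$param_id] <- rank + 1L
        }
        if (nrow(fe) == 0L) next
        if (!branching[[id]]) {
          if (levv[[id]] == L) {
            primary <- c(primary, fe$param_id)
            member_rank[fe$param_id] <- rank + 1L
          }
        } else {
          tid <- total_id(fe$param_id, id, phase_long)
          if (levv[[id]] == L) {
            combinatorial <- c(combinatorial,
                               list(list(id = tid, members = fe$param_id,
                                         compound = id, phase = phase_long)))
            total_rank[tid] <- rank + 1L
            total_of[fe$param_id] <- tid
          }
          if (splitv[[id]] == L) {
            primary <- c(primary, fe$param_id)
            split_of <- c(split_of, tid)
            member_rank[fe$param_id] <- rank + 1L
          }
        }
      }

      if (!length(primary) && !length(combinatorial) && !length(frozen)) next
      rank <- rank + 1L
      rows[[length(rows) + 1L]] <- list(
        level = L, phase = ph, label = sprintf("%d(%s)", L, ph),
        primary = primary, combinatorial = combinatorial, split_of = split_of,
        frozen = frozen, rank = rank
      )
    }
  }

  # ---- data inclusion and subsidiaries per sub-level ----------------------
  # A compound is "determined" at a rank when its removal, all formation
  # edges into it, and all its precursors are resolved by that rank.
  mrank <- function(p) {
    v <- member_rank[p]
    if (is.na(v)) .Machine$integer.max else unname(v)
  }
  trank <- function(p) {
    # rank at which the removal contribution of p becomes known: its own
    # resolution, or its covering total's estimate, whichever is earlier
    v <- mrank(p)
    tid <- total_of[p]
    if (!is.na(tid)) v <- min(v, unname(total_rank[tid]))
    v
  }

  rows <- purrr::map(rows, function(row) {
    act <- if (row$phase == "A") ed_a else ed
    r <- row$rank

    determined <- stats::setNames(logical(length(topo)), topo)
    for (id in topo) {
      fin <- act[act$product == id, , drop = FALSE]
      form_ok <- all(purrr::map_int(fin$param_id, mrank) <= r) &&
        all(determined[unique(fin$source)])
      oe <- act[act$source == id, , drop = FALSE]
      removal_ok <- !nrow(oe) || max(purrr::map_int(oe$param_id, trank)) <= r
      determined[[id]] <- form_ok && removal_ok
    }
    data_compounds <- topo[determined & obs[topo]]

    # subsidiary parameters: previously resolved quantities governing the
    # determined compounds' dynamics (individual params once split, the
    # combinatorial total while the split is still pending)
    subsidiary <- character(0)
    for (id in topo[determined]) {
      oe <- act[act$source == id & is.na(act$fixed), , drop = FALSE]
      for (p in oe$param_id) {
        if (mrank(p) < r) {
          subsidiary <- c(subsidiary, p)
        } else {
          tid <- total_of[p]
          if (!is.na(tid) && total_rank[tid] < r) subsidiary <- c(subsidiary, unname(tid))
        }
      }
    }
    row$subsidiary <- setdiff(unique(subsidiary), c(row$primary, row$split_of))
    row$data_compounds <- data_compounds
    row
  })

  plan <- tibble::tibble(
    level = purrr::map_int(rows, "level"),
    phase = purrr::map_chr(rows, "phase"),
    label = purrr::map_chr(rows, "label"),
    primary = purrr::map(rows, "primary"),
    combinatorial = purrr::map(rows, "combinatorial"),
    split_of = purrr::map(rows, "split_of"),
    subsidiary = purrr::map(rows, "subsidiary"),
    frozen = purrr::map(rows, "frozen"),
    data_compounds = purrr::map(rows, "data_compounds")
  )

  # every free parameter must be resolved somewhere
  all_free <- ed$param_id[is.na(ed$fixed)]
  orphans <- setdiff(all_free, unlist(plan$primary))
  if (length(orphans)) {
    stop("orphan parameter(s) never scheduled: ", paste(orphans, collapse = ", "),
         call. = FALSE)
  }
  class(plan) <- c("pk_plan", class(plan))
  plan
}

#' @export
print.pk_plan <- function(x, ...) {
  cat(sprintf("<pk_plan> %d sub-levels over %d levels\n",
              nrow(x), max(x$level)))
  for (i in seq_len(nrow(x))) {
    comb <- purrr::map_chr(x$combinatorial[[i]], function(cb) {
      sprintf("%s{=%s}", cb$id, paste(cb$members, collapse = "+"))
    })
    cat(sprintf("  %s: primary [%s]%s%s | data: %s\n",
                x$label[i], paste(x$primary[[i]], collapse = ", "),
                if (length(comb)) paste0(" comb [", paste(comb, collapse = ", "), "]") else "",
                if (length(x$frozen[[i]])) paste0(" frozen [",
                  paste(names(x$frozen[[i]]), collapse = ", "), "]") else "",
                paste(x$data_compounds[[i]], collapse = ", ")))
  }
  invisible(x)
}
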