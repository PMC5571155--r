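#' Measurement-noise model for synthetic batch experiments
#'
#' @param kind `"proportional"` (Gaussian with sd = `sigma * value`) or
#'   `"additive"` (Gaussian with sd = `sigma` ug/L).
#' @param sigma noise level (fraction for proportional, ug/L for additive).
#' @param floor detection floor; generated values below it are reported at
#'   the floor, emulating a quantification limit.
#' @export
noise_model <- function(kind = c("proportional", "additive"), sigma = 0.05,
                        floor = 0.01) {
  kind <- match.arg(kind)
  stopifnot(sigma >= 0, floor >= 0)
  structure(list(kind = kind, sigma = sigma, floor = floor), class = "pk_noise")
}

#' Generate a synthetic batch-experiment dataset from a pathway network
#'
#' Simulates abiotic and biotic batch experiments (the biotic experiment
#' runs with both edge sets active) at the requested sampling times and
#' corrupts the observed compounds' trajectories with measurement noise.
#' The generating truth is stored alongside the data, so parameter-recovery
#' experiments can score themselves.
#'
#' @param net a [build_network()] object.
#' @param true_params named vector of generating rate constants.
#' @param times sampling times in days.
#' @param noise a [noise_model()].
#' @param seed integer seed; regeneration with the same seed is
#'   bit-identical.
#' @param phases which experiment phases to generate.
#' @return an object of class `pk_dataset`: list with `data` (tibble:
#'   `time_d`, `compound`, `phase`, `concentration_ugL`), `truth`
#'   (parameters and noise-free trajectories), `noise`, `seed`, `tss`.
#' @export
generate_dataset <- function(net, true_params, times, noise = noise_model(),
                             seed = 1L,
                             phases = c("abiotic", "biotic")) {
  stopifnot(inherits(net, "pk_network"), inherits(noise, "pk_noise"))
  check_times(times)
  phases <- match.arg(phases, several.ok = TRUE)
  set.seed(as.integer(seed))
  obs_ids <- net$compounds$id[net$compounds$observed]
  out <- list()
  clean <- list()
  for (ph in phases) {
    sim_phase <- if (ph == "abiotic") "abiotic" else "combined"
    traj <- simulate_pathway(net, true_params, times, phase = sim_phase)
    traj <- traj[traj$compound %in% obs_ids, , drop = FALSE]
    clean[[ph]] <- traj
    v <- traj$concentration_ugL
    noisy <- switch(noise$kind,
      proportional = v * (1 + stats::rnorm(length(v), 0, noise$sigma)),
      additive = v + stats::rnorm(length(v), 0, noise$sigma)
    )
    noisy <- pmax(noisy, noise$floor)
    out[[ph]] <- tibble::tibble(
      time_d = traj$time_d, compound = traj$compound, phase = ph,
      concentration_ugL = noisy
    )
  }
  data <- dplyr::bind_rows(out)
  if (mean(data$concentration_ugL <= noise$floor) > 0.5) {
    warning("more than half of the generated values sit at the detection floor",
            call. = FALSE)
  }
  structure(
    list(data = data, truth = list(params = true_params, clean = dplyr::bind_rows(clean)),
         noise = noise, seed = as.integer(seed), tss = net$tss),
    class = "pk_dataset"
  )
}

#' @export
print.pk_dataset <- function(x, ...) {
  cat(sprintf("<pk_dataset> %d points, %d compounds, phases: %s (seed %d)\n",
              nrow(x$data), length(unique(x$data$compound)),
              paste(unique(x$data$phase), collapse = "/"), x$seed))
  invisible(x)
}

#' The heroin/codeine biomarker pathway network
#'
#' The branched in-sewer transformation network of heroin (HER) and codeine
#' (COE) and their human metabolites 6-monoacetylmorphine (6MAM), morphine
#' (MOR), morphine-3-glucuronide (MORG) and norcodeine (NCOE). Abiotic
#' edges: HER -> 6MAM -> MOR -> TP, COE -> MOR and COE -> NCOE -> TP, and a
#' MORG -> MOR deconjugation edge whose abiotic rate is frozen at zero (no
#' abiotic MORG loss is observed). Biotic edges mirror the abiotic
#' topology and add two branches to unknown transformation products,
#' HER -> TP and MORG -> TP, discovered in wastewater on top of the human
#' metabolism pathway. With `branches = FALSE` those two discovery branches
#' are omitted (the human-metabolism-only structure used in
#' mis-specification experiments).
#'
#' @param branches include the two wastewater-specific branches?
#' @param tss total suspended solids, gTSS/L.
#' @return a `pk_network` with 6 observed compounds; with branches, 7
#'   abiotic and 9 biotic rate parameters.
#' @export
heroin_codeine_network <- function(branches = TRUE, tss = 0.4) {
  compounds <- tibble::tibble(
    id = c("HER", "6MAM", "MOR", "MORG", "COE", "NCOE"),
    observed = TRUE,
    c0_abiotic = c(5, 2, 8, 6, 4, 1),
    c0_biotic = c(5, 2, 8, 6, 4, 1)
  )
  edges <- tibble::tribble(
    ~source, ~product, ~phase, ~param_id, ~fixed,
    "HER",  "6MAM",   "abiotic", "k_abio_HER",    NA,
    "6MAM", "MOR",    "abiotic", "k_abio_6MAM",   NA,
    "MOR",  "TP_A",   "abiotic", "k_abio_MOR",    NA,
    "MORG", "MOR",    "abiotic", "k_abio_MORG",   0,
    "COE",  "MOR",    "abiotic", "k_abio_COE_1",  NA,
    "COE",  "NCOE",   "abiotic", "k_abio_COE_2",  NA,
    "NCOE", "TP_A",   "abiotic", "k_abio_NCOE",   NA,
    "HER",  "6MAM",   "biotic",  "k_bio_HER_1",   NA,
    "6MAM", "MOR",    "biotic",  "k_bio_6MAM",    NA,
    "MOR",  "TP_B",   "biotic",  "k_bio_MOR",     NA,
    "MORG", "MOR",    "biotic",  "k_bio_MORG_1",  NA,
    "COE",  "MOR",    "biotic",  "k_bio_COE_1",   NA,
    "COE",  "NCOE",   "biotic",  "k_bio_COE_2",   NA,
    "NCOE", "TP_B",   "biotic",  "k_bio_NCOE",    NA
  )
  if (branches) {
    edges <- dplyr::bind_rows(edges, tibble::tribble(
      ~source, ~product, ~phase, ~param_id, ~fixed,
      "HER",  "TP_B", "biotic", "k_bio_HER_2",  NA,
      "MORG", "TP_B", "biotic", "k_bio_MORG_2", NA
    ))
  }
  edges$stoich <- 1
  build_network(compounds, edges, tss = tss)
}

#' Generating rate constants of the heroin/codeine fixture
#'
#' Fixture constants chosen for well-separated timescales (fast heroin
#' hydrolysis, slow morphine turnover) so that recovery experiments are
#' informative. They are synthetic defaults, not literature estimates.
#' Units: abiotic 1/d, biotic L/gTSS/d.
#' @export
heroin_codeine_true_params <- function() {
  c(
    k_abio_HER = 2.0, k_abio_6MAM = 0.5, k_abio_MOR = 0.1,
    k_abio_COE_1 = 0.3, k_abio_COE_2 = 0.2, k_abio_NCOE = 0.15,
    k_bio_HER_1 = 3.0, k_bio_HER_2 = 2.0, k_bio_6MAM = 1.5,
    k_bio_MOR = 0.4, k_bio_MORG_1 = 0.8, k_bio_MORG_2 = 0.5,
    k_bio_COE_1 = 0.6, k_bio_COE_2 = 0.9, k_bio_NCOE = 0.3
  )
}

#' Ready-made heroin/codeine batch-experiment fixture
#'
#' Builds the full branched network and a seeded synthetic dataset
#' emulating targeted abiotic and biotic batch experiments: dense early
#' sampling (the fast heroin hydrolysis happens within hours) followed by
#' sparser points out to three days, with proportional measurement noise.
#'
#' @param seed integer seed for the noise.
#' @param noise a [noise_model()]; default 5% proportional with a
#'   0.01 ug/L detection floor.
#' @param times sampling schedule in days.
#' @return list with `network`, `dataset` and `true_params`.
#' @export
heroin_codeine_fixture <- function(seed = 1L, noise = noise_model(),
                                   times = c(0, 0.02, 0.05, 0.1, 0.2, 0.35,
                                             0.5, 0.75, 1, 1.5, 2, 3)) {
  net <- heroin_codeine_network(branches = TRUE)
  truth <- heroin_codeine_true_params()
  ds <- generate_dataset(net, truth, times, noise = noise, seed = seed)
  list(network = net, dataset = ds, true_params = truth)
}
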