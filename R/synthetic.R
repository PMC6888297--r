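## Synthetic densitometry: pseudo-immunoblot band-intensity tables with
## the statistical structure of replicated, loading-control-normalized
## western blot quantifications.

#' Readout-to-species mapping for densitometry tables
#'
#' The measured bands and their model counterparts:
#' `AMPK_T172P` (phospho-AMPK over total AMPK) maps to A;
#' `ULK1_S555P` to U; `p70S6K_P` (the canonical mTORC1 activity proxy)
#' to M; `LC3II` (over GAPDH) increases with autophagy activity and
#' `p62` decreases with it (p62 is degraded by active autophagy), both
#' mapped to G through declared monotone transforms with a floor of 0.1
#' so band intensities never reach zero.
#'
#' @return Named list: per readout, the model `species` and the
#'   `transform` applied to its level.
#' @export
densitometry_readouts <- function() {
  list(
    AMPK_T172P = list(species = "A", transform = identity),
    p70S6K_P = list(species = "M", transform = identity),
    ULK1_S555P = list(species = "U", transform = identity),
    LC3II = list(species = "G", transform = function(g) 0.1 + g),
    p62 = list(species = "G", transform = function(g) 1 * (1 - g) + 0.1)
  )
}

#' Noise model for synthetic densitometry
#'
#' Multiplicative lognormal noise, mean-corrected so that the expected
#' value of a noisy band equals its noise-free value: a draw with
#' coefficient of variation `cv` uses
#' `meanlog = -log(1 + cv^2)/2`, `sdlog = sqrt(log(1 + cv^2))`.
#' The loading-control factor is shared by all readouts of one lane
#' (one replicate at one time point), emulating division by a common
#' GAPDH band.
#'
#' @param cv per-band coefficient of variation (>= 0).
#' @param cv_loading loading-control coefficient of variation (>= 0).
#' @param n replicates per time point (>= 1; default 3, matching
#'   triplicate blots).
#' @return Named list of class `ampk_noise`.
#' @export
noise_model <- function(cv = 0.1, cv_loading = 0.05, n = 3) {
  stopifnot(cv >= 0, cv_loading >= 0, n >= 1)
  structure(list(cv = cv, cv_loading = cv_loading, n = as.integer(n)),
            class = "ampk_noise")
}

.rlnorm_mc <- function(k, cv) {
  if (cv == 0) return(rep(1, k))
  s2 <- log(1 + cv^2)
  stats::rlnorm(k, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Generate a synthetic densitometry table from a trajectory
#'
#' Samples the trajectory at the requested time points, applies the
#' readout transforms of [densitometry_readouts()], and multiplies each
#' band by mean-corrected lognormal noise plus a per-lane
#' loading-control factor.
#'
#' @param traj `ampk_trajectory`.
#' @param noise [noise_model()].
#' @param timepoints sampling times (min), within the trajectory span;
#'   default `c(0, 30, 60, 90, 120)`, the usual blot schedule.
#' @param seed RNG seed (reproducible tables).
#' @return Data frame with columns `time_min`, `readout`, `replicate`,
#'   `value` (all intensities > 0).
#' @export
generate_densitometry <- function(traj, noise = noise_model(),
                                  timepoints = c(0, 30, 60, 90, 120),
                                  seed = 1L) {
  if (any(timepoints < min(traj$times) - 1e-9) ||
      any(timepoints > max(traj$times) + 1e-9)) {
    stop("timepoints outside the trajectory span")
  }
  rd <- densitometry_readouts()
  idx <- vapply(timepoints, function(t) which.min(abs(traj$times - t)), 0L)
  withr::with_seed(seed, {
    rows <- list()
    for (ti in seq_along(timepoints)) {
      for (r in seq_len(noise$n)) {
        lane <- .rlnorm_mc(1, noise$cv_loading)
        for (nm in names(rd)) {
          level <- traj$states[idx[ti], rd[[nm]]$species]
          clean <- rd[[nm]]$transform(level)
          rows[[length(rows) + 1L]] <- data.frame(
            time_min = timepoints[ti], readout = nm, replicate = r,
            value = clean * .rlnorm_mc(1, noise$cv) * lane)
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Standard synthetic fixture tables
#'
#' Three densitometry tables mirroring the time-course experiments:
#' rapamycin alone, ULK1 silencing followed by rapamycin, and Compound C
#' pre-treatment followed by rapamycin (sampling shifted to cover the
#' 150-min staged protocol). Ten-percent band noise, triplicates.
#'
#' @param seed RNG seed.
#' @param params,variant model configuration.
#' @param noise noise model for all three tables.
#' @return Named list of three data frames
#'   (`rapamycin`, `si_ulk1_rapamycin`, `compound_c_rapamycin`).
#' @export
fixture_suite <- function(seed = 1L, params = default_parameters(),
                          variant = extended_variant(),
                          noise = noise_model(cv = 0.1)) {
  init <- physiological_state(params, variant)
  make <- function(treatments, pre, duration, timepoints, sub_seed) {
    proto <- standard_protocol(treatments, pre, duration = duration)
    traj <- integrate_protocol(proto, params, variant, initial_state = init)
    generate_densitometry(traj, noise, timepoints, seed = sub_seed)
  }
  list(
    rapamycin = make("rapamycin", character(), 120,
                     c(0, 30, 60, 90, 120), seed),
    si_ulk1_rapamycin = make(c("si_ulk1", "rapamycin"), character(), 120,
                             c(0, 30, 60, 90, 120), seed + 1L),
    compound_c_rapamycin = make("rapamycin", "compound_c", 150,
                                c(0, 30, 60, 90, 120) + 30, seed + 2L)
  )
}

#' Read / write densitometry tables
#'
#' @param table data frame with the densitometry columns.
#' @param path CSV path.
#' @return `read_densitometry` returns the data frame.
#' @export
write_densitometry <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_densitometry
#' @export
read_densitometry <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_min", "readout", "replicate", "value")
  if (!all(need %in% names(df))) {
    stop("densitometry table must have columns: ", paste(need, collapse = ", "))
  }
  df
}
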