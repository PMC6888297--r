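## Qualitative phenotype calls, the mutant-scenario matrix, variant
## comparison and event-ordering analysis.
##
## Immunoblot readouts in this system are reported as band intensities
## judged significantly changed or not, so trajectory classification uses
## a declared convention: a readout is HIGH when its final level is at
## least theta_high; TRANSIENT when it was induced (rose through
## theta_high from below) but ended at or below theta_low; LOW when it
## ended at or below theta_low without ever being induced (e.g. mTOR
## shut off by rapamycin from its high resting level), or never reached
## theta_high at all. Anything else - chiefly a final level strictly
## between the thresholds after an induction - is AMBIGUOUS and matched
## only by wildcards. Thresholds are absolute levels on the one-unit
## scale of the untreated totals (defaults: 0.5 and 0.25), so a silenced
## species whose total was reduced is judged on the same scale as its
## untreated counterpart.

#' Classification thresholds
#' @param high HIGH/peak threshold (active level, one-unit scale).
#' @param low final-level threshold below which a peaked readout is
#'   called TRANSIENT.
#' @return named list.
#' @export
phenotype_thresholds <- function(high = 0.5, low = 0.25) {
  stopifnot(high > low, low > 0)
  list(high = high, low = low)
}

#' Classify a trajectory into qualitative calls
#'
#' @param traj `ampk_trajectory` covering the full protocol duration.
#' @param thresholds from [phenotype_thresholds()].
#' @return A list of class `ampk_call`: per readout (A, M, U, G) the
#'   level (`"LOW"`, `"HIGH"`, `"TRANSIENT"` or `"AMBIGUOUS"`), peak
#'   value, peak time, and final value.
#' @export
classify_trajectory <- function(traj, thresholds = phenotype_thresholds()) {
  stopifnot(inherits(traj, "ampk_trajectory"))
  if (max(traj$times) < traj$protocol$duration - 1e-9) {
    stop("trajectory shorter than its protocol duration")
  }
  th <- thresholds
  out <- lapply(c("A", "M", "U", "G"), function(sp) {
    x <- traj$states[, sp]
    i <- which.max(x)
    peak <- x[i]
    fin <- x[length(x)]
    # induced = rose through theta_high from below at some point
    first_below <- which(x < th$high)[1]
    induced <- !is.na(first_below) &&
      any(x[first_below:length(x)] >= th$high)
    level <- if (fin >= th$high) "HIGH"
    else if (induced && fin <= th$low) "TRANSIENT"
    else if ((!induced && fin <= th$low) || peak < th$high) "LOW"
    else "AMBIGUOUS"
    list(level = level, peak = peak, peak_time = traj$times[i], final = fin)
  })
  names(out) <- c("A", "M", "U", "G")
  structure(out, class = "ampk_call")
}

#' First-crossing times of activation/deactivation events
#'
#' Returns, per readout, the first time the level rises through the HIGH
#' threshold (`rise`) and the first time it falls through the LOW
#' threshold from above (`fall`), linearly interpolated between output
#' grid points; `NA` when the crossing never occurs.
#'
#' @param traj `ampk_trajectory`.
#' @param thresholds from [phenotype_thresholds()].
#' @return Data frame with columns `species`, `rise`, `fall`.
#' @export
event_ordering <- function(traj, thresholds = phenotype_thresholds()) {
  th <- thresholds
  cross <- function(x, t, level, up) {
    above <- if (up) x >= level else x <= level
    if (above[1]) return(0)
    i <- which(above)[1]
    if (is.na(i)) return(NA_real_)
    # interpolate within [i-1, i]
    x0 <- x[i - 1]; x1 <- x[i]
    t[i - 1] + (level - x0) / (x1 - x0) * (t[i] - t[i - 1])
  }
  sp <- c("A", "M", "U", "G")
  data.frame(
    species = sp,
    rise = vapply(sp, function(s) cross(traj$states[, s], traj$times,
                                        th$high, TRUE), 0),
    fall = vapply(sp, function(s) cross(traj$states[, s], traj$times,
                                        th$low, FALSE), 0),
    row.names = NULL)
}

.scenario <- function(id, treatments, pre = character(), duration = 120,
                      expect, provenance = "observed") {
  list(id = id, treatments = treatments, pre = pre, duration = duration,
       expect = expect, provenance = provenance)
}

#' The mutant-phenotype scenario suite
#'
#' Sixteen perturbation scenarios covering every treatment and
#' combination discussed for this network: single treatments, siRNA
#' silencing, hyper-activation, and staged combinations. Expectations
#' are qualitative calls per readout; a readout may admit a set of
#' acceptable calls (e.g. TSC1/2 silencing plus rapamycin shows strong
#' AMPK phosphorylation that may or may not have relaxed by the end of
#' the window, with some autophagy activity), and `"*"` is a wildcard.
#'
#' Durations follow the corresponding experiments: 120 min for acute
#' drug treatments and chronic silencing readouts, 150 min when a 30-min
#' Compound C pre-treatment precedes rapamycin, 360 min for starvation
#' (6 h carbohydrate-free medium) and resveratrol.
#'
#' @return List of scenario specifications (id, treatments, pre,
#'   duration, expected pattern, provenance tag).
#' @export
scenario_suite <- function() {
  H <- "HIGH"; L <- "LOW"; Tr <- "TRANSIENT"; any_ <- "*"
  list(
    .scenario("control", character(), duration = 120,
              expect = list(A = L, M = H, U = L, G = L)),
    .scenario("starvation", "starvation", duration = 360,
              expect = list(A = Tr, M = L, U = H, G = H)),
    .scenario("rapamycin", "rapamycin", duration = 120,
              expect = list(A = Tr, M = L, U = H, G = H)),
    .scenario("resveratrol", "resveratrol", duration = 360,
              expect = list(A = Tr, M = L, U = H, G = H)),
    .scenario("compound_c", "compound_c", duration = 120,
              expect = list(A = L, M = H, U = L, G = L)),
    .scenario("si_ulk1", "si_ulk1", duration = 120,
              expect = list(A = L, M = H, U = L, G = L)),
    .scenario("si_ulk1_rapamycin", c("si_ulk1", "rapamycin"), duration = 120,
              expect = list(A = H, M = L, U = L, G = L)),
    .scenario("si_ulk1_starvation", c("si_ulk1", "starvation"), duration = 360,
              expect = list(A = H, M = L, U = L, G = L),
              provenance = "predicted"),
    .scenario("si_ulk1_resveratrol", c("si_ulk1", "resveratrol"),
              duration = 360,
              expect = list(A = H, M = L, U = L, G = L),
              provenance = "predicted"),
    .scenario("si_tsc12", "si_tsc12", duration = 120,
              expect = list(A = L, M = H, U = L, G = L)),
    .scenario("si_tsc12_rapamycin", c("si_tsc12", "rapamycin"),
              duration = 120,
              expect = list(A = c(H, Tr), M = L, U = any_, G = c(H, Tr))),
    .scenario("si_tsc12_starvation", c("si_tsc12", "starvation"),
              duration = 360,
              expect = list(A = L, M = H, U = L, G = L),
              provenance = "predicted"),
    .scenario("si_tsc12_resveratrol", c("si_tsc12", "resveratrol"),
              duration = 360,
              expect = list(A = L, M = H, U = L, G = L),
              provenance = "predicted"),
    .scenario("compound_c_rapamycin", "rapamycin", pre = "compound_c",
              duration = 150,
              expect = list(A = L, M = L, U = L, G = L)),
    .scenario("ampk_hyper", "ampk_hyper", duration = 120,
              expect = list(A = H, M = L, U = H, G = H)),
    .scenario("mtor_hyper", "mtor_hyper", duration = 120,
              expect = list(A = L, M = H, U = L, G = L))
  )
}

.scenario_protocol <- function(sc, library = treatment_library()) {
  standard_protocol(sc$treatments, sc$pre, duration = sc$duration,
                    library = library)
}

.call_matches <- function(call, expect) {
  mism <- character()
  for (sp in names(expect)) {
    exp_sp <- expect[[sp]]
    if (identical(exp_sp, "*")) next
    if (!(call[[sp]]$level %in% exp_sp)) {
      mism <- c(mism, sprintf("%s: expected %s, got %s", sp,
                              paste(exp_sp, collapse = "|"),
                              call[[sp]]$level))
    }
  }
  mism
}

#' Evaluate the phenotype matrix
#'
#' Simulates every scenario of the suite from the physiological steady
#' state, classifies the trajectories, and diffs each call against the
#' scenario expectation. A scenario whose simulation fails is counted as
#' a mismatch.
#'
#' @param suite from [scenario_suite()].
#' @param params,variant model configuration.
#' @param thresholds classification thresholds.
#' @param initial_state optional explicit initial state (used for variant
#'   comparisons that must share a starting point); default is the
#'   physiological steady state of `(params, variant)`.
#' @return `ampk_matrix_report`: list with per-scenario results
#'   (`id`, `matched`, `mismatches`, `call`) and `n_matched`, `n_total`.
#' @export
evaluate_matrix <- function(suite = scenario_suite(),
                            params = default_parameters(),
                            variant = extended_variant(),
                            thresholds = phenotype_thresholds(),
                            initial_state = NULL) {
  stopifnot(length(suite) > 0)
  library <- treatment_library(params)
  init <- if (is.null(initial_state)) {
    physiological_state(params, variant)
  } else initial_state
  results <- lapply(suite, function(sc) {
    res <- tryCatch({
      traj <- integrate_protocol(.scenario_protocol(sc, library), params,
                                 variant, initial_state = init)
      call <- classify_trajectory(traj, thresholds)
      mism <- .call_matches(call, sc$expect)
      list(id = sc$id, matched = length(mism) == 0L, mismatches = mism,
           call = call, error = NULL)
    }, error = function(e) {
      list(id = sc$id, matched = FALSE,
           mismatches = paste("simulation failed:", conditionMessage(e)),
           call = NULL, error = conditionMessage(e))
    })
    res
  })
  structure(list(results = results,
                 n_matched = sum(vapply(results, `[[`, TRUE, "matched")),
                 n_total = length(results),
                 variant = variant),
            class = "ampk_matrix_report")
}

#' @export
print.ampk_matrix_report <- function(x, ...) {
  cat(sprintf("phenotype matrix: %d / %d scenarios matched (%s model)\n",
              x$n_matched, x$n_total,
              if (x$variant$mtor_inhibits_ampk) "extended" else "template"))
  for (r in x$results) {
    status <- if (r$matched) "ok " else "MISMATCH"
    cat(sprintf("  %-24s %s", r$id, status))
    if (!r$matched) cat("  [", paste(r$mismatches, collapse = "; "), "]")
    cat("\n")
  }
  invisible(x)
}

#' Tabulate a matrix report
#'
#' @param report from [evaluate_matrix()].
#' @param path optional CSV path.
#' @return Data frame with one row per scenario: id, per-readout call,
#'   matched flag and mismatch text.
#' @export
matrix_report_table <- function(report, path = NULL) {
  rows <- lapply(report$results, function(r) {
    lv <- function(sp) if (is.null(r$call)) NA_character_ else r$call[[sp]]$level
    data.frame(id = r$id, A = lv("A"), M = lv("M"), U = lv("U"), G = lv("G"),
               matched = r$matched,
               mismatches = paste(r$mismatches, collapse = "; "))
  })
  df <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Compare the extended and template variants on one scenario
#'
#' Runs the same protocol under both variants from a shared initial
#' condition (the physiological steady state of the extended model,
#' i.e. the biological resting state) and reports final levels, calls,
#' and the final AMPK-P difference (template minus extended).
#'
#' @param scenario_id id within [scenario_suite()].
#' @param params parameter set.
#' @param thresholds classification thresholds.
#' @return List with `extended`, `template` (final state + call) and
#'   `delta_A_final`.
#' @export
compare_variants <- function(scenario_id, params = default_parameters(),
                             thresholds = phenotype_thresholds()) {
  suite <- scenario_suite()
  ids <- vapply(suite, `[[`, "", "id")
  sc <- suite[[match(scenario_id, ids)]]
  if (is.null(sc)) stop("unknown scenario id: ", scenario_id)
  init <- physiological_state(params, extended_variant())
  proto <- .scenario_protocol(sc, treatment_library(params))
  run <- function(variant) {
    traj <- integrate_protocol(proto, params, variant, initial_state = init)
    list(final = traj$states[nrow(traj$states), ],
         call = classify_trajectory(traj, thresholds),
         trajectory = traj)
  }
  ext <- run(extended_variant())
  tem <- run(template_variant())
  list(extended = ext, template = tem,
       delta_A_final = unname(tem$final["A"] - ext$final["A"]))
}
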