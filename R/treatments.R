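## Treatments (timed parameter overrides) and protocols.
##
## Every experimental manipulation is encoded as a set of parameter
## overrides: rapamycin sequesters mTORC1 (total mTOR -> 0.01), Compound C
## reduces the AMPK activation rate constant to 5% of its value,
## starvation and resveratrol raise the stress input S, siRNA silencing
## reduces a total protein level, TSC1/2 silencing doubles the mTOR
## activation rate constant to 0.05.

# calibrated starvation/resveratrol stress intensity (dimensionless S);
# sits between the switching thresholds at kamtor = 0.025 and 0.05
.s_starve_default <- 2.5

#' Define a treatment
#'
#' @param name identifier.
#' @param overrides named list of parameter values (replace mode) or
#'   multipliers (multiply mode); names must be schema fields.
#' @param mode "replace" or "multiply".
#' @return A list of class `ampk_treatment`.
#' @export
treatment <- function(name, overrides, mode = c("replace", "multiply")) {
  mode <- match.arg(mode)
  bad <- setdiff(names(overrides), .param_fields)
  if (length(bad)) {
    stop("treatment '", name, "' references unknown field(s): ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, overrides = lapply(overrides, as.numeric),
                 mode = mode),
            class = "ampk_treatment")
}

#' Library of named treatments
#'
#' The in-silico counterparts of the wet-lab manipulations:
#' \describe{
#'   \item{si_ulk1}{ULK1 silencing: total ULK1 -> 0.001.}
#'   \item{si_tsc12}{TSC1/2 silencing (mTOR hyper-activation):
#'     kamtor -> 0.05.}
#'   \item{mtor_hyper}{mTOR hyper-activation expressed as a 2-fold
#'     kamtor increase (equivalent to si_tsc12 at default kamtor).}
#'   \item{rapamycin}{mTORC1 inhibition: total mTOR -> 0.01.}
#'   \item{starvation}{carbohydrate-free medium: stress input S raised
#'     to the calibrated starvation level.}
#'   \item{resveratrol}{AMPK activator, same mechanism as starvation.}
#'   \item{compound_c}{AMPK inhibitor (dorsomorphin): kaA scaled by 0.05.}
#'   \item{ampk_hyper}{strong AMPK hyper-activation: S -> 12.}
#' }
#' The starvation/resveratrol magnitude (`s_starve`) is a calibrated
#' treatment intensity: strong enough to flip the physiological switch at
#' baseline kamtor, not strong enough to defeat hyper-activated mTOR.
#'
#' @param params parameter set used to resolve relative magnitudes.
#' @return Named list of `ampk_treatment` objects.
#' @export
treatment_library <- function(params = default_parameters()) {
  s_starve <- .s_starve_default
  list(
    si_ulk1 = treatment("si_ulk1", list(UT = 0.001)),
    si_tsc12 = treatment("si_tsc12", list(kamtor = 0.05)),
    mtor_hyper = treatment("mtor_hyper", list(kamtor = 2), mode = "multiply"),
    rapamycin = treatment("rapamycin", list(MT = 0.01)),
    starvation = treatment("starvation", list(S = s_starve)),
    resveratrol = treatment("resveratrol", list(S = s_starve)),
    compound_c = treatment("compound_c", list(kaA = 0.05), mode = "multiply"),
    ampk_hyper = treatment("ampk_hyper", list(S = 12))
  )
}

#' Apply treatments to a parameter set
#'
#' Returns a new parameter set; the input is not modified. Within one
#' application, replace-mode overrides win over multiply-mode overrides
#' of the same field (reported via a warning); two different replace
#' values for the same field are an error.
#'
#' @param params parameter list.
#' @param treatments list of `ampk_treatment` objects (possibly empty).
#' @return New `ampk_parameters` list.
#' @export
apply_treatments <- function(params, treatments) {
  if (length(treatments) == 0L) return(params)
  out <- params
  repl <- list()
  mult <- list()
  for (tr in treatments) {
    stopifnot(inherits(tr, "ampk_treatment"))
    for (f in names(tr$overrides)) {
      v <- tr$overrides[[f]]
      if (tr$mode == "replace") {
        if (!is.null(repl[[f]]) && repl[[f]] != v) {
          stop("conflicting replace values for '", f, "': ",
               repl[[f]], " vs ", v)
        }
        repl[[f]] <- v
      } else {
        mult[[f]] <- if (is.null(mult[[f]])) v else mult[[f]] * v
      }
    }
  }
  clash <- intersect(names(repl), names(mult))
  if (length(clash)) {
    warning("replace-mode override wins over multiply-mode for: ",
            paste(clash, collapse = ", "))
    mult[clash] <- NULL
  }
  for (f in names(mult)) out[[f]] <- out[[f]] * mult[[f]]
  for (f in names(repl)) out[[f]] <- repl[[f]]
  stop_if_invalid(out)
  out
}

#' Build a staged treatment protocol
#'
#' A protocol is pure data: an ordered list of stages, each an onset time
#' (min) with the treatments switched on from that time onward, plus a
#' total duration. Stage onsets are strictly increasing and the first
#' stage is at time 0. The default initial condition policy starts from
#' the physiological steady state of the untreated parameters.
#'
#' @param treatments character vector of library treatment names for the
#'   main stage.
#' @param pre_treatments names applied from time 0 (pre-treatment stage);
#'   when present, the main treatments start at `onset` minutes.
#' @param duration total simulated time (min).
#' @param onset onset of the main stage when a pre-treatment exists
#'   (default 30 min, the Compound-C pre-incubation time).
#' @param library treatment library to resolve names against.
#' @return A list of class `ampk_protocol` with elements `stages`
#'   (list of `list(onset, treatments)`), `duration`, and
#'   `initial_condition` (`"physiological"`).
#' @export
standard_protocol <- function(treatments = character(),
                              pre_treatments = character(),
                              duration = 120,
                              onset = 30,
                              library = treatment_library()) {
  resolve <- function(nms) {
    bad <- setdiff(nms, names(library))
    if (length(bad)) stop("unknown treatment name(s): ",
                          paste(bad, collapse = ", "))
    library[nms]
  }
  main <- resolve(treatments)
  pre <- resolve(pre_treatments)
  stages <- if (length(pre) == 0L) {
    list(list(onset = 0, treatments = main))
  } else {
    list(list(onset = 0, treatments = pre),
         list(onset = onset, treatments = c(pre, main)))
  }
  if (duration <= max(vapply(stages, `[[`, 0, "onset"))) {
    stop("duration must exceed the last stage onset")
  }
  structure(list(stages = stages, duration = duration,
                 initial_condition = "physiological"),
            class = "ampk_protocol")
}

#' Serialize / load a protocol
#'
#' Protocols round-trip through JSON without loss, so a reloaded protocol
#' reproduces identical simulations.
#'
#' @param protocol `ampk_protocol`.
#' @param path file path.
#' @return `read_protocol` returns the protocol; `write_protocol` the
#'   path, invisibly.
#' @export
write_protocol <- function(protocol, path) {
  ser <- list(
    duration = protocol$duration,
    initial_condition = protocol$initial_condition,
    stages = lapply(protocol$stages, function(st) {
      list(onset = st$onset,
           treatments = lapply(unname(st$treatments), function(tr) {
             list(name = tr$name, mode = tr$mode, overrides = tr$overrides)
           }))
    }))
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_protocol
#' @export
read_protocol <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = FALSE)
  stages <- lapply(ser$stages, function(st) {
    trs <- lapply(st$treatments, function(tr) {
      treatment(tr$name, tr$overrides, tr$mode)
    })
    names(trs) <- vapply(trs, `[[`, "", "name")
    list(onset = as.numeric(st$onset), treatments = trs)
  })
  structure(list(stages = stages, duration = as.numeric(ser$duration),
                 initial_condition = ser$initial_condition),
            class = "ampk_protocol")
}
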