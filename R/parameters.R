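## Parameter set and network-variant definitions for the
## AMPK-mTORC1-ULK1-ATG regulatory model.

# canonical field order; also the schema used by validators and IO
.param_fields <- c(
  "kaA", "S", "kiA", "kiAU", "kiAM",
  "kamtor", "kiM", "kiMA", "kiMU",
  "kaUA", "kiU", "kiUM",
  "kaGU", "kaG0", "kiG", "kiGM",
  "JaA", "JiA", "JaM", "JiM", "JaU", "JiU", "JaG", "JiG",
  "AT", "MT", "UT", "GT")

.rate_fields <- c("kaA", "kiA", "kiAU", "kiAM", "kamtor", "kiM", "kiMA",
                  "kiMU", "kaUA", "kiU", "kiUM", "kaGU", "kaG0", "kiG",
                  "kiGM")
.mm_fields <- c("JaA", "JiA", "JaM", "JiM", "JaU", "JiU", "JaG", "JiG")
.total_fields <- c("AT", "MT", "UT", "GT")

#' Default model parameters
#'
#' Returns the shipped, calibrated parameter set for the four-variable
#' AMPK-mTORC1-ULK1-ATG model. All rate constants (`k*`) are first-order
#' coefficients in 1/min; Michaelis constants (`J*`) and total protein
#' levels (`AT`, `MT`, `UT`, `GT`) are dimensionless. The stress input `S`
#' multiplies the AMPK activation rate (`S = 1` is the physiological,
#' nutrient-rich condition).
#'
#' Two values are structural rather than calibrated: the mTOR activation
#' rate constant `kamtor = 0.025` (half the hyper-activated value 0.05
#' used to emulate TSC1/2 silencing, which is defined as a 2-fold
#' increase), and the totals, which are one unit each. Basal
#' (AMPK-independent) ULK1 activation is structurally zero: the ULK1
#' activation flux is proportional to active AMPK. All remaining values
#' were produced by the calibration module (see
#' \code{\link{calibrate_parameters}} and the shipped configuration file
#' `inst/extdata/default_parameters.yaml`) so that the physiological
#' steady state has mTOR active and AMPK/ULK1/ATG inactive, the full
#' phenotype matrix is reproduced, and a bistable window exists in the
#' stress input.
#'
#' @return A named list of class `ampk_parameters` with the fields
#'   documented in \code{\link{validate_parameters}}.
#' @seealso [model_rhs()], [validate_parameters()], [treatment_library()]
#' @export
#' @examples
#' p <- default_parameters()
#' p$kamtor   # 0.025
default_parameters <- function() {
  path <- system.file("extdata", "default_parameters.yaml",
                      package = "ampkswitch")
  read_parameters(path)
}

#' Construct a parameter set
#'
#' Builds an `ampk_parameters` object from named values, checking the
#' schema. Fields not supplied default to the shipped calibrated values.
#'
#' @param ... named parameter overrides (must match schema fields).
#' @param base parameter list to start from (default: shipped defaults).
#' @return `ampk_parameters` list.
#' @export
model_parameters <- function(..., base = default_parameters()) {
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), .param_fields)
    if (length(bad)) {
      stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
    }
    base[names(over)] <- over
  }
  structure(base[.param_fields], class = "ampk_parameters")
}

#' Network variant switches
#'
#' The extended model includes the mTOR-mediated inactivation of AMPK
#' (the double-negative mTOR/AMPK feedback); the template model is the
#' same network without that edge. Individual edges of the core wiring
#' can additionally be switched off for ablation studies:
#' \describe{
#'   \item{a}{AMPK activates ULK1 (`kaUA`)}
#'   \item{b}{ULK1 inactivates AMPK (`kiAU`)}
#'   \item{c}{mTOR inactivates ULK1 (`kiUM`)}
#'   \item{d}{ULK1 inactivates mTOR (`kiMU`)}
#'   \item{e}{AMPK inactivates mTOR (`kiMA`)}
#'   \item{f}{mTOR inactivates ATG (`kiGM`)}
#'   \item{g}{ULK1 activates ATG (`kaGU`)}
#' }
#'
#' @param mtor_inhibits_ampk logical; include the mTOR -| AMPK edge
#'   (TRUE gives the extended model, FALSE the template network).
#' @param edges named logical vector over `c("a","b","c","d","e","f","g")`;
#'   all TRUE by default.
#' @return A list of class `ampk_variant`.
#' @export
model_variant <- function(mtor_inhibits_ampk = TRUE,
                          edges = c(a = TRUE, b = TRUE, c = TRUE, d = TRUE,
                                    e = TRUE, f = TRUE, g = TRUE)) {
  full <- c(a = TRUE, b = TRUE, c = TRUE, d = TRUE, e = TRUE, f = TRUE,
            g = TRUE)
  if (!is.null(names(edges))) {
    bad <- setdiff(names(edges), names(full))
    if (length(bad)) stop("unknown edge label(s): ", paste(bad, collapse = ", "))
    full[names(edges)] <- edges
  } else if (length(edges) == 7L) {
    full[] <- edges
  } else {
    stop("'edges' must be named or of length 7")
  }
  structure(list(mtor_inhibits_ampk = isTRUE(mtor_inhibits_ampk),
                 edges = full),
            class = "ampk_variant")
}

#' @rdname model_variant
#' @export
extended_variant <- function() model_variant(TRUE)

#' @rdname model_variant
#' @export
template_variant <- function() model_variant(FALSE)

#' Validate a parameter set
#'
#' Checks the type invariants: every field present and numeric, rate
#' constants non-negative, Michaelis constants strictly positive, totals
#' non-negative. Violations are returned, not thrown, so callers can
#' report all problems at once.
#'
#' @param params parameter list.
#' @return Character vector of violation messages (empty if valid); each
#'   message names the offending field.
#' @export
validate_parameters <- function(params) {
  v <- character()
  missing <- setdiff(.param_fields, names(params))
  if (length(missing)) {
    return(paste0("missing field: ", missing))
  }
  for (f in .param_fields) {
    x <- params[[f]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
      v <- c(v, paste0(f, ": must be a finite numeric scalar"))
    }
  }
  if (length(v)) return(v)
  for (f in c(.rate_fields, "S")) {
    if (params[[f]] < 0) v <- c(v, paste0(f, ": rate must be >= 0"))
  }
  for (f in .mm_fields) {
    if (params[[f]] <= 0) v <- c(v, paste0(f, ": Michaelis constant must be > 0"))
  }
  for (f in .total_fields) {
    if (params[[f]] < 0) v <- c(v, paste0(f, ": total must be >= 0"))
  }
  v
}

stop_if_invalid <- function(params) {
  v <- validate_parameters(params)
  if (length(v)) {
    stop("invalid parameters:\n  ", paste(v, collapse = "\n  "), call. = FALSE)
  }
  invisible(params)
}

totals <- function(params) {
  c(A = params$AT, M = params$MT, U = params$UT, G = params$GT)
}

#' Read / write parameter configurations
#'
#' Parameters serialize to YAML with exactly the schema field names.
#' Unknown keys are an error so that typos cannot silently revert a value
#' to its default. A `provenance` block (free-form metadata such as the
#' calibration seed) is permitted and preserved as an attribute.
#'
#' @param path file path.
#' @param params parameter list to write.
#' @param provenance optional named list written alongside the parameters.
#' @return `read_parameters` returns an `ampk_parameters` list;
#'   `write_parameters` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  raw <- yaml::read_yaml(path)
  prov <- raw[["provenance"]]
  raw[["provenance"]] <- NULL
  bad <- setdiff(names(raw), .param_fields)
  if (length(bad)) {
    stop("unknown key(s) in parameter file: ", paste(bad, collapse = ", "))
  }
  missing <- setdiff(.param_fields, names(raw))
  if (length(missing)) {
    stop("parameter file lacks field(s): ", paste(missing, collapse = ", "))
  }
  p <- structure(lapply(raw[.param_fields], as.numeric),
                 class = "ampk_parameters")
  names(p) <- .param_fields
  stop_if_invalid(p)
  attr(p, "provenance") <- prov
  p
}

#' @rdname read_parameters
#' @export
write_parameters <- function(params, path, provenance = NULL) {
  stop_if_invalid(params)
  out <- lapply(unclass(params)[.param_fields], as.numeric)
  if (!is.null(provenance)) out$provenance <- provenance
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.ampk_parameters <- function(x, ...) {
  cat("AMPK-mTORC1-ULK1 model parameters (rates in 1/min)\n")
  m <- matrix(unlist(x[.param_fields]), nrow = 1,
              dimnames = list("", .param_fields))
  print(signif(m, 4))
  invisible(x)
}
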