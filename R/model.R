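## Right-hand side of the four-variable ODE system.
##
## Each species is a covalent modification (Goldbeter-Koshland) cycle:
## activation and inactivation are Michaelis-Menten fluxes acting on the
## inactive and active pools respectively, with conservation implicit
## (inactive pool = total - active level). Activating edges add to the
## activation rate, inhibitory edges add to the inactivation rate.

#' Time derivatives of the model
#'
#' Computes dA/dt, dM/dt, dU/dt, dG/dt (1/min) for active AMPK-P (`A`),
#' active mTORC1 (`M`), ULK1-Ser555-P (`U`) and the autophagy activator
#' ATG (`G`):
#' \deqn{dA/dt = kaA S (AT-A)/(JaA+AT-A) - (kiA + kiAU U + w\, kiAM M) A/(JiA+A)}
#' \deqn{dM/dt = kamtor (MT-M)/(JaM+MT-M) - (kiM + kiMA A + kiMU U) M/(JiM+M)}
#' \deqn{dU/dt = kaUA A (UT-U)/(JaU+UT-U) - (kiU + kiUM M) U/(JiU+U)}
#' \deqn{dG/dt = (kaG0 + kaGU U)(GT-G)/(JaG+GT-G) - (kiG + kiGM M) G/(JiG+G)}
#' where `w = 1` in the extended variant (mTOR -| AMPK edge present) and
#' `w = 0` in the template network. ULK1 has no basal activation term:
#' its activation strictly requires AMPK. `kaG0` is the small residual
#' autophagy drive present even under physiological conditions.
#'
#' @param state named numeric vector or list with entries `A`, `M`, `U`,
#'   `G`, each within `[0, total]` for its species.
#' @param params parameter list (see [default_parameters()]).
#' @param variant [model_variant()] switch set.
#' @param check validate inputs (disable in inner loops).
#' @return Named numeric vector `c(A=, M=, U=, G=)` of derivatives.
#' @export
#' @examples
#' model_rhs(c(A = 0, M = 0.99, U = 0, G = 0), default_parameters())
model_rhs <- function(state, params, variant = extended_variant(),
                      check = TRUE) {
  s <- unlist(state[c("A", "M", "U", "G")])
  if (check) {
    stop_if_invalid(params)
    tot <- totals(params)
    if (any(s < -1e-9) || any(s - tot > 1e-9)) {
      stop("state outside [0, total]: ",
           paste(names(s)[s < -1e-9 | s - tot > 1e-9], collapse = ", "))
    }
  }
  e <- variant$edges
  w <- as.numeric(variant$mtor_inhibits_ampk)
  A <- s[["A"]]; M <- s[["M"]]; U <- s[["U"]]; G <- s[["G"]]
  p <- params
  dA <- p$kaA * p$S * (p$AT - A) / (p$JaA + p$AT - A) -
    (p$kiA + e[["b"]] * p$kiAU * U + w * p$kiAM * M) * A / (p$JiA + A)
  dM <- p$kamtor * (p$MT - M) / (p$JaM + p$MT - M) -
    (p$kiM + e[["e"]] * p$kiMA * A + e[["d"]] * p$kiMU * U) * M / (p$JiM + M)
  dU <- e[["a"]] * p$kaUA * A * (p$UT - U) / (p$JaU + p$UT - U) -
    (p$kiU + e[["c"]] * p$kiUM * M) * U / (p$JiU + U)
  dG <- (p$kaG0 + e[["g"]] * p$kaGU * U) * (p$GT - G) / (p$JaG + p$GT - G) -
    (p$kiG + e[["f"]] * p$kiGM * M) * G / (p$JiG + G)
  c(A = dA, M = dM, U = dU, G = dG)
}

#' Jacobian of the model by central finite differences
#'
#' @param state,params,variant as in [model_rhs()].
#' @param h finite-difference step.
#' @return 4x4 numeric matrix.
#' @export
model_jacobian <- function(state, params, variant = extended_variant(),
                           h = 1e-6) {
  s <- unlist(state[c("A", "M", "U", "G")])
  J <- matrix(0, 4, 4, dimnames = list(c("A", "M", "U", "G"),
                                       c("A", "M", "U", "G")))
  for (j in 1:4) {
    up <- s; up[j] <- s[j] + h
    dn <- s; dn[j] <- s[j] - h
    J[, j] <- (model_rhs(up, params, variant, check = FALSE) -
                 model_rhs(dn, params, variant, check = FALSE)) / (2 * h)
  }
  J
}
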