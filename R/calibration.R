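## Calibration of the default parameter set against qualitative
## constraints, and least-squares fitting to densitometry time courses.

#' Score a parameter set against the qualitative constraint battery
#'
#' The score is the weighted count of violated constraints plus margin
#' shortfalls (distance of the offending level from the threshold it had
#' to clear, so a near-miss scores less than a gross violation). The
#' constraints are:
#' \itemize{
#'   \item every scenario in the supplied suite matches its expected
#'     pattern (weight 1 each plus shortfall);
#'   \item the extended model at `S = 1` has exactly one stable steady
#'     state, with M above `0.5 MT` and A below `0.1 AT`;
#'   \item the template model, started from the extended model's
#'     physiological state, ends siULK1 and mTOR-hyper scenarios with
#'     AMPK-P HIGH (the edge-necessity contrast);
#'   \item a bistable window exists in the stress input S (forward and
#'     backward quasi-static sweeps select different branches somewhere).
#' }
#'
#' @param params candidate parameter set.
#' @param suite scenario suite (default [scenario_suite()]).
#' @param thresholds classification thresholds.
#' @param check_bistable include the hysteresis-window constraint
#'   (the most expensive check).
#' @return List with `score` (0 = all constraints satisfied),
#'   `violations` (character), and `matrix_report`.
#' @export
calibration_score <- function(params, suite = scenario_suite(),
                              thresholds = phenotype_thresholds(),
                              check_bistable = TRUE) {
  viol <- character()
  score <- 0
  shortfall <- function(x, target, above) {
    if (above) max(0, target - x) / target else max(0, x - target) / target
  }
  ## physiological steady state structure
  ss <- tryCatch(steady_states(params, extended_variant(), n_starts = 30),
                 error = function(e) NULL)
  if (is.null(ss)) {
    return(list(score = Inf, violations = "steady-state search failed",
                matrix_report = NULL))
  }
  stable <- Filter(function(s) s$stable, ss$states)
  if (length(stable) != 1L) {
    score <- score + length(stable)
    viol <- c(viol, sprintf("S=1: %d stable states (want exactly 1)",
                            length(stable)))
  }
  if (length(stable) >= 1L) {
    st <- stable[[which.max(vapply(stable, function(s) s$state[["M"]], 0))]]
    if (st$state[["M"]] < 0.5 * params$MT) {
      score <- score + 1 + shortfall(st$state[["M"]], 0.5 * params$MT, TRUE)
      viol <- c(viol, "S=1: physiological M below 0.5")
    }
    if (st$state[["A"]] > 0.1 * params$AT) {
      score <- score + 1 + shortfall(st$state[["A"]], 0.1 * params$AT, FALSE)
      viol <- c(viol, "S=1: physiological A above 0.1")
    }
  }
  ## phenotype matrix
  rep <- tryCatch(evaluate_matrix(suite, params, extended_variant(),
                                  thresholds),
                  error = function(e) NULL)
  if (is.null(rep)) {
    return(list(score = Inf, violations = c(viol, "matrix evaluation failed"),
                matrix_report = NULL))
  }
  for (r in rep$results) {
    if (!r$matched) {
      pen <- 1
      if (!is.null(r$call)) {
        sc <- suite[[match(r$id, vapply(suite, `[[`, "", "id"))]]
        for (sp in names(sc$expect)) {
          exp_sp <- sc$expect[[sp]]
          if (identical(exp_sp, "*") || r$call[[sp]]$level %in% exp_sp) next
          want_high <- "HIGH" %in% exp_sp
          lev <- r$call[[sp]]$final
          pen <- pen + if (want_high) shortfall(lev, thresholds$high, TRUE)
          else shortfall(lev, thresholds$low, FALSE)
        }
      }
      score <- score + pen
      viol <- c(viol, sprintf("%s: %s", r$id,
                              paste(r$mismatches, collapse = "; ")))
    }
  }
  ## template-variant contrasts
  for (id in c("si_ulk1", "mtor_hyper")) {
    cv <- tryCatch(compare_variants(id, params, thresholds),
                   error = function(e) NULL)
    if (is.null(cv)) {
      score <- score + 2
      viol <- c(viol, paste0(id, ": variant comparison failed"))
      next
    }
    if (cv$template$final[["A"]] < thresholds$high) {
      score <- score + 1 + shortfall(cv$template$final[["A"]],
                                     thresholds$high, TRUE)
      viol <- c(viol, paste0(id, ": template final A not HIGH"))
    }
    if (cv$extended$final[["A"]] > thresholds$low) {
      score <- score + 1 + shortfall(cv$extended$final[["A"]],
                                     thresholds$low, FALSE)
      viol <- c(viol, paste0(id, ": extended final A not LOW"))
    }
  }
  ## bistable window in S
  if (check_bistable) {
    hy <- tryCatch(
      hysteresis_scan("S", c(0.5, 6), n_points = 23, params = params),
      error = function(e) NULL)
    if (is.null(hy)) {
      score <- score + 2
      viol <- c(viol, "hysteresis scan failed")
    } else {
      fw <- hy[hy$direction == "forward", ]
      bw <- hy[hy$direction == "backward", ]
      dis <- abs(fw$A - bw$A) > 0.2
      if (!any(dis)) {
        score <- score + 1
        viol <- c(viol, "no bistable window in S over [0.5, 6]")
      }
    }
  }
  list(score = score, violations = viol, matrix_report = rep)
}

#' Calibrate free parameters against the qualitative constraints
#'
#' Latin-hypercube screening over log-uniform ranges for the free rate
#' and Michaelis constants, followed by coordinate-wise local refinement
#' (multiplicative steps on each free parameter, accepted when the score
#' improves). `kamtor`, the totals, and the structurally-zero basal ULK1
#' activation are never searched. The accepted score sequence is
#' monotone non-increasing by construction.
#'
#' @param start starting parameter set (a reasonable seed speeds
#'   convergence; screening explores around and beyond it).
#' @param free names of parameters to search; defaults to every rate and
#'   Michaelis constant except the fixed ones.
#' @param lower,upper named bounds; defaults: log-uniform
#'   `[1e-4, 1]` for rate constants and `[1e-3, 1]` for Michaelis
#'   constants.
#' @param seed RNG seed.
#' @param budget maximum number of score evaluations.
#' @param suite,thresholds as in [calibration_score()].
#' @return List with `params` (best found), `score`, `violations`,
#'   `trace` (accepted scores), `evaluations`, `seed`.
#' @export
calibrate_parameters <- function(start = default_parameters(),
                                 free = NULL,
                                 lower = NULL, upper = NULL,
                                 seed = 1L, budget = 200,
                                 suite = scenario_suite(),
                                 thresholds = phenotype_thresholds()) {
  fixed <- c("kamtor", "S", .total_fields)
  if (is.null(free)) free <- setdiff(c(.rate_fields, .mm_fields), fixed)
  bad <- setdiff(free, .param_fields)
  if (length(bad)) stop("unknown free parameter(s): ", paste(bad, collapse = ", "))
  if (any(free %in% fixed)) stop("cannot search fixed parameter(s): ",
                                 paste(intersect(free, fixed), collapse = ", "))
  lo <- stats::setNames(ifelse(free %in% .mm_fields, 1e-3, 1e-4), free)
  hi <- stats::setNames(rep(1, length(free)), free)
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper

  evals <- 0L
  eval_score <- function(p) {
    evals <<- evals + 1L
    calibration_score(p, suite, thresholds)$score
  }
  best_p <- start
  best_s <- eval_score(start)
  trace <- best_s
  if (best_s > 0 && budget > evals) {
    ## LHS screening around the seed (log-scale jitter within bounds)
    n_screen <- min(max(budget %/% 4, 5), budget - evals)
    if (length(free) > 0 && n_screen > 0) {
      X <- withr::with_seed(seed, lhs::randomLHS(n_screen, length(free)))
      for (i in seq_len(n_screen)) {
        p <- best_p
        for (j in seq_along(free)) {
          f <- free[j]
          p[[f]] <- exp(log(lo[f]) + X[i, j] * (log(hi[f]) - log(lo[f])))
        }
        s <- eval_score(p)
        if (s < best_s) { best_s <- s; best_p <- p; trace <- c(trace, s) }
        if (best_s == 0 || evals >= budget) break
      }
    }
    ## coordinate-wise multiplicative refinement
    steps <- c(0.5, 0.8, 1.25, 2)
    repeat {
      improved <- FALSE
      for (f in free) {
        for (st in steps) {
          if (evals >= budget || best_s == 0) break
          p <- best_p
          p[[f]] <- min(max(p[[f]] * st, lo[f]), hi[f])
          if (p[[f]] == best_p[[f]]) next
          s <- eval_score(p)
          if (s < best_s) {
            best_s <- s; best_p <- p; trace <- c(trace, s); improved <- TRUE
          }
        }
      }
      if (!improved || evals >= budget || best_s == 0) break
    }
  }
  final <- calibration_score(best_p, suite, thresholds)
  list(params = best_p, score = final$score, violations = final$violations,
       trace = trace, evaluations = evals, seed = seed)
}

#' Fit parameters to a densitometry time course
#'
#' Least-squares fit of selected model parameters to a (synthetic)
#' densitometry table on the normalized band-intensity scale, using
#' multi-start Levenberg-Marquardt on log-transformed parameters.
#' Readouts are mapped to model species via [densitometry_readouts()];
#' replicates at a time point are compared individually (equivalent to
#' weighting by replicate count). At most 3 simultaneous free parameters
#' are recommended; more triggers an identifiability warning.
#'
#' @param table densitometry data frame (columns `time_min`, `readout`,
#'   `replicate`, `value`) as produced by [generate_densitometry()].
#' @param protocol protocol under which the data were generated.
#' @param free character vector of parameter names to fit.
#' @param params base parameter set (fixed values + starting point).
#' @param variant model variant.
#' @param lower,upper named multiplicative bounds relative to the start
#'   (defaults: x1/50 and x50).
#' @param n_starts random multi-starts (log-uniform within bounds).
#' @param seed RNG seed.
#' @param truth optional named vector of true values for reporting
#'   relative errors.
#' @return `ampk_fit`: list with `estimates`, `loss`, `relative_error`
#'   (if truth given), `converged`, `n_starts`, `seed`.
#' @export
fit_time_course <- function(table, protocol, free,
                            params = default_parameters(),
                            variant = extended_variant(),
                            lower = NULL, upper = NULL,
                            n_starts = 5, seed = 1L, truth = NULL) {
  stopifnot(all(c("time_min", "readout", "replicate", "value") %in%
                  names(table)))
  bad <- setdiff(free, .param_fields)
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  if (length(free) > 3) {
    warning("fitting more than 3 parameters simultaneously; ",
            "identifiability is not assured")
  }
  tps <- sort(unique(table$time_min))
  if (max(tps) > protocol$duration + 1e-9) {
    stop("table time points exceed the protocol duration")
  }
  rd <- densitometry_readouts()
  tab <- table[table$readout %in% names(rd), ]
  init <- physiological_state(params, variant)

  predict_values <- function(p) {
    traj <- integrate_protocol(protocol, p, variant, initial_state = init)
    idx <- vapply(tab$time_min, function(t) which.min(abs(traj$times - t)), 0L)
    vapply(seq_len(nrow(tab)), function(i) {
      map <- rd[[tab$readout[i]]]
      map$transform(traj$states[idx[i], map$species])
    }, 0)
  }
  resid_fn <- function(logtheta) {
    p <- params
    for (j in seq_along(free)) p[[free[j]]] <- exp(logtheta[j])
    pred <- tryCatch(predict_values(p), error = function(e) NULL)
    if (is.null(pred)) return(rep(1e3, nrow(tab)))
    pred - tab$value
  }

  if (length(free) == 0L) {
    loss <- sum(resid_fn(numeric(0))^2)
    return(structure(list(estimates = stats::setNames(numeric(0), free),
                          loss = loss, converged = TRUE,
                          relative_error = NULL, n_starts = 0, seed = seed),
                     class = "ampk_fit"))
  }
  start0 <- log(unlist(params[free]))
  lo <- start0 + log(1 / 50); hi <- start0 + log(50)
  if (!is.null(lower)) lo[names(lower)] <- log(unlist(params[names(lower)]) *
                                                 unlist(lower))
  if (!is.null(upper)) hi[names(upper)] <- log(unlist(params[names(upper)]) *
                                                 unlist(upper))
  starts <- if (n_starts <= 1L) {
    rbind(start0)
  } else {
    withr::with_seed(seed, {
      rbind(start0,
            matrix(stats::runif((n_starts - 1) * length(free)),
                   ncol = length(free)) %*% diag(hi - lo, length(free)) +
              matrix(lo, n_starts - 1, length(free), byrow = TRUE))
    })
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fn,
                         lower = lo, upper = hi,
                         control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
    if (is.null(fit)) next
    loss <- sum(fit$fvec^2)
    if (is.null(best) || loss < best$loss) {
      best <- list(par = fit$par, loss = loss, info = fit$info)
    }
  }
  if (is.null(best)) stop("optimizer failed from every start")
  est <- stats::setNames(exp(best$par), free)
  rel <- NULL
  if (!is.null(truth)) {
    rel <- abs(est[names(truth)] - truth) / truth
  }
  structure(list(estimates = est, loss = best$loss,
                 relative_error = rel,
                 converged = best$info %in% 1:4,
                 n_starts = n_starts, seed = seed),
            class = "ampk_fit")
}
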