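## Protocol integration and steady-state location.

.rhs_desolve <- function(t, y, parms) {
  list(model_rhs(y, parms$params, parms$variant, check = FALSE))
}

#' Integrate a treatment protocol
#'
#' Integrates the model through the stages of a protocol with a
#' stiff-capable solver (`deSolve::lsoda`, relative tolerance 1e-8,
#' absolute 1e-10, output every minute). Parameters jump at stage
#' onsets; the state is continuous across stages except that levels are
#' clamped into `[0, total]` at each onset (a silencing treatment that
#' lowers a total caps the corresponding active level).
#'
#' The default initial condition is the physiological steady state of the
#' untreated parameter set under the same variant: the stable steady
#' state at the given `S` with the highest mTOR activity (ties broken by
#' largest M, then smallest A). `initial_state` overrides it.
#'
#' @param protocol `ampk_protocol` from [standard_protocol()].
#' @param params untreated parameter set.
#' @param variant model variant.
#' @param initial_state optional named state vector used instead of the
#'   physiological steady state.
#' @param dt output grid spacing (min).
#' @param rtol,atol solver tolerances.
#' @return An `ampk_trajectory`: list with `times`, `states` (matrix with
#'   columns A, M, U, G), `protocol`, and `diagnostics`.
#' @export
integrate_protocol <- function(protocol, params = default_parameters(),
                               variant = extended_variant(),
                               initial_state = NULL,
                               dt = 1, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(protocol, "ampk_protocol"))
  stop_if_invalid(params)
  y <- if (is.null(initial_state)) {
    physiological_state(params, variant)
  } else {
    unlist(initial_state[c("A", "M", "U", "G")])
  }
  onsets <- vapply(protocol$stages, `[[`, 0, "onset")
  if (onsets[1] != 0) stop("first stage must start at time 0")
  if (is.unsorted(onsets, strictly = TRUE)) {
    stop("stage onsets must be strictly increasing")
  }
  bounds <- c(onsets, protocol$duration)
  times <- NULL
  states <- NULL
  nsteps <- 0L
  for (i in seq_along(protocol$stages)) {
    p_i <- apply_treatments(params, protocol$stages[[i]]$treatments)
    tot <- totals(p_i)
    y <- pmin(pmax(y, 0), tot)   # clamp at stage onset
    tt <- unique(c(seq(bounds[i], bounds[i + 1], by = dt), bounds[i + 1]))
    out <- .integrate_raw(y, tt, p_i, variant, rtol = rtol, atol = atol)
    nsteps <- nsteps + attr(out, "istate")[3]
    seg <- as.matrix(out[, 2:5, drop = FALSE])
    keep <- if (is.null(times)) seq_len(nrow(seg)) else 2:nrow(seg)
    times <- c(times, out[keep, 1])
    states <- rbind(states, seg[keep, , drop = FALSE])
    y <- seg[nrow(seg), ]
    low <- pmin(y, 0); high <- pmax(y - tot, 0)
    if (any(abs(low) > 1e-6) || any(high > 1e-6)) {
      stop("trajectory left [0, total] beyond tolerance at stage ", i)
    }
  }
  structure(list(times = times, states = states, protocol = protocol,
                 params = params, variant = variant,
                 diagnostics = list(rtol = rtol, atol = atol, dt = dt,
                                    steps = unname(nsteps))),
            class = "ampk_trajectory")
}

#' Physiological steady state
#'
#' The stable steady state with the highest active mTOR level at the
#' given parameters (tie-break: largest M, then smallest A). Errors when
#' no stable steady state exists.
#'
#' @param params,variant model configuration.
#' @param n_starts,seed multi-start budget passed to [steady_states()].
#' @return Named state vector.
#' @export
physiological_state <- function(params, variant = extended_variant(),
                                n_starts = 40, seed = 1L) {
  ss <- steady_states(params, variant, n_starts = n_starts, seed = seed)
  stable <- Filter(function(s) s$stable, ss$states)
  if (length(stable) == 0L) {
    stop("no stable physiological steady state found")
  }
  Ms <- vapply(stable, function(s) s$state[["M"]], 0)
  As <- vapply(stable, function(s) s$state[["A"]], 0)
  ord <- order(-Ms, As)
  stable[[ord[1]]]$state
}

## finite-difference Jacobian on the numeric parameter vector
.jac_num <- function(y, pv, h = 1e-6) {
  J <- matrix(0, 4, 4)
  for (j in 1:4) {
    up <- y; up[j] <- y[j] + h
    dn <- y; dn[j] <- y[j] - h
    J[, j] <- (.rhs_num(up, pv) - .rhs_num(dn, pv)) / (2 * h)
  }
  J
}

## damped Newton iteration on the RHS with finite-difference Jacobian
.newton_root <- function(y0, params, variant, tol = 1e-12, maxit = 60) {
  pv <- .parm_vector(params, variant)
  tot <- totals(params)
  y <- pmin(pmax(unname(unlist(y0)), 0), tot)
  for (it in seq_len(maxit)) {
    f <- .rhs_num(y, pv)
    if (max(abs(f)) < tol) break
    J <- .jac_num(y, pv)
    step <- tryCatch(solve(J, -f), error = function(e) NULL)
    if (is.null(step)) return(list(root = stats::setNames(y, names(tot)),
                                   converged = FALSE))
    lam <- 1
    f0 <- sum(f^2)
    repeat {
      yn <- pmin(pmax(y + lam * step, 0), tot)
      if (sum(.rhs_num(yn, pv)^2) < f0 || lam < 1e-6) break
      lam <- lam / 2
    }
    if (max(abs(yn - y)) < 1e-15) break
    y <- yn
  }
  list(root = stats::setNames(y, c("A", "M", "U", "G")),
       converged = max(abs(.rhs_num(y, pv))) < 1e-9)
}

#' Locate steady states by multi-start root finding
#'
#' Runs a damped Newton iteration from Latin-hypercube starting points in
#' the state box (plus the box corners and forward-integration endpoints)
#' and de-duplicates converged roots. Each root is classified by the sign
#' pattern of the eigenvalue real parts of the finite-difference
#' Jacobian: stable (all < -1e-8), unstable (any > 1e-8), or marginal.
#'
#' With all rate constants equal to zero every point is a fixed point;
#' this degenerate case is detected and reported instead of returning an
#' arbitrary root list.
#'
#' @param params,variant model configuration.
#' @param n_starts number of random starting points (>= 1).
#' @param seed integer seed making the multi-start reproducible.
#' @param merge_tol roots closer than this (max-norm) are merged.
#' @return List with `states` (list of `list(state, stable, eigenvalues)`)
#'   and `degenerate` flag.
#' @export
steady_states <- function(params, variant = extended_variant(),
                          n_starts = 40, seed = 1L, merge_tol = 1e-5) {
  stop_if_invalid(params)
  stopifnot(n_starts >= 1)
  if (all(unlist(params[.rate_fields]) == 0)) {
    return(list(states = list(), degenerate = TRUE))
  }
  tot <- totals(params)
  starts <- withr::with_seed(seed, lhs::randomLHS(n_starts, 4))
  starts <- sweep(starts, 2, tot, `*`)
  corners <- rbind(c(0, 0, 0, 0), tot,
                   c(0, tot[2], 0, 0), c(tot[1], 0, tot[3], tot[4]))
  starts <- rbind(starts, corners)
  colnames(starts) <- c("A", "M", "U", "G")
  # endpoints of forward integration from a few starts make good seeds
  for (i in c(1L, 2L)) {
    traj <- .integrate_raw(starts[i, ], c(0, 2000, 4000), params, variant)
    starts <- rbind(starts, traj[nrow(traj), 2:5])
  }
  roots <- list()
  for (i in seq_len(nrow(starts))) {
    res <- .newton_root(starts[i, ], params, variant)
    if (!res$converged) next
    dup <- any(vapply(roots, function(r) max(abs(r - res$root)) < merge_tol,
                      TRUE))
    if (!dup) roots[[length(roots) + 1L]] <- res$root
  }
  if (length(roots) == 0L) {
    stop("steady-state search did not converge from any start")
  }
  states <- lapply(roots, function(r) {
    ev <- eigen(model_jacobian(r, params, variant), only.values = TRUE)$values
    re <- Re(ev)
    list(state = r,
         stable = all(re < -1e-8),
         unstable = any(re > 1e-8),
         eigenvalues = ev)
  })
  list(states = states, degenerate = FALSE)
}

#' Export a trajectory as a tidy data frame / CSV
#'
#' @param traj `ampk_trajectory`.
#' @param path optional CSV path; when given the table is also written.
#' @return Data frame with columns `time_min`, `species`, `level`.
#' @export
trajectory_table <- function(traj, path = NULL) {
  df <- data.frame(
    time_min = rep(traj$times, times = 4),
    species = rep(c("A", "M", "U", "G"), each = length(traj$times)),
    level = c(traj$states[, "A"], traj$states[, "M"],
              traj$states[, "U"], traj$states[, "G"]))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
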