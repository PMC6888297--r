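## One-parameter steady-state scans, hysteresis/bistability detection,
## and the AMPK-mTOR phase-plane reduction with nullclines.

#' One-parameter steady-state scan
#'
#' Tracks all steady states across a grid of values of one parameter.
#' Continuation is brute-force: at each grid value the multi-start root
#' finder is re-run, seeded with the roots found at the neighbouring
#' value plus fresh Latin-hypercube starts, which is adequate for a
#' four-dimensional system at this scale. Bistable sub-intervals (two or
#' more stable states) are reported as grid brackets of the fold points,
#' not refined to machine precision.
#'
#' @param param_name parameter to scan (must be a schema field).
#' @param range length-2 numeric, lower < upper.
#' @param n_points number of grid values (>= 3).
#' @param params,variant base model configuration.
#' @param n_starts fresh multi-starts per grid value.
#' @param seed reproducibility seed.
#' @return `ampk_bifurcation`: list with `param`, `values`, `states`
#'   (per value, list of steady states with stability), and
#'   `bistable_intervals` (data frame of fold brackets).
#' @export
scan_parameter <- function(param_name, range, n_points = 60,
                           params = default_parameters(),
                           variant = extended_variant(),
                           n_starts = 25, seed = 1L) {
  if (!param_name %in% .param_fields) stop("unknown parameter: ", param_name)
  if (length(range) != 2 || range[1] >= range[2]) {
    stop("range must be increasing (lower < upper)")
  }
  stopifnot(n_points >= 3)
  values <- seq(range[1], range[2], length.out = n_points)
  per_value <- vector("list", n_points)
  seed_neighbours <- function(found, p_i, seeds) {
    for (r in seeds) {
      res <- .newton_root(r, p_i, variant)
      if (!res$converged) {
        # a vanished root: relax onto the attractor and polish there
        tr <- .integrate_raw(res$root, c(0, 3000, 6000), p_i, variant)
        res <- .newton_root(tr[nrow(tr), 2:5], p_i, variant)
      }
      if (res$converged) {
        dup <- any(vapply(found, function(s)
          max(abs(s$state - res$root)) < 1e-5, TRUE))
        if (!dup) {
          ev <- eigen(model_jacobian(res$root, p_i, variant),
                      only.values = TRUE)$values
          found[[length(found) + 1L]] <-
            list(state = res$root, stable = all(Re(ev) < -1e-8),
                 unstable = any(Re(ev) > 1e-8), eigenvalues = ev)
        }
      }
    }
    found
  }
  prev_roots <- NULL
  for (i in seq_len(n_points)) {
    p_i <- params
    p_i[[param_name]] <- values[i]
    ss <- tryCatch(
      steady_states(p_i, variant, n_starts = n_starts, seed = seed + i),
      error = function(e) NULL)
    found <- if (is.null(ss)) list() else ss$states
    found <- seed_neighbours(found, p_i, prev_roots)
    per_value[[i]] <- found
    prev_roots <- lapply(found, `[[`, "state")
  }
  # backward seeding pass: branches entered from above the fold
  prev_roots <- NULL
  for (i in rev(seq_len(n_points))) {
    p_i <- params
    p_i[[param_name]] <- values[i]
    per_value[[i]] <- seed_neighbours(per_value[[i]], p_i, prev_roots)
    prev_roots <- lapply(per_value[[i]], `[[`, "state")
  }
  n_stable <- vapply(per_value, function(st)
    sum(vapply(st, `[[`, TRUE, "stable")), 0L)
  bist <- n_stable >= 2L
  intervals <- NULL
  if (any(bist)) {
    r <- rle(bist)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- which(r$values)
    intervals <- data.frame(
      lower_bracket_lo = values[pmax(starts[keep] - 1L, 1L)],
      lower_bracket_hi = values[starts[keep]],
      upper_bracket_lo = values[ends[keep]],
      upper_bracket_hi = values[pmin(ends[keep] + 1L, n_points)])
  }
  structure(list(param = param_name, values = values, states = per_value,
                 n_stable = n_stable, bistable_intervals = intervals,
                 params = params, variant = variant),
            class = "ampk_bifurcation")
}

#' Forward/backward hysteresis scan
#'
#' Slowly steps a parameter up and then down, integrating to the
#' attractor at each value from the previous endpoint. Branch selection
#' disagreeing between directions delimits the hysteresis window of the
#' bistable toggle.
#'
#' @param param_name,range,n_points,params,variant as [scan_parameter()].
#' @param t_settle integration time per step (min).
#' @return Data frame: value, direction, final A/M/U/G.
#' @export
hysteresis_scan <- function(param_name, range, n_points = 40,
                            params = default_parameters(),
                            variant = extended_variant(),
                            t_settle = 6000) {
  values <- seq(range[1], range[2], length.out = n_points)
  run_dir <- function(vals, y0) {
    y <- y0
    out <- matrix(NA_real_, length(vals), 4,
                  dimnames = list(NULL, c("A", "M", "U", "G")))
    for (i in seq_along(vals)) {
      p_i <- params
      p_i[[param_name]] <- vals[i]
      y <- pmin(pmax(y, 0), totals(p_i))
      tr <- .integrate_raw(y, c(0, t_settle / 2, t_settle), p_i, variant)
      y <- tr[nrow(tr), 2:5]
      out[i, ] <- y
    }
    out
  }
  p_lo <- params; p_lo[[param_name]] <- values[1]
  y_lo <- physiological_state(p_lo, variant)
  fw <- run_dir(values, y_lo)
  bw <- run_dir(rev(values), fw[n_points, ])[n_points:1, , drop = FALSE]
  rbind(
    data.frame(value = values, direction = "forward", fw),
    data.frame(value = values, direction = "backward", bw))
}

## quasi-steady-state levels of U and G for given (A, M).
## dU/dt = 0 and dG/dt = 0 are each monotone in their own variable,
## so the roots are unique and bracketed in [0, total].
.qss_ug <- function(A, M, params, variant) {
  e <- variant$edges
  p <- params
  fu <- function(U) {
    e[["a"]] * p$kaUA * A * (p$UT - U) / (p$JaU + p$UT - U) -
      (p$kiU + e[["c"]] * p$kiUM * M) * U / (p$JiU + U)
  }
  U <- if (fu(p$UT) >= 0) p$UT else if (fu(0) <= 0) 0 else
    stats::uniroot(fu, c(0, p$UT), tol = 1e-12)$root
  fg <- function(G) {
    (p$kaG0 + e[["g"]] * p$kaGU * U) * (p$GT - G) / (p$JaG + p$GT - G) -
      (p$kiG + e[["f"]] * p$kiGM * M) * G / (p$JiG + G)
  }
  G <- if (fg(p$GT) >= 0) p$GT else if (fg(0) <= 0) 0 else
    stats::uniroot(fg, c(0, p$GT), tol = 1e-12)$root
  c(U = U, G = G)
}

.reduced_rhs <- function(A, M, params, variant) {
  ug <- .qss_ug(A, M, params, variant)
  f <- model_rhs(c(A = A, M = M, U = ug[["U"]], G = ug[["G"]]),
                 params, variant, check = FALSE)
  f[c("A", "M")]
}

#' AMPK-mTOR nullclines in the reduced phase plane
#'
#' Treats ULK1 and ATG as fast variables at quasi-steady state for given
#' (A, M) — a visualization device; quantitative claims use the full
#' 4-variable system — and samples the dA/dt = 0 and dM/dt = 0 curves on
#' a grid. Intersections are refined by 2-D Newton polishing on the
#' reduced system and each is checked against the full system's steady
#' states. A crude time-scale ratio (slowest U/G relaxation rate over
#' fastest A/M rate at the intersections) is reported so the validity of
#' the reduction can be judged.
#'
#' @param params,variant model configuration.
#' @param n_grid grid resolution per axis.
#' @return `ampk_nullclines`: list with `A_nullcline`, `M_nullcline`
#'   (data frames of curve points), `intersections` (data frame with
#'   stability of the corresponding full-system state), and
#'   `qss_timescale_ratio`.
#' @export
nullclines <- function(params = default_parameters(),
                       variant = extended_variant(), n_grid = 120) {
  p <- params
  As <- seq(1e-4, p$AT - 1e-4, length.out = n_grid)
  Ms <- seq(1e-4, p$MT - 1e-4, length.out = n_grid)
  # evaluate the reduced field once on the grid, then trace the zero
  # contours of dA/dt and dM/dt (robust to axis-parallel curves)
  zA <- matrix(NA_real_, n_grid, n_grid)
  zM <- matrix(NA_real_, n_grid, n_grid)
  for (i in seq_len(n_grid)) {
    for (j in seq_len(n_grid)) {
      f <- tryCatch(.reduced_rhs(As[i], Ms[j], p, variant),
                    error = function(e) c(A = NA_real_, M = NA_real_))
      zA[i, j] <- f[["A"]]
      zM[i, j] <- f[["M"]]
    }
  }
  contour_pts <- function(z) {
    cl <- grDevices::contourLines(As, Ms, z, levels = 0)
    if (length(cl) == 0L) {
      return(data.frame(A = numeric(), M = numeric()))
    }
    do.call(rbind, lapply(cl, function(cc) data.frame(A = cc$x, M = cc$y)))
  }
  a_null <- contour_pts(zA)
  m_null <- contour_pts(zM)
  # intersections: polish from near-coincident points of the two curves
  # (checked from both curves; a steep branch can be sparsely sampled on
  # one of them) and from the (A, M) projections of the full system's
  # steady states
  cand <- NULL
  h <- 4 * max(diff(As)[1], diff(Ms)[1])
  if (nrow(a_null) && nrow(m_null)) {
    for (i in seq_len(nrow(a_null))) {
      d <- sqrt((m_null$A - a_null$A[i])^2 + (m_null$M - a_null$M[i])^2)
      if (min(d) < h) cand <- rbind(cand, as.numeric(a_null[i, ]))
    }
    for (i in seq_len(nrow(m_null))) {
      d <- sqrt((a_null$A - m_null$A[i])^2 + (a_null$M - m_null$M[i])^2)
      if (min(d) < h) cand <- rbind(cand, as.numeric(m_null[i, ]))
    }
  }
  full_ss <- tryCatch(steady_states(p, variant, n_starts = 20),
                      error = function(e) NULL)
  if (!is.null(full_ss)) {
    for (s in full_ss$states) {
      cand <- rbind(cand, c(s$state[["A"]], s$state[["M"]]))
    }
  }
  inters <- list()
  if (!is.null(cand)) {
    for (i in seq_len(nrow(cand))) {
      xy <- cand[i, ]
      for (it in 1:50) {
        f <- .reduced_rhs(xy[1], xy[2], p, variant)
        if (max(abs(f)) < 1e-12) break
        h <- 1e-6
        J <- matrix(0, 2, 2)
        J[, 1] <- (.reduced_rhs(xy[1] + h, xy[2], p, variant) -
                     .reduced_rhs(xy[1] - h, xy[2], p, variant)) / (2 * h)
        J[, 2] <- (.reduced_rhs(xy[1], xy[2] + h, p, variant) -
                     .reduced_rhs(xy[1], xy[2] - h, p, variant)) / (2 * h)
        step <- tryCatch(solve(J, -f), error = function(e) c(0, 0))
        xy <- pmin(pmax(xy + step, 1e-8), c(p$AT - 1e-8, p$MT - 1e-8))
        if (max(abs(step)) < 1e-13) break
      }
      dup <- any(vapply(inters, function(z) max(abs(z$AM - xy)) < 1e-4, TRUE))
      if (!dup && max(abs(.reduced_rhs(xy[1], xy[2], p, variant))) < 1e-9) {
        ug <- .qss_ug(xy[1], xy[2], p, variant)
        full <- c(A = unname(xy[1]), M = unname(xy[2]), ug)
        ev <- eigen(model_jacobian(full, p, variant), only.values = TRUE)$values
        inters[[length(inters) + 1L]] <-
          list(AM = xy, state = full, stable = all(Re(ev) < -1e-8))
      }
    }
  }
  ratio <- NA_real_
  if (length(inters)) {
    rats <- vapply(inters, function(z) {
      J <- model_jacobian(z$state, p, variant)
      slow_ug <- min(abs(Re(diag(J)[c("U", "G")])))
      fast_am <- max(abs(Re(diag(J)[c("A", "M")])))
      slow_ug / fast_am
    }, 0)
    ratio <- min(rats)
  }
  structure(list(
    A_nullcline = a_null, M_nullcline = m_null,
    intersections = if (length(inters)) data.frame(
      A = vapply(inters, function(z) z$AM[1], 0),
      M = vapply(inters, function(z) z$AM[2], 0),
      U = vapply(inters, function(z) z$state[["U"]], 0),
      G = vapply(inters, function(z) z$state[["G"]], 0),
      stable = vapply(inters, `[[`, TRUE, "stable"))
    else data.frame(A = numeric(), M = numeric(), U = numeric(),
                    G = numeric(), stable = logical()),
    qss_timescale_ratio = ratio),
    class = "ampk_nullclines")
}

#' Export a bifurcation diagram as a tidy table / CSV
#'
#' @param diagram from [scan_parameter()].
#' @param path optional CSV path.
#' @return Data frame: param_value, A, M, U, G, stable.
#' @export
bifurcation_table <- function(diagram, path = NULL) {
  rows <- list()
  for (i in seq_along(diagram$values)) {
    for (s in diagram$states[[i]]) {
      rows[[length(rows) + 1L]] <- data.frame(
        param_value = diagram$values[i],
        A = s$state[["A"]], M = s$state[["M"]],
        U = s$state[["U"]], G = s$state[["G"]],
        stable = s$stable)
    }
  }
  df <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Plot the S-shaped bifurcation branches
#'
#' @param diagram from [scan_parameter()].
#' @param species which level to plot on the y axis.
#' @export
plot_bifurcation <- function(diagram, species = "A") {
  df <- bifurcation_table(diagram)
  graphics::plot(df$param_value, df[[species]],
                 pch = ifelse(df$stable, 16, 1),
                 col = ifelse(df$stable, "black", "grey50"),
                 xlab = diagram$param,
                 ylab = paste("steady-state", species))
  graphics::legend("topleft", pch = c(16, 1), col = c("black", "grey50"),
                   legend = c("stable", "unstable"), bty = "n")
  invisible(df)
}
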