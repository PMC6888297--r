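test_that("the stress-input scan reports a bistable window", {
  sc <- scan_parameter("S", c(0.5, 3), n_points = 26, params = defaults,
                       n_starts = 15, seed = 5)
  expect_false(is.null(sc$bistable_intervals))
  expect_gt(nrow(sc$bistable_intervals), 0)
  # inside a reported interval: at least two stable states coexist
  expect_true(any(sc$n_stable >= 2))
  # monostable at both ends of the scanned range
  expect_equal(sc$n_stable[1], 1L)
  expect_equal(sc$n_stable[length(sc$n_stable)], 1L)
})

test_that("cutting both mutual-inhibition arms leaves a monostable system", {
  p <- defaults
  p$kiAM <- 0
  p$kiMA <- 0
  sc <- scan_parameter("S", c(0.5, 3), n_points = 11, params = p,
                       n_starts = 15, seed = 7)
  expect_true(all(sc$n_stable == 1L))
  expect_null(sc$bistable_intervals)
})

test_that("scan input contracts are enforced", {
  expect_error(scan_parameter("nope", c(0, 1)), "unknown parameter")
  expect_error(scan_parameter("S", c(2, 2)), "increasing")
  expect_error(scan_parameter("S", c(1, 2), n_points = 2), "n_points")
})

test_that("diagram states re-verify as rhs roots after a disk round-trip", {
  sc <- scan_parameter("S", c(1.4, 2.0), n_points = 4, params = defaults,
                       n_starts = 12, seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  bifurcation_table(sc, path)
  df <- utils::read.csv(path)
  for (i in seq_len(nrow(df))) {
    p <- defaults
    p$S <- df$param_value[i]
    r <- model_rhs(c(A = df$A[i], M = df$M[i], U = df$U[i], G = df$G[i]), p)
    expect_lt(max(abs(r)), 1e-8)
  }
})

test_that("forward/backward sweeps disagree only around the bistable window", {
  hy <- hysteresis_scan("S", c(0.8, 3.0), n_points = 12, params = defaults)
  fw <- hy[hy$direction == "forward", ]
  bw <- hy[hy$direction == "backward", ]
  dis <- abs(fw$M - bw$M) > 0.2
  expect_true(any(dis))            # hysteresis exists
  # disagreement confined to a contiguous inner block of the sweep
  expect_false(dis[1])
  expect_false(dis[length(dis)])
  expect_lte(max(rle(dis)$lengths[rle(dis)$values]), sum(dis))
  expect_equal(sum(rle(dis)$values), 1)
})

test_that("nullcline intersections mirror the full system's steady states", {
  nc <- nullclines(defaults, n_grid = 60)
  expect_equal(nrow(nc$intersections), 1)
  expect_true(all(nc$intersections$stable))

  p <- defaults
  p$S <- 1.8
  nc2 <- nullclines(p, n_grid = 60)
  expect_equal(nrow(nc2$intersections), 3)
  expect_equal(sum(nc2$intersections$stable), 2)
  # every intersection is a steady state of the reduced system: re-check
  for (i in seq_len(nrow(nc2$intersections))) {
    f <- ampkswitch:::.reduced_rhs(nc2$intersections$A[i],
                                   nc2$intersections$M[i], p,
                                   extended_variant())
    expect_lt(max(abs(f)), 1e-8)
  }
})

test_that("decoupled inhibition gives axis-parallel nullcline structure", {
  p <- defaults
  p$kiAM <- 0; p$kiMA <- 0; p$kiMU <- 0; p$kiAU <- 0
  nc <- nullclines(p, n_grid = 40)
  # with no coupling each nullcline pins its own variable: the A-curve is
  # vertical (constant A) and the M-curve horizontal (constant M)
  expect_lt(diff(range(nc$A_nullcline$A)), 1e-3)
  expect_lt(diff(range(nc$M_nullcline$M)), 1e-3)
  expect_equal(nrow(nc$intersections), 1)
})
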