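test_that("the control protocol is invariant over 24 simulated hours", {
  ctrl <- standard_protocol(character(), duration = 1440)
  traj <- integrate_protocol(ctrl, defaults)
  drift <- apply(abs(sweep(traj$states, 2, traj$states[1, ])), 2, max)
  expect_lt(max(drift), 1e-6)
})

test_that("state is continuous across stage onsets", {
  # rate-modifying treatments leave the state untouched at onset
  # (total-reducing treatments clamp instead; see the silencing test)
  pr <- standard_protocol("starvation", "compound_c", duration = 150)
  traj <- integrate_protocol(pr, defaults, dt = 0.5)
  i <- which(traj$times == 30)
  expect_length(i, 1)   # exact grid point, recorded once
  before <- traj$states[i - 1L, ]
  after <- traj$states[i + 1L, ]
  # no jump beyond what 0.5-min dynamics can produce
  expect_lt(max(abs(after - before)), 0.05)
})

test_that("silencing clamps the state at stage onset", {
  # start with high active ULK1, then silence it
  y0 <- c(A = 0.2, M = 0.05, U = 0.9, G = 0.8)
  pr <- standard_protocol("si_ulk1", duration = 30)
  traj <- integrate_protocol(pr, defaults, initial_state = y0)
  expect_lte(max(traj$states[, "U"]), 0.001 + 1e-9)
})

test_that("halving solver tolerances barely moves the endpoint", {
  pr <- standard_protocol("rapamycin", duration = 120)
  t1 <- integrate_protocol(pr, defaults, initial_state = phys,
                           rtol = 1e-8, atol = 1e-10)
  t2 <- integrate_protocol(pr, defaults, initial_state = phys,
                           rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(t1$states[nrow(t1$states), ] -
                      t2$states[nrow(t2$states), ])), 1e-5)
})

test_that("steady-state search finds the unique physiological state", {
  ss <- steady_states(defaults, n_starts = 40, seed = 3)
  stable <- Filter(function(s) s$stable, ss$states)
  expect_length(stable, 1)
  st <- stable[[1]]$state
  expect_gt(st[["M"]], 0.5 * defaults$MT)
  expect_lt(st[["A"]], 0.1 * defaults$AT)
  # reproducible from the seed
  ss2 <- steady_states(defaults, n_starts = 40, seed = 3)
  expect_identical(lapply(ss$states, `[[`, "state"),
                   lapply(ss2$states, `[[`, "state"))
})

test_that("all-zero rates are reported as degenerate", {
  p <- defaults
  for (f in c("kaA", "kiA", "kiAU", "kiAM", "kamtor", "kiM", "kiMA", "kiMU",
              "kaUA", "kiU", "kiUM", "kaGU", "kaG0", "kiG", "kiGM")) {
    p[[f]] <- 0
  }
  ss <- steady_states(p)
  expect_true(ss$degenerate)
  expect_length(ss$states, 0)
})

test_that("long-time flows from random interior starts land on a stable state", {
  ss <- steady_states(defaults, n_starts = 40)
  stable <- Filter(function(s) s$stable, ss$states)
  set.seed(21)
  for (i in 1:100) {
    y <- random_valid_state(defaults)
    out <- ampkswitch:::.integrate_raw(y, c(0, 10000, 20000), defaults,
                                       extended_variant())
    yf <- out[nrow(out), 2:5]
    d <- min(vapply(stable, function(s) max(abs(s$state - yf)), 0))
    expect_lt(d, 1e-4)
  }
})

test_that("trajectories export to a tidy table", {
  pr <- standard_protocol("rapamycin", duration = 10)
  traj <- integrate_protocol(pr, defaults, initial_state = phys)
  df <- trajectory_table(traj)
  expect_named(df, c("time_min", "species", "level"))
  expect_equal(nrow(df), 4 * length(traj$times))
  expect_setequal(unique(df$species), c("A", "M", "U", "G"))
})
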