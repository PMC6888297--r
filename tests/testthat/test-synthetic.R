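rap_proto <- standard_protocol("rapamycin", duration = 120)
rap_traj <- integrate_protocol(rap_proto, defaults, initial_state = phys)

test_that("noise-free tables equal the sampled model levels", {
  tab <- generate_densitometry(rap_traj, noise_model(cv = 0, cv_loading = 0,
                                                     n = 1), seed = 1)
  rd <- densitometry_readouts()
  for (i in seq_len(nrow(tab))) {
    map <- rd[[tab$readout[i]]]
    lev <- rap_traj$states[which(rap_traj$times == tab$time_min[i]),
                           map$species]
    expect_equal(tab$value[i], unname(map$transform(lev)),
                 tolerance = 1e-12)
  }
  expect_true(all(tab$value > 0))
})

test_that("tables are reproducible from the seed and strictly positive", {
  t1 <- generate_densitometry(rap_traj, noise_model(cv = 0.1), seed = 42)
  t2 <- generate_densitometry(rap_traj, noise_model(cv = 0.1), seed = 42)
  expect_identical(t1, t2)
  t3 <- generate_densitometry(rap_traj, noise_model(cv = 0.1), seed = 43)
  expect_false(identical(t1, t3))
  expect_true(all(t1$value > 0))
})

test_that("timepoints outside the trajectory span are rejected", {
  expect_error(generate_densitometry(rap_traj, noise_model(),
                                     timepoints = c(0, 200)),
               "span")
})

test_that("replicate scatter reflects the declared noise level", {
  # with 10% band noise, replicate CVs concentrate around 0.1
  cvs <- c()
  for (s in 1:60) {
    tab <- generate_densitometry(rap_traj,
                                 noise_model(cv = 0.1, cv_loading = 0,
                                             n = 3),
                                 timepoints = c(30, 60, 90), seed = s)
    per_cell <- tapply(tab$value,
                       interaction(tab$time_min, tab$readout),
                       function(v) stats::sd(v) / mean(v))
    cvs <- c(cvs, per_cell)
  }
  expect_gt(mean(cvs > 0.02 & cvs < 0.25), 0.95)
  expect_equal(stats::median(cvs), 0.1, tolerance = 0.35)
})

test_that("multiplicative noise is mean-corrected (unbiased)", {
  draws <- withr::with_seed(99, ampkswitch:::.rlnorm_mc(1e4, 0.2))
  expect_equal(mean(draws), 1, tolerance = 0.01)
})

test_that("the fixture suite mirrors the three time-course experiments", {
  fx <- fixture_suite(seed = 7)
  expect_named(fx, c("rapamycin", "si_ulk1_rapamycin",
                     "compound_c_rapamycin"))
  for (tab in fx) {
    expect_equal(length(unique(tab$time_min)), 5)
    expect_equal(max(table(tab$time_min, tab$readout)), 3)
  }
  # noise-free fixtures inherit the trajectory's event ordering
  fx0 <- fixture_suite(seed = 1, noise = noise_model(cv = 0, cv_loading = 0,
                                                     n = 1))
  rap <- fx0$rapamycin
  a_vals <- rap$value[rap$readout == "AMPK_T172P"]
  u_vals <- rap$value[rap$readout == "ULK1_S555P"]
  tp <- unique(rap$time_min)
  expect_lt(tp[which.max(a_vals)], tp[which.max(u_vals)])
  # silenced ULK1 pins the phospho-ULK1 readout near zero
  si <- fx0$si_ulk1_rapamycin[fx0$si_ulk1_rapamycin$readout == "ULK1_S555P", ]
  u0 <- si$value[si$time_min == 0][1]
  expect_lte(max(si$value), 2 * u0 + 1e-9)
})

test_that("densitometry tables round-trip through CSV", {
  tab <- generate_densitometry(rap_traj, noise_model(cv = 0.1), seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_densitometry(tab, path)
  tab2 <- read_densitometry(path)
  expect_equal(tab$value, tab2$value, tolerance = 1e-12)
  expect_error(read_densitometry(
    withr::local_tempfile(lines = "a,b\n1,2", fileext = ".csv")),
    "columns")
})
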