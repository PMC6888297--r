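test_that("the shipped defaults satisfy the full constraint battery", {
  cs <- calibration_score(defaults, check_bistable = FALSE)
  expect_equal(cs$score, 0)
  expect_length(cs$violations, 0)
  expect_equal(cs$matrix_report$n_matched, cs$matrix_report$n_total)
})

test_that("calibration returns defaults unchanged when already optimal", {
  cal <- calibrate_parameters(start = defaults, free = character(),
                              budget = 2)
  expect_identical(cal$params, defaults)
  expect_equal(cal$score, 0)
  # accepted-score trace is monotone non-increasing
  expect_true(all(diff(cal$trace) <= 0))
})

test_that("contradictory expectations are reported, not silently passed", {
  suite <- scenario_suite()[1]
  clash <- suite[[1]]
  clash$id <- "control_clash"
  clash$expect <- list(A = "HIGH", M = "HIGH", U = "LOW", G = "LOW")
  suite[[2]] <- clash
  cal <- calibrate_parameters(start = defaults, free = "kiG",
                              budget = 3, suite = suite)
  expect_gt(cal$score, 0)
  expect_true(any(grepl("control_clash", cal$violations)))
})

test_that("fixed quantities cannot be searched", {
  expect_error(calibrate_parameters(free = "kamtor"), "fixed")
  expect_error(calibrate_parameters(free = "AT"), "fixed")
})

test_that("noise-free synthetic data identifies the ULK1-AMPK loop rates", {
  proto <- standard_protocol("rapamycin", duration = 120)
  traj <- integrate_protocol(proto, defaults, initial_state = phys)
  tab <- generate_densitometry(traj, noise_model(cv = 0, cv_loading = 0,
                                                 n = 1), seed = 4)
  truth <- c(kaUA = defaults$kaUA, kiAU = defaults$kiAU)
  start <- defaults
  start$kaUA <- defaults$kaUA * 3
  start$kiAU <- defaults$kiAU / 3
  fit <- fit_time_course(tab, proto, c("kaUA", "kiAU"), params = start,
                         n_starts = 3, seed = 1, truth = truth)
  expect_lt(max(fit$relative_error), 0.01)
})

test_that("recovery error shrinks as the noise level drops", {
  proto <- standard_protocol("rapamycin", duration = 120)
  traj <- integrate_protocol(proto, defaults, initial_state = phys)
  truth <- c(kaUA = defaults$kaUA, kiAU = defaults$kiAU)
  start <- defaults
  start$kaUA <- defaults$kaUA * 2
  start$kiAU <- defaults$kiAU / 2
  err_at <- function(cv) {
    errs <- vapply(1:3, function(s) {
      tab <- generate_densitometry(traj, noise_model(cv = cv,
                                                     cv_loading = cv / 2,
                                                     n = 3), seed = s)
      f <- fit_time_course(tab, proto, c("kaUA", "kiAU"), params = start,
                           n_starts = 2, seed = s, truth = truth)
      max(f$relative_error)
    }, 0)
    stats::median(errs)
  }
  e0 <- err_at(0)
  e10 <- err_at(0.10)
  expect_lt(e0, e10)
  expect_lt(e10, 0.2)
})

test_that("zero free parameters means loss evaluation only", {
  proto <- standard_protocol("rapamycin", duration = 120)
  traj <- integrate_protocol(proto, defaults, initial_state = phys)
  tab <- generate_densitometry(traj, noise_model(cv = 0, cv_loading = 0,
                                                 n = 1), seed = 4)
  fit <- fit_time_course(tab, proto, character(), params = defaults)
  expect_length(fit$estimates, 0)
  expect_lt(fit$loss, 1e-10)
  expect_true(fit$converged)
})

test_that("over-parameterized fits trigger an identifiability warning", {
  proto <- standard_protocol("rapamycin", duration = 120)
  traj <- integrate_protocol(proto, defaults, initial_state = phys)
  tab <- generate_densitometry(traj, noise_model(cv = 0, cv_loading = 0,
                                                 n = 1), seed = 4)
  expect_warning(
    fit_time_course(tab, proto, c("kaUA", "kiAU", "kiU", "kaA"),
                    params = defaults, n_starts = 1),
    "identifiability")
})
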