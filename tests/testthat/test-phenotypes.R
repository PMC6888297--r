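test_that("classification follows the declared threshold conventions", {
  flat <- function(level) {
    pr <- standard_protocol(character(), duration = 10)
    structure(list(times = 0:10,
                   states = matrix(level, 11, 4,
                                   dimnames = list(NULL, c("A", "M", "U", "G"))),
                   protocol = pr),
              class = "ampk_trajectory")
  }
  c0 <- classify_trajectory(flat(0))
  expect_true(all(vapply(c0, `[[`, "", "level") == "LOW"))
  c1 <- classify_trajectory(flat(1))
  expect_true(all(vapply(c1, `[[`, "", "level") == "HIGH"))
  # induced then shut off = TRANSIENT; shut off from a high start = LOW
  pr <- standard_protocol(character(), duration = 4)
  mk <- function(x) structure(
    list(times = 0:4,
         states = matrix(rep(x, 4), 5, 4,
                         dimnames = list(NULL, c("A", "M", "U", "G"))),
         protocol = pr),
    class = "ampk_trajectory")
  tr <- classify_trajectory(mk(c(0.1, 0.8, 0.8, 0.3, 0.1)))
  expect_equal(tr$A$level, "TRANSIENT")
  off <- classify_trajectory(mk(c(0.9, 0.6, 0.3, 0.1, 0.05)))
  expect_equal(off$A$level, "LOW")
  mid <- classify_trajectory(mk(c(0.1, 0.8, 0.6, 0.4, 0.35)))
  expect_equal(mid$A$level, "AMBIGUOUS")
})

test_that("classification is invariant to output-grid resolution", {
  pr <- standard_protocol("rapamycin", duration = 120)
  t1 <- integrate_protocol(pr, defaults, initial_state = phys, dt = 1)
  t2 <- integrate_protocol(pr, defaults, initial_state = phys, dt = 0.25)
  c1 <- vapply(classify_trajectory(t1), `[[`, "", "level")
  c2 <- vapply(classify_trajectory(t2), `[[`, "", "level")
  expect_identical(c1, c2)
})

test_that("the scenario suite covers the treatment battery", {
  suite <- scenario_suite()
  expect_gte(length(suite), 16)
  ids <- vapply(suite, `[[`, "", "id")
  expect_true(all(c("control", "starvation", "rapamycin", "resveratrol",
                    "compound_c", "si_ulk1", "si_ulk1_rapamycin",
                    "si_tsc12", "si_tsc12_rapamycin",
                    "compound_c_rapamycin", "ampk_hyper", "mtor_hyper")
                  %in% ids))
  # every scenario resolves against the library
  lib <- treatment_library(defaults)
  for (sc in suite) {
    expect_true(all(c(sc$treatments, sc$pre) %in% names(lib)), label = sc$id)
  }
  ctrl <- suite[[match("control", ids)]]
  expect_equal(ctrl$expect, list(A = "LOW", M = "HIGH", U = "LOW", G = "LOW"))
})

test_that("the rapamycin time course reproduces the blot pattern", {
  pr <- standard_protocol("rapamycin", duration = 120)
  traj <- integrate_protocol(pr, defaults, initial_state = phys)
  cl <- classify_trajectory(traj)
  expect_equal(cl$A$level, "TRANSIENT")
  expect_equal(cl$M$level, "LOW")
  expect_equal(cl$U$level, "HIGH")
  expect_equal(cl$G$level, "HIGH")
})

test_that("all-wildcard expectations always match", {
  suite <- scenario_suite()[1:3]
  for (i in seq_along(suite)) {
    suite[[i]]$expect <- list(A = "*", M = "*", U = "*", G = "*")
  }
  rep <- evaluate_matrix(suite, defaults)
  expect_equal(rep$n_matched, length(suite))
})

test_that("matrix evaluation is deterministic and tabulates cleanly", {
  suite <- scenario_suite()[c(1, 3)]
  r1 <- evaluate_matrix(suite, defaults, initial_state = phys)
  r2 <- evaluate_matrix(suite, defaults, initial_state = phys)
  expect_identical(matrix_report_table(r1), matrix_report_table(r2))
  df <- matrix_report_table(r1)
  expect_named(df, c("id", "A", "M", "U", "G", "matched", "mismatches"))
})

test_that("event ordering matches the rapamycin narrative", {
  pr <- standard_protocol("rapamycin", duration = 120)
  eo <- event_ordering(integrate_protocol(pr, defaults, initial_state = phys))
  t_m_fall <- eo$fall[eo$species == "M"]
  t_a_rise <- eo$rise[eo$species == "A"]
  t_u_rise <- eo$rise[eo$species == "U"]
  expect_lt(t_m_fall, t_a_rise)
  expect_lt(t_a_rise, t_u_rise)
})

test_that("the control protocol crosses no thresholds", {
  pr <- standard_protocol(character(), duration = 120)
  eo <- event_ordering(integrate_protocol(pr, defaults, initial_state = phys))
  # the inactive species never rise; mTOR (already active) never falls
  expect_true(all(is.na(eo$rise[eo$species %in% c("A", "U", "G")])))
  expect_true(is.na(eo$fall[eo$species == "M"]))
})

test_that("ULK1 silencing decouples AMPK activation from autophagy", {
  pr <- standard_protocol(c("si_ulk1", "rapamycin"), duration = 120)
  traj <- integrate_protocol(pr, defaults, initial_state = phys)
  eo <- event_ordering(traj)
  expect_false(is.na(eo$rise[eo$species == "A"]))   # AMPK-P rises
  expect_true(is.na(eo$rise[eo$species == "U"]))    # ULK1-P never does
  cl <- classify_trajectory(traj)
  expect_equal(cl$A$level, "HIGH")
  expect_equal(cl$G$level, "LOW")
})

test_that("identical variants compared give zero difference", {
  suite <- scenario_suite()
  ids <- vapply(suite, `[[`, "", "id")
  sc <- suite[[match("rapamycin", ids)]]
  init <- phys
  proto <- standard_protocol(sc$treatments, sc$pre, duration = sc$duration)
  t1 <- integrate_protocol(proto, defaults, extended_variant(),
                           initial_state = init)
  t2 <- integrate_protocol(proto, defaults, extended_variant(),
                           initial_state = init)
  expect_identical(t1$states, t2$states)
})

test_that("removing the mTOR-AMPK edge flips the silencing phenotypes", {
  for (id in c("si_ulk1", "mtor_hyper")) {
    cv <- compare_variants(id, defaults)
    expect_lt(cv$extended$final[["A"]], 0.25)
    expect_gt(cv$template$final[["A"]], 0.5)
    expect_gt(cv$delta_A_final, 0.25)
  }
})

test_that("at baseline the template model transiently hyper-activates AMPK", {
  # at the shipped defaults the template network cannot hold AMPK down at
  # S = 1: AMPK-P surges and is then pulled down by induced ULK1
  cv <- compare_variants("control", defaults)
  expect_equal(cv$extended$call$A$level, "LOW")
  expect_gt(cv$template$call$A$peak, 0.5)
})
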