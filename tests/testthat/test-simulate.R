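test_that("simulation config validates its parameters", {
  expect_error(simulation_config(n_pairs = 0), "n_pairs")
  expect_error(simulation_config(p_fh = 1.2), "p_fh")
  expect_error(simulation_config(bmi_sd = -1), "positive")
  expect_error(simulation_config(age_range = c(80, 30)), "age_range")
  cfg <- simulation_config()
  expect_equal(cfg$n_pairs, 342)
  expect_equal(cfg$age_range, c(28, 87))
})

test_that("model-implied measures are exact: null, calibration, monotonicity", {
  null_cfg <- simulation_config(beta_fh = 0, beta_low = 0, beta_over = 0,
                                beta_obese = 0, beta_int = 0)
  tr <- theoretical_measures(null_cfg)
  expect_equal(c(tr$or11, tr$or10, tr$or01), c(1, 1, 1), tolerance = 1e-12)
  expect_equal(tr$reri, 0, tolerance = 1e-12)
  expect_equal(tr$si, 1, tolerance = 1e-12)

  # default configuration is calibrated to RERI 5.67
  expect_equal(theoretical_measures(simulation_config())$reri, 5.67,
               tolerance = 1e-6)
  # the FH-only cell is homogeneous, so its OR is exactly exp(beta_fh)
  expect_equal(theoretical_measures(simulation_config())$or10, 4.986,
               tolerance = 1e-9)

  # root-finding recovers an arbitrary target
  cfg <- simulation_config()
  b <- calibrate_beta_int(cfg, target_reri = 3.2)
  cfg$beta_int <- b
  expect_equal(theoretical_measures(cfg)$reri, 3.2, tolerance = 1e-3)

  # implied RERI increases with the joint-exposure coefficient
  rs <- sapply(c(-0.5, 0, 0.5, 1), function(bi) {
    c2 <- simulation_config(beta_int = bi)
    theoretical_measures(c2)$reri
  })
  expect_true(all(diff(rs) > 0))
})

test_that("theoretical cell ORs match a large Monte-Carlo cohort", {
  cfg <- simulation_config(seed = 505)
  tr <- theoretical_measures(cfg)
  pop <- simulate_population(cfg, 4e5, seed = 505)
  odds <- function(fh, abn) {
    sel <- pop$family_history == fh &
      (pop$bmi_category != "normal") == abn
    mean(pop$disease[sel]) / mean(!pop$disease[sel])
  }
  ref <- odds(FALSE, FALSE)
  expect_equal(odds(TRUE, TRUE) / ref, tr$or11, tolerance = 0.08)
  expect_equal(odds(TRUE, FALSE) / ref, tr$or10, tolerance = 0.08)
  expect_equal(odds(FALSE, TRUE) / ref, tr$or01, tolerance = 0.08)
  expect_equal(mean(pop$disease), tr$prevalence, tolerance = 0.02)
})

test_that("population simulation honours the null and its configured margins", {
  cfg <- simulation_config(beta_fh = 0, beta_low = 0, beta_over = 0,
                           beta_obese = 0, beta_int = 0, beta0 = -1.5)
  pop <- simulate_population(cfg, 20000, seed = 8)
  p0 <- plogis(-1.5)
  expect_lt(abs(mean(pop$disease) - p0), 3 * sqrt(p0 * (1 - p0) / 20000))

  cfg2 <- simulation_config(seed = 12)
  pop2 <- simulate_population(cfg2, 20000, seed = 12)
  bmi <- pop2$weight_kg / (pop2$height_cm / 100)^2
  expect_equal(mean(bmi), cfg2$bmi_mean, tolerance = 0.05)
  expect_equal(mean(pop2$family_history), 0.62, tolerance = 0.02)
  expect_true(all(pop2$age >= 28 & pop2$age <= 87))
  # degenerate risk configurations are refused
  expect_error(simulate_population(simulation_config(beta0 = 60), 100),
               "0 or 1")
})

test_that("matched sampling respects eligibility and reports infeasibility", {
  cohort <- data.frame(
    sex = c("male", "male", "female"), age = c(60, 62, 61),
    family_history = FALSE, bmi_true = 22, bmi_category = "normal",
    height_cm = 165, weight_kg = 60, waist_cm = 80, hip_cm = 95,
    disease = c(TRUE, FALSE, FALSE), stringsAsFactors = FALSE)
  ds <- sample_matched_study(cohort, 1, seed = 1)
  expect_equal(ds$n_pairs, 1)
  expect_equal(sort(unique(ds$records$sex)), "male")

  cohort_bad <- cohort
  cohort_bad$sex <- c("male", "female", "female")
  cohort_bad$age <- c(60, 80, 85)
  expect_error(sample_matched_study(cohort_bad, 1, seed = 1),
               "0 of 1 pairs")

  set.seed(21)
  cfg <- simulation_config(n_pairs = 60, seed = 21)
  ds2 <- simulate_matched_study(cfg)
  rec <- ds2$records
  by_pair <- split(rec, rec$pair_id)
  expect_true(all(vapply(by_pair, function(p) p$sex[1] == p$sex[2], logical(1))))
  expect_true(all(vapply(by_pair, function(p) abs(diff(p$age)) <= 5, logical(1))))
  expect_true(all(vapply(by_pair, function(p)
    setequal(p$status, c("case", "control")), logical(1))))
})

test_that("identical seeds give byte-identical simulated CSV output", {
  cfg <- simulation_config(n_pairs = 40, seed = 303)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  run_simulation(cfg, d1)
  run_simulation(cfg, d2)
  expect_identical(readLines(file.path(d1, "dataset.csv")),
                   readLines(file.path(d2, "dataset.csv")))
  truth <- jsonlite::fromJSON(file.path(d1, "truth.json"))
  expect_equal(truth$truth$reri, 5.67, tolerance = 1e-6)
  # sidecar measures satisfy the interaction identities
  expect_equal(truth$truth$reri, truth$truth$ap * truth$truth$or11,
               tolerance = 1e-9)
  expect_equal(truth$truth$pap, 1 - 1 / truth$truth$si, tolerance = 1e-9)
})
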