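pub <- c(or11 = 12.993, or10 = 4.986, or01 = 3.333)

test_that("interaction measures reproduce hand-computed values", {
  expect_equal(round(reri(pub[1], pub[2], pub[3]), 3), 5.674,
               ignore_attr = TRUE)
  expect_equal(round(synergy_index(pub[1], pub[2], pub[3]), 3), 1.898,
               ignore_attr = TRUE)
  expect_equal(round(attributable_proportion(pub[1], pub[2], pub[3]), 4),
               0.4367, ignore_attr = TRUE)
  expect_equal(round(pure_attributable_proportion(pub[1], pub[2], pub[3]), 4),
               0.4731, ignore_attr = TRUE)

  expect_equal(reri(1, 1, 1), 0)
  expect_equal(reri(6, 4, 3), 0)
  expect_equal(synergy_index(6, 4, 3), 1)
  expect_equal(synergy_index(7, 3, 3), 1.5)
  expect_equal(attributable_proportion(2, 1, 1), 0.5)
  expect_equal(pure_attributable_proportion(3, 2, 1.5), 0.25)
  expect_error(reri(-1, 2, 2), "positive")
})

test_that("undefined regions raise typed signals, not sentinel numbers", {
  expect_error(synergy_index(3, 0.5, 0.5),
               class = "addint_undefined_measure")
  expect_error(pure_attributable_proportion(0.9, 2, 2),
               class = "addint_undefined_measure")
  m <- interaction_measures(0.9, 0.5, 0.6)
  expect_true(is.na(m$si))
  expect_true(is.na(m$pap))
  expect_gte(length(m$notes), 2)
})

test_that("the four algebraic identities hold across random OR triples", {
  set.seed(123)
  for (i in 1:1000) {
    o <- random_or_triple()
    m <- interaction_measures(o[1], o[2], o[3])
    expect_equal(m$reri, m$ap * o[["or11"]], tolerance = 1e-9)
    if (o[["or11"]] > 1)
      expect_equal(m$pap, m$reri / (o[["or11"]] - 1), tolerance = 1e-9)
    if (is.finite(m$si) && !is.na(m$si)) {
      expect_equal(m$si, (o[["or11"]] - 1) / ((o[["or11"]] - 1) - m$reri),
                   tolerance = 1e-9)
      if (m$si > 0)
        expect_equal(m$pap, 1 - 1 / m$si, tolerance = 1e-9)
    }
  }
})

test_that("RERI is symmetric in the two singly-exposed ORs and zero under additivity", {
  set.seed(5)
  for (i in 1:50) {
    o <- random_or_triple()
    expect_equal(reri(o[1], o[2], o[3]), reri(o[1], o[3], o[2]))
    # exact additivity: all four measures at their null simultaneously
    o11_add <- o[["or10"]] + o[["or01"]] - 1
    m <- interaction_measures(o11_add, o[["or10"]], o[["or01"]])
    expect_equal(m$reri, 0, tolerance = 1e-12)
    expect_equal(m$ap, 0, tolerance = 1e-12)
    expect_equal(m$pap, 0, tolerance = 1e-12)
    expect_equal(m$si, 1, tolerance = 1e-12)
  }
})

test_that("interaction direction follows the sign of RERI", {
  expect_equal(classify_interaction(5.674), "positive")
  expect_equal(classify_interaction(0), "none")
  expect_equal(classify_interaction(reri(2, 2, 2)), "negative")
  m <- interaction_measures(12.993, 4.986, 3.333)
  expect_equal(classify_interaction(m), "positive")
})

test_that("delta CI collapses at zero covariance and scales linearly", {
  b <- log(pub)
  zero <- matrix(0, 3, 3)
  for (meas in c("reri", "ap", "si")) {
    ci <- delta_ci(meas, b, zero)
    expect_equal(ci$conf_low, ci$estimate, tolerance = 1e-12)
    expect_equal(ci$conf_high, ci$estimate, tolerance = 1e-12)
  }
  V <- diag(c(0.02, 0.03, 0.04))
  ci1 <- delta_ci("reri", b, V)
  ci4 <- delta_ci("reri", b, 4 * V)
  expect_equal(ci4$conf_high - ci4$conf_low,
               2 * (ci1$conf_high - ci1$conf_low), tolerance = 1e-9)
  expect_error(delta_ci("reri", b, matrix(c(1, 2, 0, 0, 1, 0, 0, 0, 1), 3)),
               "symmetric")
})

test_that("delta CIs agree with a parametric bootstrap oracle", {
  # consistent 2x4 counts (doubly-exposed control count 71 back-calculated
  # from the published OR); oracle draws log ORs from their asymptotic
  # normal and takes percentile intervals
  tab <- exposure_table(c(neither = 20, a_only = 117, b_only = 32, both = 246),
                        c(neither = 75, a_only = 88, b_only = 36, both = 71))
  m <- estimate_interaction(tab)
  set.seed(2024)
  B <- 2000
  L <- chol(m$covariance)
  draws <- matrix(rnorm(3 * B), B, 3) %*% L
  draws <- sweep(draws, 2, m$log_or, "+")
  o <- exp(draws)
  sim <- list(reri = o[, 1] - o[, 2] - o[, 3] + 1,
              ap = (o[, 1] - o[, 2] - o[, 3] + 1) / o[, 1],
              si = (o[, 1] - 1) / (o[, 2] + o[, 3] - 2))
  for (meas in names(sim)) {
    q <- quantile(sim[[meas]], c(0.025, 0.975), names = FALSE)
    ci <- m$ci[[meas]]
    width <- ci$conf_high - ci$conf_low
    expect_lt(abs(ci$conf_low - q[1]), 0.15 * width)
    expect_lt(abs(ci$conf_high - q[2]), 0.15 * width)
  }
})

test_that("pair bootstrap is deterministic, sane, and degenerate when it should be", {
  set.seed(77)
  cfg <- simulation_config(n_pairs = 120, seed = 31)
  ds <- simulate_matched_study(cfg)
  b1 <- bootstrap_ci(ds, "reri", B = 200, seed = 9)
  b2 <- bootstrap_ci(ds, "reri", B = 200, seed = 9)
  expect_identical(b1$replicates, b2$replicates)
  expect_lt(b1$conf_low, b1$estimate)
  expect_gt(b1$conf_high, b1$estimate)
  expect_error(bootstrap_ci(ds, "reri", B = 50, seed = 1), "at least 100")
  expect_error(bootstrap_ci(ds, "reri", B = 200), "seed")

  # one exposure pattern only: every resample gives the same table
  n <- 12
  df <- rbind(
    do.call(rbind, lapply(seq_len(n), function(i)
      subject_row(paste0("ca", i), sprintf("p%02d", i), "case",
                  family_history = TRUE, weight_kg = 90))),
    do.call(rbind, lapply(seq_len(n), function(i)
      subject_row(paste0("co", i), sprintf("p%02d", i), "control",
                  family_history = TRUE, weight_kg = 90))))
  ds0 <- study_dataset(df)
  b0 <- bootstrap_ci(ds0, "reri", B = 100, seed = 2)
  expect_equal(b0$conf_low, b0$conf_high)
})

test_that("delta and bootstrap intervals approach each other as n grows", {
  cfg <- simulation_config(n_pairs = 800, seed = 404)
  ds <- simulate_matched_study(cfg)
  tab <- build_exposure_table(ds)
  m <- estimate_interaction(tab, continuity = TRUE)
  bs <- bootstrap_ci(ds, "reri", B = 400, seed = 6)
  width <- m$ci$reri$conf_high - m$ci$reri$conf_low
  expect_lt(abs(m$ci$reri$conf_low - bs$conf_low), 0.25 * width)
  expect_lt(abs(m$ci$reri$conf_high - bs$conf_high), 0.25 * width)
})
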