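#!/usr/bin/env Rscript
# Operating characteristics of the RERI estimator at the study's design
# size (342 pairs): bias and delta-method CI coverage under the
# calibrated super-additive model, and type-I error calibration under an
# additive null (family-history effect only). 200 repetitions per
# scenario keep the run in the low minutes on one core.

suppressPackageStartupMessages(library(addint))
n_rep <- 200
set.seed(42)

run_scenario <- function(make_cfg, truth_reri) {
  seeds <- sample.int(1e6, n_rep)
  est <- numeric(n_rep); lo <- numeric(n_rep); hi <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    ds <- simulate_matched_study(make_cfg(seeds[i]))
    m <- estimate_interaction(build_exposure_table(ds), continuity = TRUE)
    est[i] <- m$reri; lo[i] <- m$ci$reri$conf_low; hi[i] <- m$ci$reri$conf_high
  }
  data.frame(truth = truth_reri,
             mean_est = mean(est),
             rel_bias = (mean(est) - truth_reri) /
               ifelse(truth_reri == 0, 1, truth_reri),
             coverage = mean(lo <= truth_reri & truth_reri <= hi),
             reject_null = mean(lo > 0 | hi < 0))
}

alt <- run_scenario(function(s) simulation_config(seed = s),
                    theoretical_measures(simulation_config())$reri)
null <- run_scenario(function(s)
  simulation_config(seed = s, beta_low = 0, beta_over = 0,
                    beta_obese = 0, beta_int = 0), 0)

oc <- rbind(cbind(scenario = "calibrated RERI 5.67", alt),
            cbind(scenario = "additive null", null))
dir.create("results", showWarnings = FALSE)
write.table(oc, file.path("results", "operating_characteristics.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
print(oc, digits = 3)
message("Under the calibrated model the mean RERI estimate sits within ",
        round(100 * abs(alt$rel_bias), 1), "% of truth with ",
        round(100 * alt$coverage, 1), "% delta-CI coverage; under the ",
        "additive null the 5% test rejects in ",
        round(100 * null$reject_null, 1), "% of studies.")
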