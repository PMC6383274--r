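# Shared fixture builders and independent oracles, all generated in code.

# A minimal well-formed subject row.
subject_row <- function(subject_id, pair_id, status,
                        sex = "female", age = 60,
                        height_cm = 165, weight_kg = 60,
                        waist_cm = 80, hip_cm = 95,
                        family_history = FALSE) {
  data.frame(subject_id = subject_id, pair_id = pair_id, status = status,
             sex = sex, age = age, height_cm = height_cm,
             weight_kg = weight_kg, waist_cm = waist_cm, hip_cm = hip_cm,
             family_history = family_history, stringsAsFactors = FALSE)
}

# n complete matched pairs with per-pair exposure pattern given as a
# 2-column logical matrix (case exposure, control exposure) for one
# binary exposure; weight chosen so bmi_abnormal is FALSE throughout.
pairs_dataset <- function(case_exposed, control_exposed) {
  n <- length(case_exposed)
  df <- rbind(
    do.call(rbind, lapply(seq_len(n), function(i)
      subject_row(paste0("ca", i), sprintf("p%03d", i), "case",
                  family_history = case_exposed[i]))),
    do.call(rbind, lapply(seq_len(n), function(i)
      subject_row(paste0("co", i), sprintf("p%03d", i), "control",
                  family_history = control_exposed[i]))))
  study_dataset(df)
}

# Random strictly positive 2x4 table.
random_exposure_table <- function(min_count = 1, max_count = 60) {
  counts <- sample(min_count:max_count, 8, replace = TRUE)
  exposure_table(
    cases = stats::setNames(counts[1:4],
                            c("neither", "a_only", "b_only", "both")),
    controls = stats::setNames(counts[5:8],
                               c("neither", "a_only", "b_only", "both")))
}

# Brute-force Pearson chi-square: explicit expected-count double loop.
chisq_bruteforce <- function(counts) {
  counts <- as.matrix(counts)
  n <- sum(counts)
  stat <- 0
  for (i in seq_len(nrow(counts))) for (j in seq_len(ncol(counts))) {
    e <- sum(counts[i, ]) * sum(counts[, j]) / n
    stat <- stat + (counts[i, j] - e)^2 / e
  }
  stat
}

# Random OR triple with all ORs above 1 (the regime where all four
# interaction measures are defined).
random_or_triple <- function() {
  c(or11 = exp(stats::runif(1, 0.1, 3)),
    or10 = exp(stats::runif(1, 0.05, 2)),
    or01 = exp(stats::runif(1, 0.05, 2)))
}
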