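#' Published joint-exposure counts from the motivating hypertension study
#'
#' Case and control counts over the four (family history, abnormal BMI)
#' joint-exposure cells as printed by the motivating 342-pair matched
#' case-control study of hypertension (Shanghai, adults aged 28-87),
#' together with its published crude odds ratios and 95% CIs. Note the
#' printed counts are not perfectly internally consistent with the
#' printed doubly-exposed OR (12.993 back-calculates to a control count
#' of 71, not the printed 70); the counts are kept exactly as printed.
#'
#' @return An \code{\link{exposure_table}} (family history x abnormal
#'   BMI) with the published OR columns attached as
#'   \code{attr(, "published")}.
#' @export
study_joint_counts <- function() {
  path <- system.file("extdata", "fh_bmi_joint_counts.csv",
                      package = "addint", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  cases <- stats::setNames(df$cases, df$cell)
  controls <- stats::setNames(df$controls, df$cell)
  tab <- exposure_table(cases, controls,
                        exposure_a = "family_history",
                        exposure_b = "bmi_abnormal")
  attr(tab, "published") <- df
  tab
}

#' Published odds-ratio triple of the motivating study
#'
#' The printed doubly-exposed, family-history-only and abnormal-BMI-only
#' odds ratios, used as inputs when recomputing the study's additive
#' interaction measures.
#'
#' @return Named numeric: \code{or11}, \code{or10}, \code{or01}.
#' @export
published_or_triple <- function() {
  pub <- attr(study_joint_counts(), "published")
  c(or11 = pub$published_or[pub$cell == "both"],
    or10 = pub$published_or[pub$cell == "a_only"],
    or01 = pub$published_or[pub$cell == "b_only"])
}

#' Published anthropometric group summaries of the motivating study
#'
#' Per-group (case/control) means and SDs of age, BMI, WHR, height,
#' weight, waist and hip circumference, with the published t statistics.
#'
#' @return Data frame, one row per variable.
#' @export
study_anthropometry <- function() {
  utils::read.csv(system.file("extdata", "anthropometry_summary.csv",
                              package = "addint", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Published categorical distributions of the motivating study
#'
#' Case/control counts for sex, family history, BMI category and WHR
#' status, with the published chi-square statistics.
#'
#' @return Data frame, one row per variable level.
#' @export
study_categorical_counts <- function() {
  utils::read.csv(system.file("extdata", "categorical_counts.csv",
                              package = "addint", mustWork = TRUE),
                  stringsAsFactors = FALSE)
}

#' Expand a joint-exposure table into subject-level records
#'
#' Builds a synthetic subject-level dataset whose 2x4 table reproduces
#' the given counts exactly: each subject gets the cell's family-history
#' flag and a BMI placed inside the matching category (22 for normal,
#' 26 for abnormal/overweight), with neutral values for the remaining
#' fields. Pair identifiers link the i-th case to the i-th control where
#' counts allow; the construction is for table-level analyses, not for
#' pair-level inference.
#'
#' @param table An \code{exposure_table}.
#' @return A data frame of subject records whose
#'   \code{\link{build_exposure_table}} equals \code{table}. Passing it
#'   through \code{\link{study_dataset}} drops records beyond the number
#'   of completable pairs (the published counts are unbalanced), so
#'   table-level analyses should use the data frame directly.
#' @export
expand_table_to_records <- function(table) {
  stopifnot(inherits(table, "exposure_table"))
  counts <- table$counts
  cells <- rownames(counts)
  fh <- c(neither = FALSE, a_only = TRUE, b_only = FALSE, both = TRUE)
  abn <- c(neither = FALSE, a_only = FALSE, b_only = TRUE, both = TRUE)
  rows <- list()
  for (cl in cells) for (st in c("case", "control")) {
    k <- counts[cl, st]
    if (k == 0) next
    rows[[paste(cl, st)]] <- data.frame(
      cell = cl, status = st,
      family_history = fh[[cl]],
      weight_kg = if (abn[[cl]]) round(26 * 1.65^2, 1) else round(22 * 1.65^2, 1),
      n = seq_len(k), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  n_case <- sum(counts[, "case"]); n_ctrl <- sum(counts[, "control"])
  df$subject_id <- paste0(substr(df$status, 1, 2), seq_len(nrow(df)))
  pair_no <- ifelse(df$status == "case",
                    cumsum(df$status == "case"),
                    cumsum(df$status == "control"))
  # a case and control share a pair id while both sides last; leftovers get
  # singleton ids and are dropped from pair-based analyses by construction
  df$pair_id <- ifelse(pair_no <= min(n_case, n_ctrl),
                       sprintf("p%04d", pair_no),
                       paste0("x", df$status, pair_no))
  out <- data.frame(subject_id = df$subject_id, pair_id = df$pair_id,
                    status = df$status, sex = "female", age = 60,
                    height_cm = 165, weight_kg = df$weight_kg,
                    waist_cm = 80, hip_cm = 95,
                    family_history = df$family_history,
                    stringsAsFactors = FALSE)
  derive_measures(out)
}
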