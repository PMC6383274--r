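#' Body-mass index from weight and height
#'
#' BMI = weight (kg) / height (m) squared. Height is taken in centimetres,
#' the unit in which clinical anthropometry is recorded.
#'
#' @param weight Body weight in kg. Must be positive.
#' @param height Standing height in cm. Must be positive.
#' @return BMI in kg/m^2, same length as the inputs.
#' @examples
#' compute_bmi(67.75, 162.81)
#' @export
compute_bmi <- function(weight, height) {
  if (any(!is.finite(weight)) || any(weight <= 0))
    stop("compute_bmi: 'weight' must be positive and finite", call. = FALSE)
  if (any(!is.finite(height)) || any(height <= 0))
    stop("compute_bmi: 'height' must be positive and finite", call. = FALSE)
  weight / (height / 100)^2
}

#' BMI category under the Chinese adult standard
#'
#' Cut points: low weight below 18.5, normal weight 18.5 to below 24.0,
#' overweight 24.0 to below 28.0, obese at and above 28.0 kg/m^2. The
#' intervals are half-open on the right so every positive BMI falls in
#' exactly one category.
#'
#' @param bmi BMI in kg/m^2, positive.
#' @return A factor with levels \code{low}, \code{normal}, \code{overweight},
#'   \code{obese}.
#' @export
categorize_bmi <- function(bmi) {
  if (any(!is.finite(bmi)) || any(bmi <= 0))
    stop("categorize_bmi: 'bmi' must be positive and finite", call. = FALSE)
  cut(bmi, breaks = c(0, 18.5, 24, 28, Inf), right = FALSE,
      labels = c("low", "normal", "overweight", "obese"))
}

#' Whether a BMI category counts as abnormal weight
#'
#' The joint-exposure analysis dichotomizes BMI as normal versus abnormal,
#' where abnormal collects low weight, overweight and obese.
#'
#' @param category Factor or character of BMI categories.
#' @return Logical vector, TRUE for abnormal weight.
#' @export
bmi_abnormal <- function(category) {
  category <- as.character(category)
  bad <- !category %in% c("low", "normal", "overweight", "obese")
  if (any(bad))
    stop("bmi_abnormal: unknown category ", paste(unique(category[bad]), collapse = ", "),
         call. = FALSE)
  category != "normal"
}

#' Sex-specific waist-to-hip ratio abnormality
#'
#' WHR at or below 0.90 for men and at or below 0.80 for women is normal;
#' values strictly above the cutoff are abnormal (central obesity).
#'
#' @param whr Waist/hip circumference ratio, positive.
#' @param sex Character or factor, \code{"male"} or \code{"female"}.
#' @return Logical vector, TRUE for abnormal WHR.
#' @export
classify_whr <- function(whr, sex) {
  if (any(!is.finite(whr)) || any(whr <= 0))
    stop("classify_whr: 'whr' must be positive and finite", call. = FALSE)
  sex <- as.character(sex)
  bad <- !sex %in% c("male", "female")
  if (any(bad))
    stop("classify_whr: 'sex' must be 'male' or 'female'", call. = FALSE)
  cutoff <- ifelse(sex == "male", 0.90, 0.80)
  whr > cutoff
}

# Required subject-level columns, in canonical order.
.required_columns <- c("subject_id", "pair_id", "status", "sex", "age",
                       "height_cm", "weight_kg", "waist_cm", "hip_cm",
                       "family_history")

# Append derived anthropometric columns (bmi, bmi_category, bmi_abnormal,
# whr, whr_abnormal) to a validated subject-level data frame.
derive_measures <- function(df) {
  df$bmi <- compute_bmi(df$weight_kg, df$height_cm)
  df$bmi_category <- categorize_bmi(df$bmi)
  df$bmi_abnormal <- bmi_abnormal(df$bmi_category)
  df$whr <- df$waist_cm / df$hip_cm
  df$whr_abnormal <- classify_whr(df$whr, df$sex)
  df
}

.parse_binary <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("1", "true", "yes", "y")] <- TRUE
  out[x %in% c("0", "false", "no", "n")] <- FALSE
  out
}

.parse_status <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep(NA_character_, length(x))
  out[x %in% c("case", "1")] <- "case"
  out[x %in% c("control", "0")] <- "control"
  out
}

#' Assemble a validated matched case-control dataset
#'
#' Validates subject-level records, derives BMI/WHR fields, and enforces the
#' pairing structure of a 1:1 matched design: a retained pair consists of
#' exactly one case and one control. Rows failing validation, and pairs that
#' are incomplete, are dropped with recorded reasons. Pair matching quality
#' (same sex, age difference of at most 5 years) is checked; violations are
#' a warning by default and an error with \code{strict = TRUE}.
#'
#' @param df Data frame with columns \code{subject_id}, \code{pair_id},
#'   \code{status} (case/control), \code{sex} (male/female), \code{age},
#'   \code{height_cm}, \code{weight_kg}, \code{waist_cm}, \code{hip_cm},
#'   \code{family_history} (logical or 0/1). Extra columns are carried
#'   through untouched.
#' @param strict Logical; treat matching-criteria violations as errors.
#' @return An object of class \code{study_dataset}: a list with
#'   \code{records} (validated data frame with derived columns),
#'   \code{n_pairs}, and \code{dropped} (data frame of subject_id + reason).
#' @export
study_dataset <- function(df, strict = FALSE) {
  missing_cols <- setdiff(.required_columns, names(df))
  if (length(missing_cols))
    stop("study_dataset: missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  df <- as.data.frame(df, stringsAsFactors = FALSE)
  dropped <- data.frame(subject_id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  drop_rows <- function(idx, reason) {
    if (!any(idx)) return(invisible())
    dropped <<- rbind(dropped, data.frame(
      subject_id = as.character(df$subject_id[idx]), reason = reason,
      stringsAsFactors = FALSE))
    df <<- df[!idx, , drop = FALSE]
    invisible()
  }

  df$status <- .parse_status(df$status)
  drop_rows(is.na(df$status), "unrecognized status")
  df$sex <- tolower(trimws(as.character(df$sex)))
  drop_rows(!df$sex %in% c("male", "female"), "unrecognized sex")
  df$family_history <- .parse_binary(df$family_history)
  drop_rows(is.na(df$family_history), "unrecognized family_history")

  for (col in c("age", "height_cm", "weight_kg", "waist_cm", "hip_cm")) {
    df[[col]] <- suppressWarnings(as.numeric(df[[col]]))
    drop_rows(!is.finite(df[[col]]), paste0("unparseable ", col))
  }
  drop_rows(df$age <= 0 | df$age >= 130, "age out of range")
  for (col in c("height_cm", "weight_kg", "waist_cm", "hip_cm"))
    drop_rows(df[[col]] <= 0, paste0("non-positive ", col))

  # Pairing: exactly one case and one control per retained pair_id.
  if (nrow(df)) {
    tab <- table(df$pair_id, factor(df$status, levels = c("case", "control")))
    ok_pairs <- rownames(tab)[tab[, "case"] == 1 & tab[, "control"] == 1 &
                                rowSums(tab) == 2]
    drop_rows(!df$pair_id %in% ok_pairs, "incomplete or malformed pair")
  }

  if (nrow(df)) {
    by_pair <- split(df, df$pair_id)
    sex_ok <- vapply(by_pair, function(p) p$sex[1] == p$sex[2], logical(1))
    age_ok <- vapply(by_pair, function(p) abs(diff(p$age)) <= 5, logical(1))
    bad <- names(by_pair)[!(sex_ok & age_ok)]
    if (length(bad)) {
      msg <- paste0("pair(s) violating matching criteria (same sex, age gap <= 5): ",
                    paste(bad, collapse = ", "))
      if (strict) stop("study_dataset: ", msg, call. = FALSE)
      warning("study_dataset: ", msg, call. = FALSE)
    }
  }

  df <- derive_measures(df)
  rownames(df) <- NULL
  structure(list(records = df,
                 n_pairs = length(unique(df$pair_id)),
                 dropped = dropped),
            class = "study_dataset")
}

#' Load a matched case-control dataset from CSV
#'
#' Reads a comma-separated file with a header row, optionally remaps
#' column names, validates it and derives BMI/WHR fields. See
#' \code{\link{study_dataset}} for the validation rules.
#'
#' @param path Path to a UTF-8 CSV file with header.
#' @param columns Optional named character vector mapping required canonical
#'   names to the file's column names, e.g.
#'   \code{c(height_cm = "Height", weight_kg = "Wt")}.
#' @param strict Passed to \code{\link{study_dataset}}.
#' @return A \code{study_dataset}.
#' @export
load_dataset <- function(path, columns = NULL, strict = FALSE) {
  if (!file.exists(path))
    stop("load_dataset: file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(columns)) {
    for (canonical in names(columns)) {
      src <- columns[[canonical]]
      if (!src %in% names(df))
        stop("load_dataset: mapped column '", src, "' not present in file",
             call. = FALSE)
      names(df)[names(df) == src] <- canonical
    }
  }
  study_dataset(df, strict = strict)
}

#' Write a study dataset (with derived columns) to CSV
#'
#' @param dataset A \code{study_dataset}.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_dataset <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("Matched case-control dataset:",
      nrow(x$records), "subjects in", x$n_pairs, "pairs;",
      nrow(x$dropped), "row(s) dropped\n")
  invisible(x)
}
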