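.cell_labels <- c("neither", "a_only", "b_only", "both")

#' Construct a 2x4 joint-exposure table from counts
#'
#' The 2x4 layout cross-classifies case/control status against the four
#' combinations of two binary exposures A and B, all compared against the
#' common doubly-unexposed reference cell. Cells are labelled
#' \code{neither} (A=0,B=0), \code{a_only}, \code{b_only} and \code{both}.
#'
#' @param cases,controls Named numeric vectors of non-negative integer
#'   counts with names \code{neither}, \code{a_only}, \code{b_only},
#'   \code{both} (any order).
#' @param exposure_a,exposure_b Human-readable exposure names.
#' @return An object of class \code{exposure_table}.
#' @export
exposure_table <- function(cases, controls,
                           exposure_a = "A", exposure_b = "B") {
  for (v in list(cases, controls)) {
    if (!all(.cell_labels %in% names(v)))
      stop("exposure_table: counts must be named ",
           paste(.cell_labels, collapse = ", "), call. = FALSE)
    if (any(v < 0) || any(v != round(v)))
      stop("exposure_table: counts must be non-negative integers", call. = FALSE)
  }
  counts <- cbind(case = cases[.cell_labels], control = controls[.cell_labels])
  rownames(counts) <- .cell_labels
  structure(list(counts = counts,
                 exposure_a = exposure_a, exposure_b = exposure_b,
                 reference = "neither"),
            class = "exposure_table")
}

#' Build the joint-exposure table from a matched dataset
#'
#' Tabulates case and control counts over the four combinations of two
#' binary exposure columns, by default family history and abnormal BMI.
#'
#' @param dataset A \code{study_dataset} (or a data frame with the exposure
#'   and \code{status} columns).
#' @param exposure_a,exposure_b Names of logical (or 0/1) columns.
#' @return An \code{exposure_table}.
#' @export
build_exposure_table <- function(dataset,
                                 exposure_a = "family_history",
                                 exposure_b = "bmi_abnormal") {
  df <- if (inherits(dataset, "study_dataset")) dataset$records else dataset
  for (col in c(exposure_a, exposure_b, "status"))
    if (!col %in% names(df))
      stop("build_exposure_table: column '", col, "' not found", call. = FALSE)
  a <- as.logical(df[[exposure_a]])
  b <- as.logical(df[[exposure_b]])
  if (any(is.na(a)) || any(is.na(b))) {
    bad <- df$subject_id[is.na(a) | is.na(b)]
    stop("build_exposure_table: undetermined exposure for subject(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  cell <- ifelse(!a & !b, "neither",
          ifelse(a & !b, "a_only",
          ifelse(!a & b, "b_only", "both")))
  cell <- factor(cell, levels = .cell_labels)
  cases <- table(cell[df$status == "case"])
  controls <- table(cell[df$status == "control"])
  exposure_table(as.numeric(cases)[match(.cell_labels, names(cases))] |>
                   stats::setNames(.cell_labels),
                 as.numeric(controls)[match(.cell_labels, names(controls))] |>
                   stats::setNames(.cell_labels),
                 exposure_a = exposure_a, exposure_b = exposure_b)
}

#' Woolf confidence interval for an odds ratio
#'
#' Log-scale normal interval with standard error
#' \code{sqrt(1/a + 1/b + 1/c + 1/d)} over the four cell counts.
#'
#' @param case_cell,control_cell Counts in the index exposure cell.
#' @param case_ref,control_ref Counts in the reference cell.
#' @param alpha Two-sided significance level (default 0.05).
#' @return Numeric vector \code{c(ci_low, ci_high)}.
#' @export
woolf_ci <- function(case_cell, control_cell, case_ref, control_ref,
                     alpha = 0.05) {
  counts <- c(case_cell, control_cell, case_ref, control_ref)
  if (any(counts <= 0))
    stop("woolf_ci: all four counts must be positive (use the continuity ",
         "option upstream for zero cells)", call. = FALSE)
  log_or <- log((case_cell * control_ref) / (control_cell * case_ref))
  se <- sqrt(sum(1 / counts))
  z <- stats::qnorm(1 - alpha / 2)
  exp(log_or + c(-1, 1) * z * se)
}

#' Crude odds ratio of one joint-exposure cell against the reference
#'
#' The cross-product odds ratio of the index cell against the
#' doubly-unexposed reference, with a Woolf confidence interval. Zero
#' counts are an error by default; with \code{continuity = TRUE} the
#' Haldane-Anscombe correction adds 0.5 to all four counts involved.
#'
#' @param table An \code{exposure_table}.
#' @param cell One of \code{"a_only"}, \code{"b_only"}, \code{"both"}
#'   (or \code{"neither"}, which gives OR exactly 1).
#' @param alpha Two-sided significance level.
#' @param continuity Apply the +0.5 correction when any count is zero.
#' @return An object of class \code{or_estimate}: list with \code{or},
#'   \code{log_or}, \code{se_log_or}, \code{conf_low}, \code{conf_high},
#'   \code{alpha}, \code{cell}, \code{reference}, \code{continuity}.
#' @export
crude_or <- function(table, cell, alpha = 0.05, continuity = FALSE) {
  stopifnot(inherits(table, "exposure_table"))
  cell <- match.arg(cell, .cell_labels)
  ref <- table$reference
  a <- table$counts[cell, "case"]
  b <- table$counts[cell, "control"]
  c0 <- table$counts[ref, "case"]
  d0 <- table$counts[ref, "control"]
  corrected <- FALSE
  if (cell == ref) {
    est <- list(or = 1, log_or = 0, se_log_or = 0,
                conf_low = 1, conf_high = 1)
  } else {
    if (any(c(a, b, c0, d0) == 0)) {
      if (!continuity)
        stop("crude_or: zero cell count in '", cell, "' vs reference; ",
             "set continuity = TRUE for the Haldane-Anscombe correction",
             call. = FALSE)
      a <- a + 0.5; b <- b + 0.5; c0 <- c0 + 0.5; d0 <- d0 + 0.5
      corrected <- TRUE
    }
    log_or <- log((a * d0) / (b * c0))
    se <- sqrt(1 / a + 1 / b + 1 / c0 + 1 / d0)
    ci <- exp(log_or + c(-1, 1) * stats::qnorm(1 - alpha / 2) * se)
    est <- list(or = exp(log_or), log_or = log_or, se_log_or = se,
                conf_low = ci[1], conf_high = ci[2])
  }
  structure(c(est, list(alpha = alpha, cell = cell, reference = ref,
                        continuity = corrected)),
            class = "or_estimate")
}

#' All three index-cell odds ratios of a 2x4 table
#'
#' @param table An \code{exposure_table}.
#' @param alpha Significance level.
#' @param continuity Passed to \code{\link{crude_or}}.
#' @return Data frame with one row per cell (a_only, b_only, both):
#'   cases, controls, or, conf_low, conf_high.
#' @export
or_table <- function(table, alpha = 0.05, continuity = FALSE) {
  cells <- c("a_only", "b_only", "both")
  ests <- lapply(cells, crude_or, table = table, alpha = alpha,
                 continuity = continuity)
  data.frame(cell = cells,
             cases = table$counts[cells, "case"],
             controls = table$counts[cells, "control"],
             or = vapply(ests, `[[`, numeric(1), "or"),
             conf_low = vapply(ests, `[[`, numeric(1), "conf_low"),
             conf_high = vapply(ests, `[[`, numeric(1), "conf_high"),
             row.names = NULL)
}

# Covariance matrix of the three log odds ratios (both, a_only, b_only)
# sharing the 2x4 table's reference cell. Var = sum of reciprocal counts
# of the two cells; shared reference induces Cov = 1/case_ref + 1/control_ref.
log_or_covariance <- function(table, continuity = FALSE) {
  stopifnot(inherits(table, "exposure_table"))
  counts <- table$counts
  if (any(counts == 0)) {
    if (!continuity)
      stop("log_or_covariance: zero cell; set continuity = TRUE", call. = FALSE)
    counts <- counts + 0.5
  }
  cells <- c("both", "a_only", "b_only")
  ref_var <- 1 / counts["neither", "case"] + 1 / counts["neither", "control"]
  V <- matrix(ref_var, 3, 3, dimnames = list(cells, cells))
  diag(V) <- ref_var + 1 / counts[cells, "case"] + 1 / counts[cells, "control"]
  V
}

#' Welch two-sample t-test from summary statistics
#'
#' Unpooled-variance t statistic with Welch-Satterthwaite degrees of
#' freedom; with equal group sizes and SDs this coincides with the pooled
#' form. Suitable for comparing published group means/SDs.
#'
#' @param mean1,sd1,n1 First group summary (n >= 2, sd >= 0).
#' @param mean2,sd2,n2 Second group summary.
#' @return List with \code{t} (absolute value), \code{df}, \code{p}
#'   (two-sided).
#' @export
two_sample_t <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) stop("two_sample_t: each group needs n >= 2", call. = FALSE)
  if (sd1 < 0 || sd2 < 0) stop("two_sample_t: SDs must be non-negative", call. = FALSE)
  v1 <- sd1^2 / n1
  v2 <- sd2^2 / n2
  if (v1 + v2 == 0) {
    if (mean1 == mean2)
      return(list(t = 0, df = n1 + n2 - 2, p = 1))
    stop("two_sample_t: zero variance with unequal means (infinite t)",
         call. = FALSE)
  }
  tstat <- abs(mean2 - mean1) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  list(t = tstat, df = df, p = 2 * stats::pt(-tstat, df))
}

#' Pearson chi-square test for an r x c count table
#'
#' Pearson statistic without continuity correction,
#' df = (r - 1)(c - 1). Zero row or column marginals are an error.
#'
#' @param counts Numeric matrix of non-negative counts.
#' @return List with \code{statistic}, \code{df}, \code{p},
#'   \code{expected}.
#' @export
chisq_rxc <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("chisq_rxc: negative count", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chisq_rxc: zero marginal total", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = res$expected)
}

#' Per-group mean/SD summaries of numeric variables
#'
#' Summarizes numeric variables by case/control status, with the n-1
#' denominator for the SD. Groups with fewer than two observations are
#' flagged and get no SD.
#'
#' @param dataset A \code{study_dataset} or data frame with \code{status}.
#' @param variables Character vector of numeric column names.
#' @return Data frame: variable, group, n, mean, sd, flagged.
#' @export
summarize_by_group <- function(dataset, variables) {
  df <- if (inherits(dataset, "study_dataset")) dataset$records else dataset
  out <- do.call(rbind, lapply(variables, function(v) {
    if (!is.numeric(df[[v]]))
      stop("summarize_by_group: '", v, "' is not numeric", call. = FALSE)
    do.call(rbind, lapply(c("control", "case"), function(g) {
      x <- df[[v]][df$status == g]
      data.frame(variable = v, group = g, n = length(x),
                 mean = if (length(x)) mean(x) else NA_real_,
                 sd = if (length(x) >= 2) stats::sd(x) else NA_real_,
                 flagged = length(x) < 2)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.exposure_table <- function(x, ...) {
  cat("2x4 joint-exposure table (", x$exposure_a, " x ", x$exposure_b,
      "), reference = ", x$reference, "\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' @export
print.or_estimate <- function(x, ...) {
  cat(sprintf("OR[%s vs %s] = %.3f (%g%% CI %.3f-%.3f)%s\n",
              x$cell, x$reference, x$or, 100 * (1 - x$alpha),
              x$conf_low, x$conf_high,
              if (isTRUE(x$continuity)) " [continuity-corrected]" else ""))
  invisible(x)
}

#' Serialize an exposure table to JSON
#'
#' Cells are keyed \code{"00"}, \code{"10"}, \code{"01"}, \code{"11"} by
#' (A, B) exposure state, each a two-element [case, control] array.
#'
#' @param table An \code{exposure_table}.
#' @param path Optional file path; if NULL the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
exposure_table_to_json <- function(table, path = NULL) {
  key <- c(neither = "00", a_only = "10", b_only = "01", both = "11")
  cells <- lapply(.cell_labels, function(cl) unname(table$counts[cl, ]))
  names(cells) <- key[.cell_labels]
  doc <- list(exposure_a = table$exposure_a, exposure_b = table$exposure_b,
              cells = cells)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(json)
}

#' Read an exposure table from its JSON serialization
#'
#' @param path File path or JSON string produced by
#'   \code{\link{exposure_table_to_json}}.
#' @return An \code{exposure_table}.
#' @export
exposure_table_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path)
  key <- c("00" = "neither", "10" = "a_only", "01" = "b_only", "11" = "both")
  cases <- controls <- stats::setNames(numeric(4), .cell_labels)
  for (k in names(doc$cells)) {
    cases[key[[k]]] <- doc$cells[[k]][1]
    controls[key[[k]]] <- doc$cells[[k]][2]
  }
  exposure_table(cases, controls,
                 exposure_a = doc$exposure_a %||% "A",
                 exposure_b = doc$exposure_b %||% "B")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
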