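#' Run the full matched case-control interaction analysis
#'
#' Orchestrates the complete pipeline on one dataset: validation and
#' derived anthropometry, per-group summaries with t statistics,
#' categorical distributions with chi-square tests, the 2x4
#' joint-exposure table with crude ORs and Woolf CIs, unconditional
#' (sex-adjusted) and conditional (matched-pair) logistic fits, and the
#' four additive-interaction measures with delta-method and matched-pair
#' bootstrap CIs. Sections that fail (for example regression
#' non-convergence) are marked with the error message and the remaining
#' sections still run.
#'
#' @param input Path to a subject-level CSV, a \code{study_dataset}, or a
#'   data frame acceptable to \code{\link{study_dataset}}.
#' @param alpha Two-sided significance level (default 0.05).
#' @param bootstrap_B Bootstrap replicates for the interaction CIs
#'   (default 2000; set to 0 to skip the bootstrap).
#' @param seed Integer seed for the bootstrap.
#' @param strict Passed to \code{\link{study_dataset}}.
#' @return An object of class \code{analysis_report}: a named list of
#'   sections (\code{dataset}, \code{group_summaries},
#'   \code{categorical}, \code{exposure}, \code{regression},
#'   \code{interaction}, \code{provenance}); failed sections carry an
#'   \code{error} entry.
#' @export
run_analysis <- function(input, alpha = 0.05, bootstrap_B = 2000,
                         seed = 1L, strict = FALSE) {
  dataset <- if (inherits(input, "study_dataset")) input
             else if (is.character(input)) load_dataset(input, strict = strict)
             else study_dataset(input, strict = strict)
  if (nrow(dataset$records) == 0)
    stop("run_analysis: no records remain after validation (",
         nrow(dataset$dropped), " dropped)", call. = FALSE)
  section <- function(expr) tryCatch(expr, error = function(e)
    list(error = conditionMessage(e)))
  rec <- dataset$records

  report <- list()
  report$dataset <- list(
    n_subjects = nrow(rec),
    n_pairs = dataset$n_pairs,
    n_dropped = nrow(dataset$dropped),
    dropped_reasons = if (nrow(dataset$dropped))
      as.list(table(dataset$dropped$reason)) else list())

  report$group_summaries <- section({
    vars <- c("age", "bmi", "whr", "height_cm", "weight_kg",
              "waist_cm", "hip_cm")
    summ <- summarize_by_group(dataset, vars)
    tests <- do.call(rbind, lapply(vars, function(v) {
      s <- summ[summ$variable == v, ]
      ct <- s[s$group == "control", ]; ca <- s[s$group == "case", ]
      tt <- two_sample_t(ct$mean, ct$sd, ct$n, ca$mean, ca$sd, ca$n)
      data.frame(variable = v, t = tt$t, df = tt$df, p = tt$p)
    }))
    list(summaries = summ, t_tests = tests)
  })

  report$categorical <- section({
    out <- lapply(c(sex = "sex", family_history = "family_history",
                    bmi_category = "bmi_category",
                    whr_abnormal = "whr_abnormal"), function(v) {
      counts <- table(rec[[v]], rec$status)[, c("control", "case"),
                                            drop = FALSE]
      ch <- chisq_rxc(counts)
      list(counts = as.data.frame.matrix(counts),
           statistic = ch$statistic, df = ch$df, p = ch$p)
    })
    out
  })

  report$exposure <- section({
    tab <- build_exposure_table(dataset)
    list(table = tab, or_table = or_table(tab, alpha = alpha))
  })

  report$regression <- list(
    unconditional = section({
      rec2 <- joint_exposure_design(rec)
      rec2$sex <- factor(rec2$sex, levels = c("female", "male"))
      fit_logistic(rec2, ~ a_only + b_only + both + sex, alpha = alpha)
    }),
    conditional = section({
      ds2 <- joint_exposure_design(dataset)
      fit_conditional_pairs(ds2, ~ a_only + b_only + both, alpha = alpha)
    }))

  report$interaction <- section({
    tab <- build_exposure_table(dataset)
    m <- estimate_interaction(tab, alpha = alpha)
    if (bootstrap_B >= 100) {
      m$bootstrap <- lapply(
        stats::setNames(nm = c("reri", "ap", "pap", "si")),
        function(meas) {
          b <- tryCatch(
            bootstrap_ci(dataset, meas, B = bootstrap_B, seed = seed,
                         alpha = alpha),
            error = function(e) NULL)
          if (is.null(b)) NULL else b[c("estimate", "conf_low",
                                        "conf_high", "B", "n_undefined")]
        })
    }
    m
  })

  report$provenance <- list(
    package = "addint",
    version = as.character(utils::packageVersion("addint")),
    alpha = alpha, bootstrap_B = bootstrap_B, seed = seed,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))
  class(report) <- "analysis_report"
  report
}

# Strip non-serializable pieces and shape a report for JSON output.
.report_to_list <- function(report) {
  out <- unclass(report)
  if (!is.null(out$exposure$table)) {
    tab <- out$exposure$table
    out$exposure$table <- list(
      exposure_a = tab$exposure_a, exposure_b = tab$exposure_b,
      counts = as.data.frame.matrix(tab$counts))
  }
  strip_fit <- function(f) {
    if (is.null(f) || !inherits(f, "fit_result")) return(f)
    list(coefficients = as.list(f$coefficients),
         or_table = f$or_table, loglik = f$loglik,
         converged = f$converged, n_used = f$n_used)
  }
  out$regression$unconditional <- strip_fit(out$regression$unconditional)
  out$regression$conditional <- strip_fit(out$regression$conditional)
  if (inherits(out$interaction, "interaction_measures")) {
    m <- out$interaction
    out$interaction <- list(
      ors = as.list(m$ors),
      estimates = list(reri = m$reri, ap = m$ap, pap = m$pap, si = m$si),
      delta_ci = lapply(m$ci, function(ci)
        if (is.null(ci)) NULL else ci[c("estimate", "conf_low", "conf_high")]),
      bootstrap_ci = m$bootstrap,
      direction = classify_interaction(m),
      notes = m$notes)
  }
  out
}

#' Write an analysis report to disk
#'
#' Emits \code{report.json} (the full machine-readable report),
#' \code{report.md} (a human-readable summary whose numbers all appear in
#' the JSON) and \code{tables/*.tsv} (group summaries, categorical
#' counts, and the joint-exposure OR table).
#'
#' @param report An \code{analysis_report} from \code{\link{run_analysis}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  doc <- .report_to_list(report)
  jsonlite::write_json(doc, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows", pretty = TRUE)

  if (is.null(report$group_summaries$error))
    utils::write.table(merge(report$group_summaries$summaries,
                             report$group_summaries$t_tests, by = "variable"),
                       file.path(dir, "tables", "group_summaries.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (is.null(report$exposure$error))
    utils::write.table(report$exposure$or_table,
                       file.path(dir, "tables", "joint_exposure_or.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)

  md <- c("# Matched case-control additive-interaction report", "",
          sprintf("Subjects: %d in %d pairs (%d dropped)",
                  report$dataset$n_subjects, report$dataset$n_pairs,
                  report$dataset$n_dropped), "")
  if (is.null(report$exposure$error)) {
    md <- c(md, "## Joint-exposure odds ratios", "",
            "cell | cases | controls | OR | 95% CI",
            "---- | ----- | -------- | -- | ------")
    ot <- report$exposure$or_table
    md <- c(md, sprintf("%s | %d | %d | %.3f | %.3f-%.3f",
                        ot$cell, ot$cases, ot$controls, ot$or,
                        ot$conf_low, ot$conf_high))
    md <- c(md, "")
  }
  m <- report$interaction
  if (inherits(m, "interaction_measures")) {
    md <- c(md, "## Additive interaction", "")
    for (meas in c("reri", "ap", "pap", "si")) {
      ci <- m$ci[[meas]]
      line <- if (!is.null(ci))
        sprintf("- %s = %.4f (%.0f%% delta CI %.4f to %.4f)",
                toupper(meas), m[[meas]], 100 * (1 - m$alpha),
                ci$conf_low, ci$conf_high)
      else sprintf("- %s = %.4f", toupper(meas), m[[meas]])
      md <- c(md, line)
    }
    md <- c(md, sprintf("- direction: %s", classify_interaction(m)), "")
  }
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}

#' Simulate a matched study and write it with its ground truth
#'
#' Generates a matched case-control study from a
#' \code{\link{simulation_config}}, writes the subject-level CSV (the
#' same schema \code{\link{load_dataset}} reads) and a JSON sidecar with
#' the configuration and the model-implied true odds ratios and
#' interaction measures.
#'
#' @param config A \code{simulation_config}.
#' @param dir Output directory (created if needed).
#' @return The \code{study_dataset}, invisibly.
#' @export
run_simulation <- function(config, dir) {
  stopifnot(inherits(config, "simulation_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ds <- simulate_matched_study(config)
  write_dataset(ds, file.path(dir, "dataset.csv"))
  truth <- attr(ds, "truth")
  jsonlite::write_json(
    list(config = unclass(config), truth = unclass(truth)),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(ds)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("addint analysis report\n")
  cat("  subjects:", x$dataset$n_subjects, "in", x$dataset$n_pairs,
      "pairs;", x$dataset$n_dropped, "dropped\n")
  if (is.null(x$exposure$error)) {
    cat("  joint-exposure ORs:\n")
    print(x$exposure$or_table)
  }
  if (inherits(x$interaction, "interaction_measures")) print(x$interaction)
  invisible(x)
}
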