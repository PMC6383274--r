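#' @name interaction-measures
#' @title Additive-interaction measures from three odds ratios
#'
#' @description
#' For two binary risk factors A and B with a common doubly-unexposed
#' reference, let OR11 be the odds ratio of the doubly-exposed group, OR10
#' of the A-only group and OR01 of the B-only group (odds ratios standing
#' in for risk ratios under the rare-disease approximation, with the
#' reference risk normalized to 1). The four measures of departure from
#' additivity of excess risks are
#' \itemize{
#'   \item RERI = OR11 - OR10 - OR01 + 1 (relative excess risk due to
#'     interaction; 0 under exact additivity),
#'   \item AP = RERI / OR11 (proportion of the doubly-exposed risk
#'     attributable to interaction),
#'   \item PAP = RERI / (OR11 - 1) (interaction's share of the
#'     doubly-exposed excess risk; equals 1 - 1/SI),
#'   \item SI = (OR11 - 1) / ((OR10 - 1) + (OR01 - 1)) (synergy index;
#'     1 under additivity, above 1 for super-additive interaction).
#' }
#'
#' @param or11 Odds ratio of the doubly-exposed cell versus reference.
#' @param or10 Odds ratio of the A-only cell.
#' @param or01 Odds ratio of the B-only cell.
#' @return A single numeric value.
NULL

.check_ors <- function(or11, or10, or01) {
  x <- c(or11, or10, or01)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("interaction measures: odds ratios must be positive and finite",
         call. = FALSE)
}

.undefined <- function(msg) {
  stop(structure(class = c("addint_undefined_measure", "error", "condition"),
                 list(message = msg, call = NULL)))
}

#' @rdname interaction-measures
#' @export
reri <- function(or11, or10, or01) {
  .check_ors(or11, or10, or01)
  or11 - or10 - or01 + 1
}

#' @rdname interaction-measures
#' @export
synergy_index <- function(or11, or10, or01) {
  .check_ors(or11, or10, or01)
  denom <- (or10 - 1) + (or01 - 1)
  if (denom <= 0)
    .undefined(paste0("synergy_index undefined: (OR10 - 1) + (OR01 - 1) = ",
                      format(denom), " is not positive"))
  (or11 - 1) / denom
}

#' @rdname interaction-measures
#' @export
attributable_proportion <- function(or11, or10, or01) {
  .check_ors(or11, or10, or01)
  reri(or11, or10, or01) / or11
}

#' @rdname interaction-measures
#' @export
pure_attributable_proportion <- function(or11, or10, or01) {
  .check_ors(or11, or10, or01)
  if (or11 <= 1)
    .undefined("pure_attributable_proportion undefined: OR11 <= 1")
  reri(or11, or10, or01) / (or11 - 1)
}

#' Bundle the four additive-interaction measures
#'
#' Computes RERI, AP, PAP and SI from one odds-ratio triple. SI and PAP are
#' set to NA (with a note) where undefined rather than failing, so that the
#' bundle can be formed for any valid triple.
#'
#' @inheritParams interaction-measures
#' @return An object of class \code{interaction_measures}: list with
#'   \code{reri}, \code{ap}, \code{pap}, \code{si}, the input \code{ors},
#'   and \code{notes} for undefined components.
#' @export
interaction_measures <- function(or11, or10, or01) {
  .check_ors(or11, or10, or01)
  notes <- character()
  r <- reri(or11, or10, or01)
  ap <- attributable_proportion(or11, or10, or01)
  si <- tryCatch(synergy_index(or11, or10, or01),
                 addint_undefined_measure = function(e) {
                   notes <<- c(notes, conditionMessage(e)); NA_real_ })
  pap <- tryCatch(pure_attributable_proportion(or11, or10, or01),
                  addint_undefined_measure = function(e) {
                    notes <<- c(notes, conditionMessage(e)); NA_real_ })
  structure(list(reri = r, ap = ap, pap = pap, si = si,
                 ors = c(or11 = or11, or10 = or10, or01 = or01),
                 notes = notes),
            class = "interaction_measures")
}

#' Qualitative direction of additive interaction
#'
#' Positive when RERI is above zero (equivalently SI above 1 where SI is
#' defined), negative below zero, none at exactly zero.
#'
#' @param x An \code{interaction_measures} object or a RERI value.
#' @return One of \code{"positive"}, \code{"none"}, \code{"negative"}.
#' @export
classify_interaction <- function(x) {
  r <- if (inherits(x, "interaction_measures")) x$reri else x
  if (r > 0) "positive" else if (r < 0) "negative" else "none"
}

#' Delta-method confidence interval for an interaction measure
#'
#' Normal-approximation interval obtained by expressing the measure as a
#' function of the three log odds ratios and propagating their covariance
#' through the gradient. RERI and AP are handled on their natural scale;
#' SI on the log scale with exponentiated bounds; the PAP interval is the
#' 1 - 1/SI transform of the SI interval.
#'
#' @param measure One of \code{"reri"}, \code{"ap"}, \code{"si"},
#'   \code{"pap"}.
#' @param log_or Length-3 numeric: log OR11, log OR10, log OR01 (the
#'   doubly-exposed, A-only and B-only log odds ratios).
#' @param covariance 3x3 symmetric positive semi-definite covariance matrix
#'   of \code{log_or}, in the same order.
#' @param alpha Two-sided significance level.
#' @return List with \code{estimate}, \code{conf_low}, \code{conf_high},
#'   \code{se} (on the working scale), \code{method = "delta"}.
#' @export
delta_ci <- function(measure = c("reri", "ap", "si", "pap"),
                     log_or, covariance, alpha = 0.05) {
  measure <- match.arg(measure)
  stopifnot(length(log_or) == 3, all(dim(covariance) == c(3, 3)))
  if (max(abs(covariance - t(covariance))) > 1e-8)
    stop("delta_ci: covariance must be symmetric", call. = FALSE)
  if (any(eigen(covariance, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("delta_ci: covariance must be positive semi-definite", call. = FALSE)
  o11 <- exp(log_or[1]); o10 <- exp(log_or[2]); o01 <- exp(log_or[3])
  z <- stats::qnorm(1 - alpha / 2)

  if (measure == "pap") {
    si <- delta_ci("si", log_or, covariance, alpha)
    est <- pure_attributable_proportion(o11, o10, o01)
    return(list(estimate = est,
                conf_low = 1 - 1 / si$conf_low,
                conf_high = 1 - 1 / si$conf_high,
                se = si$se, method = "delta"))
  }

  if (measure == "reri") {
    est <- reri(o11, o10, o01)
    grad <- c(o11, -o10, -o01)
    working <- est
  } else if (measure == "ap") {
    # AP = 1 - e^(b10 - b11) - e^(b01 - b11) + e^(-b11)
    est <- attributable_proportion(o11, o10, o01)
    grad <- c(o10 / o11 + o01 / o11 - 1 / o11,
              -o10 / o11,
              -o01 / o11)
    working <- est
  } else { # si, log scale
    if (o11 <= 1)
      .undefined("delta_ci: log SI undefined, OR11 <= 1")
    denom <- (o10 - 1) + (o01 - 1)
    if (denom <= 0)
      .undefined("delta_ci: log SI undefined, (OR10-1)+(OR01-1) <= 0")
    est <- (o11 - 1) / denom
    grad <- c(o11 / (o11 - 1), -o10 / denom, -o01 / denom)
    working <- log(est)
  }
  se <- sqrt(drop(t(grad) %*% covariance %*% grad))
  lo <- working - z * se
  hi <- working + z * se
  if (measure == "si") { lo <- exp(lo); hi <- exp(hi) }
  list(estimate = est, conf_low = lo, conf_high = hi, se = se,
       method = "delta")
}

#' Interaction measures with delta-method CIs from a 2x4 table
#'
#' Computes the odds-ratio triple and its log-scale covariance from a
#' joint-exposure table (Woolf variance structure with the shared
#' reference cell) and attaches a delta-method CI to each measure.
#'
#' @param table An \code{exposure_table}.
#' @param alpha Two-sided significance level.
#' @param continuity Apply +0.5 correction on zero cells.
#' @return An \code{interaction_measures} object whose components gain
#'   \code{ci} entries: list of per-measure
#'   \code{(estimate, conf_low, conf_high, method)}.
#' @export
estimate_interaction <- function(table, alpha = 0.05, continuity = FALSE) {
  stopifnot(inherits(table, "exposure_table"))
  o11 <- crude_or(table, "both", alpha, continuity)
  o10 <- crude_or(table, "a_only", alpha, continuity)
  o01 <- crude_or(table, "b_only", alpha, continuity)
  m <- interaction_measures(o11$or, o10$or, o01$or)
  b <- c(o11$log_or, o10$log_or, o01$log_or)
  V <- log_or_covariance(table, continuity = continuity)
  m$log_or <- b
  m$covariance <- V
  m$ci <- list()
  for (meas in c("reri", "ap", "pap", "si")) {
    m$ci[[meas]] <- tryCatch(delta_ci(meas, b, V, alpha),
                             addint_undefined_measure = function(e) NULL,
                             error = function(e) NULL)
  }
  m$alpha <- alpha
  m
}

# Recompute one measure from a resampled set of pairs; NA when undefined.
.measure_from_records <- function(df, measure, continuity) {
  tab <- build_exposure_table(df)
  est <- tryCatch({
    o11 <- crude_or(tab, "both", continuity = continuity)$or
    o10 <- crude_or(tab, "a_only", continuity = continuity)$or
    o01 <- crude_or(tab, "b_only", continuity = continuity)$or
    switch(measure,
           reri = reri(o11, o10, o01),
           ap = attributable_proportion(o11, o10, o01),
           pap = pure_attributable_proportion(o11, o10, o01),
           si = synergy_index(o11, o10, o01))
  }, error = function(e) NA_real_)
  est
}

#' Matched-pair bootstrap confidence interval for an interaction measure
#'
#' Resamples matched pairs (the design's exchangeable unit) with
#' replacement, recomputes the measure from each replicate's 2x4 table and
#' returns the percentile interval. Replicates where the measure is
#' undefined (zero cells without continuity, non-positive SI denominator)
#' are dropped and counted; more than 20% undefined attaches a warning.
#'
#' @param dataset A \code{study_dataset} with complete pairs.
#' @param measure One of \code{"reri"}, \code{"ap"}, \code{"pap"},
#'   \code{"si"}.
#' @param B Number of bootstrap replicates (at least 100).
#' @param seed Integer seed (required, for reproducibility).
#' @param alpha Two-sided significance level.
#' @param continuity Apply the +0.5 correction inside replicates with zero
#'   cells (default TRUE; resampling small tables hits zeros routinely).
#' @return List with \code{estimate}, \code{conf_low}, \code{conf_high},
#'   \code{method = "bootstrap"}, \code{B}, \code{n_undefined},
#'   \code{replicates} (the vector of replicate values).
#' @export
bootstrap_ci <- function(dataset, measure = c("reri", "ap", "pap", "si"),
                         B = 2000, seed, alpha = 0.05, continuity = TRUE) {
  measure <- match.arg(measure)
  stopifnot(inherits(dataset, "study_dataset"))
  if (B < 100) stop("bootstrap_ci: B must be at least 100", call. = FALSE)
  if (missing(seed)) stop("bootstrap_ci: 'seed' is required", call. = FALSE)
  df <- dataset$records
  pair_ids <- unique(df$pair_id)
  n <- length(pair_ids)
  if (n < 1) stop("bootstrap_ci: no complete pairs", call. = FALSE)
  by_pair <- split(seq_len(nrow(df)), df$pair_id)

  est <- .measure_from_records(df, measure, continuity)
  set.seed(seed)
  reps <- vapply(seq_len(B), function(i) {
    take <- sample(pair_ids, n, replace = TRUE)
    idx <- unlist(by_pair[take], use.names = FALSE)
    .measure_from_records(df[idx, , drop = FALSE], measure, continuity)
  }, numeric(1))
  n_undef <- sum(is.na(reps))
  if (n_undef > 0.2 * B)
    warning("bootstrap_ci: ", n_undef, " of ", B,
            " replicates had an undefined measure", call. = FALSE)
  ci <- stats::quantile(reps, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE,
                        names = FALSE)
  list(estimate = est, conf_low = ci[1], conf_high = ci[2],
       method = "bootstrap", B = B, n_undefined = n_undef,
       replicates = reps)
}

#' @export
print.interaction_measures <- function(x, ...) {
  fmt <- function(name, value) {
    ci <- x$ci[[name]]
    if (!is.null(ci))
      sprintf("%-5s %8.4f  (%.4f, %.4f) [%s]", toupper(name), value,
              ci$conf_low, ci$conf_high, ci$method)
    else sprintf("%-5s %8.4f", toupper(name), value)
  }
  cat("Additive interaction (OR11 =", format(x$ors["or11"], digits = 5),
      ", OR10 =", format(x$ors["or10"], digits = 5),
      ", OR01 =", format(x$ors["or01"], digits = 5), ")\n")
  for (m in c("reri", "ap", "pap", "si"))
    if (is.finite(x[[m]]) || !is.null(x$ci[[m]])) cat(fmt(m, x[[m]]), "\n")
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  cat("direction:", classify_interaction(x), "\n")
  invisible(x)
}
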