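#' Add joint-exposure indicator columns
#'
#' Recodes two binary exposures into three mutually exclusive indicators
#' against the doubly-unexposed reference: A only, B only, and both. This
#' is the dummy coding whose saturated logistic fit reproduces the 2x4
#' table's crude odds ratios.
#'
#' @param dataset A \code{study_dataset} or data frame.
#' @param exposure_a,exposure_b Names of logical (or 0/1) columns.
#' @return The input with integer columns \code{a_only}, \code{b_only},
#'   \code{both} appended (a data frame, or the records updated in place
#'   for a \code{study_dataset}).
#' @export
joint_exposure_design <- function(dataset,
                                  exposure_a = "family_history",
                                  exposure_b = "bmi_abnormal") {
  is_ds <- inherits(dataset, "study_dataset")
  df <- if (is_ds) dataset$records else dataset
  a <- as.logical(df[[exposure_a]])
  b <- as.logical(df[[exposure_b]])
  if (any(is.na(a)) || any(is.na(b)))
    stop("joint_exposure_design: undetermined exposure", call. = FALSE)
  df$a_only <- as.integer(a & !b)
  df$b_only <- as.integer(!a & b)
  df$both <- as.integer(a & b)
  if (is_ds) { dataset$records <- df; dataset } else df
}

.fit_result <- function(coefficients, covariance, loglik, converged, n_used,
                        alpha = 0.05) {
  se <- sqrt(diag(covariance))
  z <- stats::qnorm(1 - alpha / 2)
  or_table <- data.frame(term = names(coefficients),
                         b = unname(coefficients),
                         se = unname(se),
                         or = exp(unname(coefficients)),
                         conf_low = exp(unname(coefficients) - z * se),
                         conf_high = exp(unname(coefficients) + z * se),
                         p = 2 * stats::pnorm(-abs(unname(coefficients) / se)),
                         row.names = NULL)
  structure(list(coefficients = coefficients, covariance = covariance,
                 or_table = or_table, loglik = loglik,
                 converged = converged, n_used = n_used, alpha = alpha),
            class = "fit_result")
}

.check_design <- function(X) {
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop("rank-deficient design; collinear term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
}

.separation_error <- function(what) {
  stop(structure(class = c("addint_separation", "error", "condition"),
                 list(message = paste0(what,
                        ": apparent separation, estimates diverge"),
                      call = NULL)))
}

#' Unconditional logistic regression for case-control status
#'
#' Maximum-likelihood logistic regression of case status on the given
#' model formula, with Wald confidence intervals on the odds-ratio scale.
#' The design matrix is checked for full rank (collinear terms are an
#' error naming them) and fits showing separation raise a typed error.
#'
#' @param dataset A \code{study_dataset} or data frame with a
#'   \code{status} column coded case/control.
#' @param formula Right-hand-side model formula, e.g.
#'   \code{~ a_only + b_only + both} or \code{~ family_history + sex}.
#'   Categorical terms use ordinary factor contrasts; set the reference
#'   level with \code{stats::relevel} before fitting.
#' @param alpha Significance level for Wald intervals.
#' @return An object of class \code{fit_result}: coefficients, covariance
#'   (inverse observed information), \code{or_table} (term, b, se, or,
#'   conf_low, conf_high, p), \code{loglik}, \code{converged},
#'   \code{n_used}.
#' @export
fit_logistic <- function(dataset, formula, alpha = 0.05) {
  df <- if (inherits(dataset, "study_dataset")) dataset$records else dataset
  y <- as.integer(df$status == "case")
  if (length(unique(y)) < 2)
    stop("fit_logistic: outcome is constant", call. = FALSE)
  mf <- stats::model.frame(formula, data = df)
  used <- match(rownames(mf), rownames(df))
  y <- y[used]
  X <- stats::model.matrix(formula, mf)
  .check_design(X)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)))
  beta <- fit$coefficients
  if (!fit$converged || any(abs(beta) > 15))
    .separation_error("fit_logistic")
  eta <- drop(X %*% beta)
  p <- stats::plogis(eta)
  if (any(p < 1e-10) || any(p > 1 - 1e-10))
    .separation_error("fit_logistic")
  W <- p * (1 - p)
  info <- crossprod(X * sqrt(W))
  covariance <- solve(info)
  dimnames(covariance) <- list(colnames(X), colnames(X))
  ll <- sum(y * eta - log1p(exp(eta)))
  .fit_result(beta, covariance, ll, TRUE, nrow(X), alpha)
}

#' Conditional logistic regression for 1:1 matched pairs
#'
#' Maximizes the conditional likelihood given the pair strata, which for
#' 1:1 matching is equivalent to logistic regression on within-pair
#' covariate differences without an intercept. Matching variables (sex,
#' age) drop out of the likelihood and must not appear in the formula.
#' For a single binary exposure the estimate is the classical
#' discordant-pair ratio.
#'
#' @param dataset A \code{study_dataset} (complete pairs enforced at
#'   construction).
#' @param formula Right-hand-side formula of exposure terms, e.g.
#'   \code{~ family_history} or \code{~ a_only + b_only + both}.
#' @param alpha Significance level for Wald intervals.
#' @return A \code{fit_result}; \code{n_used} is the number of pairs that
#'   are informative (discordant on at least one term).
#' @importFrom survival clogit coxph Surv strata
#' @export
fit_conditional_pairs <- function(dataset, formula, alpha = 0.05) {
  stopifnot(inherits(dataset, "study_dataset"))
  df <- dataset$records
  terms <- attr(stats::terms(formula), "term.labels")
  X <- stats::model.matrix(formula, df)
  X <- X[, colnames(X) != "(Intercept)", drop = FALSE]
  .check_design(X)
  # discordance check per term
  diffs <- do.call(rbind, lapply(split(seq_len(nrow(df)), df$pair_id),
    function(idx) {
      i_case <- idx[df$status[idx] == "case"]
      i_ctrl <- idx[df$status[idx] == "control"]
      X[i_case, , drop = FALSE] - X[i_ctrl, , drop = FALSE]
    }))
  no_info <- colnames(X)[colSums(abs(diffs) > 0) == 0]
  if (length(no_info))
    stop("fit_conditional_pairs: no discordant pairs for term(s): ",
         paste(no_info, collapse = ", "), call. = FALSE)

  y <- as.integer(df$status == "case")
  strata_id <- df$pair_id
  f <- stats::as.formula(paste("y ~",
                               paste(colnames(diffs), collapse = " + "),
                               "+ strata(strata_id)"))
  dat <- data.frame(y = y, X, strata_id = strata_id, check.names = FALSE)
  names(dat)[seq_len(ncol(X)) + 1] <- colnames(X)
  fit <- tryCatch(
    clogit(f, data = dat,
           control = survival::coxph.control(eps = 1e-10, iter.max = 100)),
    warning = function(w) .separation_error("fit_conditional_pairs"),
    error = function(e) stop(e))
  beta <- stats::coef(fit)
  if (any(!is.finite(beta)) || any(abs(beta) > 15))
    .separation_error("fit_conditional_pairs")
  covariance <- stats::vcov(fit)
  informative <- sum(rowSums(abs(diffs) > 0) > 0)
  .fit_result(beta, as.matrix(covariance), fit$loglik[2], TRUE, informative,
              alpha)
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Logistic fit (n =", x$n_used, ", logLik =",
      format(x$loglik, digits = 6), ")\n")
  print(transform(x$or_table,
                  b = round(b, 4), se = round(se, 4), or = round(or, 3),
                  conf_low = round(conf_low, 3),
                  conf_high = round(conf_high, 3),
                  p = signif(p, 3)))
  invisible(x)
}
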