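# Joint-exposure coefficient at which the default configuration's
# model-implied RERI equals 5.67 (output of calibrate_beta_int under the
# simulation_config defaults; the multiplicative main effects alone would
# already be super-additive, so the calibrated value is mildly negative).
.default_beta_int <- -0.246262740884236

#' Configuration of the matched case-control study generator
#'
#' Defines the generative model for a synthetic 1:1 sex- and age-matched
#' case-control study of two interacting risk factors: a binary family
#' history (FH) and BMI category. Disease arises from a logistic model on
#' FH, BMI category, and an extra log-odds term for the jointly exposed
#' (FH and abnormal BMI) state; the size of that term controls the
#' additive-scale interaction (see \code{\link{calibrate_beta_int}}).
#'
#' Defaults describe a 342-pair study of adults aged 28-87 with exposure
#' prevalences and anthropometric distributions in the range of the
#' motivating published hypertension study: population BMI about
#' N(23.5, 3.2^2) kg/m^2, FH prevalence 0.62, and main-effect odds ratios
#' near 4.99 (FH), 1.53 / 3.33 / 7.31 (low / overweight / obese BMI).
#' The default \code{beta_int} is calibrated so the model-implied RERI is
#' 5.67.
#'
#' @param n_pairs Number of matched pairs (default 342).
#' @param seed Integer seed driving all randomness.
#' @param p_fh FH prevalence among normal-BMI individuals.
#' @param fh_bmi_log_or Log odds-ratio association between FH and abnormal
#'   BMI in the source population (0 = independent, the default).
#' @param bmi_mean,bmi_sd Population continuous-BMI distribution (kg/m^2).
#' @param beta0 Baseline log-odds of disease (FH absent, normal BMI).
#' @param beta_fh,beta_low,beta_over,beta_obese Log-odds effects of FH and
#'   of the low/overweight/obese BMI categories.
#' @param beta_int Extra log-odds for the FH-and-abnormal-BMI joint state.
#' @param age_mean,age_sd,age_range Age distribution (truncated normal,
#'   years).
#' @param anthro Named list: \code{height_mean}, \code{height_sd} (cm);
#'   \code{wc_mean}, \code{wc_slope}, \code{wc_sd}; \code{hc_mean},
#'   \code{hc_slope}, \code{hc_sd} — waist and hip circumference (cm)
#'   modelled as linear in BMI around \code{bmi_mean} plus Gaussian
#'   residual.
#' @return A validated list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_pairs = 342,
                              seed = 1L,
                              p_fh = 0.62,
                              fh_bmi_log_or = 0,
                              bmi_mean = 23.5, bmi_sd = 3.2,
                              beta0 = -2.2,
                              beta_fh = log(4.986),
                              beta_low = log(1.528),
                              beta_over = log(3.333),
                              beta_obese = log(7.312),
                              beta_int = NULL,
                              age_mean = 62, age_sd = 10.7,
                              age_range = c(28, 87),
                              anthro = list(height_mean = 163.1,
                                            height_sd = 8.0,
                                            wc_mean = 83.7, wc_slope = 2.5,
                                            wc_sd = 6.5,
                                            hc_mean = 92.8, hc_slope = 2.0,
                                            hc_sd = 6.9)) {
  cfg <- list(n_pairs = n_pairs, seed = as.integer(seed), p_fh = p_fh,
              fh_bmi_log_or = fh_bmi_log_or,
              bmi_mean = bmi_mean, bmi_sd = bmi_sd,
              beta0 = beta0, beta_fh = beta_fh, beta_low = beta_low,
              beta_over = beta_over, beta_obese = beta_obese,
              beta_int = beta_int, age_mean = age_mean, age_sd = age_sd,
              age_range = age_range, anthro = anthro)
  if (is.null(cfg$beta_int)) cfg$beta_int <- .default_beta_int
  if (n_pairs < 1) stop("simulation_config: n_pairs must be >= 1", call. = FALSE)
  if (p_fh <= 0 || p_fh >= 1)
    stop("simulation_config: p_fh must lie in (0, 1)", call. = FALSE)
  if (bmi_sd <= 0 || age_sd <= 0)
    stop("simulation_config: scale parameters must be positive", call. = FALSE)
  if (length(age_range) != 2 || age_range[1] >= age_range[2])
    stop("simulation_config: age_range must be increasing", call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

# Probabilities of the four BMI categories under the configured
# continuous-BMI normal distribution.
.bmi_category_probs <- function(cfg) {
  q <- stats::pnorm(c(18.5, 24, 28), cfg$bmi_mean, cfg$bmi_sd)
  c(low = q[1], normal = q[2] - q[1], overweight = q[3] - q[2],
    obese = 1 - q[3])
}

# Disease log-odds for given FH (0/1) and BMI category label.
.disease_eta <- function(cfg, fh, category) {
  abn <- category != "normal"
  cfg$beta0 +
    cfg$beta_fh * fh +
    cfg$beta_low * (category == "low") +
    cfg$beta_over * (category == "overweight") +
    cfg$beta_obese * (category == "obese") +
    cfg$beta_int * fh * abn
}

# FH probability given abnormal-BMI state (odds-scale association).
.p_fh_given <- function(cfg, abnormal) {
  stats::plogis(stats::qlogis(cfg$p_fh) + cfg$fh_bmi_log_or * abnormal)
}

# Marginal disease probability under the configured covariate model.
.model_prevalence <- function(cfg) {
  cats <- c("low", "normal", "overweight", "obese")
  pc <- .bmi_category_probs(cfg)
  grid <- expand.grid(fh = 0:1, category = cats, stringsAsFactors = FALSE)
  abn <- grid$category != "normal"
  p_fh <- .p_fh_given(cfg, abn)
  w <- pc[grid$category] * ifelse(grid$fh == 1, p_fh, 1 - p_fh)
  sum(w * stats::plogis(.disease_eta(cfg, grid$fh, grid$category)))
}

#' Model-implied joint-exposure odds ratios and interaction measures
#'
#' Computes the exact theoretical odds ratios of the four (FH, abnormal
#' BMI) joint-exposure cells under the configured generative model, by
#' summing case and control mass over the FH-by-BMI-category covariate
#' distribution (the BMI-category mixture makes the abnormal cells
#' heterogeneous, so aggregation is done on the probability scale, not on
#' the coefficients). The implied RERI, AP, PAP and SI follow from the
#' odds-ratio triple.
#'
#' @param config A \code{simulation_config}.
#' @return List of class \code{simulation_truth}: \code{or11},
#'   \code{or10}, \code{or01}, \code{reri}, \code{ap}, \code{pap},
#'   \code{si}, \code{prevalence} (marginal disease probability).
#' @export
theoretical_measures <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cats <- c("low", "normal", "overweight", "obese")
  pc <- .bmi_category_probs(config)
  grid <- expand.grid(fh = 0:1, category = cats, stringsAsFactors = FALSE)
  abn <- grid$category != "normal"
  p_fh <- .p_fh_given(config, abn)
  grid$w <- pc[grid$category] * ifelse(grid$fh == 1, p_fh, 1 - p_fh)
  grid$p <- stats::plogis(.disease_eta(config, grid$fh, grid$category))

  cell_odds <- function(fh, abnormal) {
    sel <- grid$fh == fh & (grid$category != "normal") == abnormal
    sum(grid$w[sel] * grid$p[sel]) / sum(grid$w[sel] * (1 - grid$p[sel]))
  }
  ref <- cell_odds(0, FALSE)
  or11 <- cell_odds(1, TRUE) / ref
  or10 <- cell_odds(1, FALSE) / ref
  or01 <- cell_odds(0, TRUE) / ref
  if (any(!is.finite(c(or11, or10, or01))))
    stop("theoretical_measures: configuration implies degenerate ",
         "(0 or 1) disease probabilities", call. = FALSE)
  if (abs(or11 - 1) < 1e-12 && abs(or10 - 1) < 1e-12 &&
      abs(or01 - 1) < 1e-12) {
    # exact global null: SI -> 1 and PAP -> 0 in the additive limit
    m <- list(reri = 0, ap = 0, pap = 0, si = 1)
  } else {
    m <- interaction_measures(or11, or10, or01)
  }
  structure(list(or11 = or11, or10 = or10, or01 = or01,
                 reri = m$reri, ap = m$ap, pap = m$pap, si = m$si,
                 prevalence = sum(grid$w * grid$p)),
            class = "simulation_truth")
}

#' Calibrate the joint-exposure interaction coefficient to a target RERI
#'
#' Root-finds the \code{beta_int} value at which the model-implied RERI of
#' \code{\link{theoretical_measures}} equals the target. The implied RERI
#' is continuous and increasing in \code{beta_int}, so the root is unique.
#'
#' @param config A \code{simulation_config} (its \code{beta_int} is
#'   ignored).
#' @param target_reri Desired model-implied RERI.
#' @param interval Search interval for \code{beta_int}.
#' @return The calibrated \code{beta_int} (numeric scalar).
#' @export
calibrate_beta_int <- function(config, target_reri, interval = c(-6, 6)) {
  stopifnot(inherits(config, "simulation_config"))
  f <- function(b) {
    cfg <- config
    cfg$beta_int <- b
    theoretical_measures(cfg)$reri - target_reri
  }
  stats::uniroot(f, interval, tol = 1e-10)$root
}

#' Simulate a source population
#'
#' Draws individuals from the configured covariate model and assigns
#' disease from the logistic risk model. Sex is Bernoulli(0.5) and age a
#' truncated normal, both independent of the exposures (so matching on
#' them does not distort exposure odds ratios). Weight is back-solved
#' from continuous BMI and height; waist and hip circumference are linear
#' in BMI plus Gaussian residual. Anthropometric measurements are rounded
#' to 0.1 (cm or kg), age to whole years.
#'
#' @param config A \code{simulation_config}.
#' @param n Number of individuals.
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return Data frame with sex, age, family_history, bmi_true,
#'   bmi_category, height_cm, weight_kg, waist_cm, hip_cm, disease.
#' @export
simulate_population <- function(config, n, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) set.seed(seed)
  cfg <- config
  # guard against degenerate risk configurations
  pr <- .model_prevalence(cfg)
  if (pr < 1e-6 || pr > 1 - 1e-6)
    stop("simulate_population: configuration implies disease probability ",
         "0 or 1 everywhere", call. = FALSE)

  sex <- ifelse(stats::runif(n) < 0.5, "male", "female")
  age <- stats::qnorm(stats::runif(n,
                                   stats::pnorm(cfg$age_range[1], cfg$age_mean, cfg$age_sd),
                                   stats::pnorm(cfg$age_range[2], cfg$age_mean, cfg$age_sd)),
                      cfg$age_mean, cfg$age_sd)
  bmi <- stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd)
  while (any(bmi <= 10))
    bmi[bmi <= 10] <- stats::rnorm(sum(bmi <= 10), cfg$bmi_mean, cfg$bmi_sd)
  category <- as.character(categorize_bmi(bmi))
  abn <- category != "normal"
  fh <- stats::runif(n) < .p_fh_given(cfg, abn)

  a <- cfg$anthro
  height <- round(stats::rnorm(n, a$height_mean, a$height_sd), 1)
  waist <- round(a$wc_mean + a$wc_slope * (bmi - cfg$bmi_mean) +
                   stats::rnorm(n, 0, a$wc_sd), 1)
  hip <- round(a$hc_mean + a$hc_slope * (bmi - cfg$bmi_mean) +
                 stats::rnorm(n, 0, a$hc_sd), 1)
  waist <- pmax(waist, 40); hip <- pmax(hip, 50)
  weight <- round(bmi * (height / 100)^2, 1)

  p <- stats::plogis(.disease_eta(cfg, as.integer(fh), category))
  disease <- stats::runif(n) < p

  data.frame(sex = sex, age = round(age), family_history = fh,
             bmi_true = bmi, bmi_category = category,
             height_cm = height, weight_kg = weight,
             waist_cm = waist, hip_cm = hip, disease = disease,
             stringsAsFactors = FALSE)
}

#' Draw a 1:1 sex- and age-matched study from a simulated cohort
#'
#' Samples cases without replacement; for each case one eligible
#' non-diseased control (same sex, age difference at most 5 years) is
#' sampled without replacement. Cases without any remaining eligible
#' control are skipped; if fewer than \code{n_pairs} pairs can be formed
#' an error reports the achievable count.
#'
#' @param cohort Data frame from \code{\link{simulate_population}}.
#' @param n_pairs Number of pairs to form.
#' @param seed Optional seed; NULL continues the current RNG stream.
#' @return A \code{study_dataset}.
#' @export
sample_matched_study <- function(cohort, n_pairs, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  case_idx <- sample(which(cohort$disease))
  ctrl_idx <- which(!cohort$disease)
  used <- rep(FALSE, length(ctrl_idx))
  pairs_case <- integer(0)
  pairs_ctrl <- integer(0)
  for (i in case_idx) {
    if (length(pairs_case) >= n_pairs) break
    elig <- !used &
      cohort$sex[ctrl_idx] == cohort$sex[i] &
      abs(cohort$age[ctrl_idx] - cohort$age[i]) <= 5
    w <- which(elig)
    if (!length(w)) next
    j <- if (length(w) == 1) w else sample(w, 1)
    used[j] <- TRUE
    pairs_case <- c(pairs_case, i)
    pairs_ctrl <- c(pairs_ctrl, ctrl_idx[j])
  }
  if (length(pairs_case) < n_pairs)
    stop("sample_matched_study: only ", length(pairs_case),
         " of ", n_pairs, " pairs achievable with eligible controls",
         call. = FALSE)

  take <- function(idx, status, pair_no) {
    data.frame(subject_id = paste0("s", idx),
               pair_id = sprintf("p%04d", pair_no),
               status = status,
               sex = cohort$sex[idx], age = cohort$age[idx],
               height_cm = cohort$height_cm[idx],
               weight_kg = cohort$weight_kg[idx],
               waist_cm = cohort$waist_cm[idx],
               hip_cm = cohort$hip_cm[idx],
               family_history = cohort$family_history[idx],
               stringsAsFactors = FALSE)
  }
  df <- rbind(take(pairs_case, "case", seq_len(n_pairs)),
              take(pairs_ctrl, "control", seq_len(n_pairs)))
  df <- df[order(df$pair_id, df$status), ]
  study_dataset(df)
}

#' Simulate a complete matched case-control study
#'
#' End-to-end generator: sizes a source cohort from the model-implied
#' disease prevalence, simulates it, and draws the matched study. All
#' randomness flows from \code{config$seed}.
#'
#' @param config A \code{simulation_config}.
#' @return A \code{study_dataset} with \code{attr(, "truth")} set to the
#'   \code{\link{theoretical_measures}} of the configuration.
#' @export
simulate_matched_study <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  truth <- theoretical_measures(config)
  n <- ceiling(config$n_pairs / min(truth$prevalence, 1 - truth$prevalence) * 1.4)
  for (attempt in 1:3) {
    cohort <- simulate_population(config, n)
    ds <- tryCatch(sample_matched_study(cohort, config$n_pairs),
                   error = function(e) NULL)
    if (!is.null(ds)) {
      attr(ds, "truth") <- truth
      return(ds)
    }
    n <- n * 2
  }
  stop("simulate_matched_study: could not form ", config$n_pairs,
       " pairs; increase the cohort or relax the configuration",
       call. = FALSE)
}

#' @export
print.simulation_truth <- function(x, ...) {
  cat(sprintf(paste0("Model-implied joint-exposure ORs: OR11 = %.3f, ",
                     "OR10 = %.3f, OR01 = %.3f\n"),
              x$or11, x$or10, x$or01))
  cat(sprintf("Implied RERI = %.3f, AP = %.4f, PAP = %.4f, SI = %.3f\n",
              x$reri, x$ap, x$pap, x$si))
  cat(sprintf("Marginal disease prevalence: %.3f\n", x$prevalence))
  invisible(x)
}
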