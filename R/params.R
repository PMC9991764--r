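#' Parameters of the synthetic-cohort generator
#'
#' Builds a validated parameter set describing the study conditions the
#' generator emulates: a high cardiovascular-risk cohort whose mean 24-h
#' urinary sodium, demographic mix and attrition match the population the
#' package's method-comparison battery is designed for. The defaults encode
#' those conditions and are not meant to be tuned per run:
#'
#' * `mean_true_na = 3122.7` mg/d of true usual intake, so that with 90%
#'   urinary excretion the expected 24-h urinary sodium is 2810.4 mg/d;
#' * `excretion_fraction = 0.90`: fraction of ingested sodium excreted in
#'   urine over 24 h;
#' * `recall_underreport_mean = 0.62`: mean multiplicative underreporting
#'   factor of the 24-h recalls (participant-level, truncated normal on
#'   (0, 1.2]);
#' * `discretionary_share = 0.15`: share of total intake from cooking and
#'   table salt, invisible to composition-table scoring;
#' * `incomplete_collection_rate = 0.074`: fraction of 24-h collections that
#'   violate completeness rules;
#' * availability fractions (`avail_*`) reproduce per-instrument sample
#'   sizes of 71/122 (spot), 119/122 (recalls), 87/122 (FFQ), 60/122 (NaFFQ).
#'
#' @param n_participants cohort size (>= 2).
#' @param mean_true_na,cv_true_na mean (mg/d) and coefficient of variation of
#'   true usual sodium intake (log-normal across participants).
#' @param excretion_fraction fraction of intake excreted in a 24-h urine.
#' @param day_cv_urine day-to-day CV of 24-h urinary excretion
#'   (multiplicative, mean-one log-normal).
#' @param recall_underreport_mean,recall_underreport_sd mean and SD of the
#'   participant-level recall underreporting factor, truncated to (0, 1.2].
#' @param recall_day_cv day-to-day CV of reported recall totals (mean-one).
#' @param discretionary_share share of true intake that is discretionary.
#' @param ffq_error_cv participant-level CV of FFQ reporting error.
#' @param ffq_underreport_mean mean multiplicative underreporting factor of
#'   the standard FFQ's food-sodium capture.
#' @param naffq_underreport_mean same factor for the sodium-extended FFQ;
#'   defaults to 1 (the extended Na-rich food list is assumed to capture
#'   food sodium completely).
#' @param spot_noise_cv CV of spot-urine concentration noise.
#' @param spot_correlation exponent linking spot concentrations to the same
#'   day's 24-h excretion on the log scale (0 = independent, 1 = proportional).
#' @param spot_overestimation multiplicative calibration factor on spot
#'   sodium concentration; values > 1 make every spot equation overestimate.
#' @param incomplete_collection_rate fraction of collections injected as
#'   incomplete (recorded volume scaled below the completeness threshold).
#' @param pct_male,age_mean,age_sd demographic targets.
#' @param avail_spot,avail_recall,avail_ffq,avail_naffq per-instrument
#'   availability fractions (independent Bernoulli per participant).
#' @param seed integer root seed; every data type draws from its own named
#'   substream derived from it, so adding a stream never perturbs others.
#' @return an object of class `generator_params` (a named list).
#' @seealso [generate_cohort()]
#' @export
generator_params <- function(n_participants = 122,
                             mean_true_na = 3122.7,
                             cv_true_na = 0.39,
                             excretion_fraction = 0.90,
                             day_cv_urine = 0.25,
                             recall_underreport_mean = 0.62,
                             recall_underreport_sd = 0.15,
                             recall_day_cv = 0.20,
                             discretionary_share = 0.15,
                             ffq_error_cv = 0.35,
                             ffq_underreport_mean = 0.60,
                             naffq_underreport_mean = 1.0,
                             spot_noise_cv = 0.35,
                             spot_correlation = 0.6,
                             spot_overestimation = 1.0,
                             incomplete_collection_rate = 0.074,
                             pct_male = 0.557,
                             age_mean = 56.0,
                             age_sd = 12.6,
                             avail_spot = 71 / 122,
                             avail_recall = 119 / 122,
                             avail_ffq = 87 / 122,
                             avail_naffq = 60 / 122,
                             seed = 1L) {
  p <- list(
    n_participants = n_participants,
    mean_true_na = mean_true_na,
    cv_true_na = cv_true_na,
    excretion_fraction = excretion_fraction,
    day_cv_urine = day_cv_urine,
    recall_underreport_mean = recall_underreport_mean,
    recall_underreport_sd = recall_underreport_sd,
    recall_day_cv = recall_day_cv,
    discretionary_share = discretionary_share,
    ffq_error_cv = ffq_error_cv,
    ffq_underreport_mean = ffq_underreport_mean,
    naffq_underreport_mean = naffq_underreport_mean,
    spot_noise_cv = spot_noise_cv,
    spot_correlation = spot_correlation,
    spot_overestimation = spot_overestimation,
    incomplete_collection_rate = incomplete_collection_rate,
    pct_male = pct_male,
    age_mean = age_mean,
    age_sd = age_sd,
    avail_spot = avail_spot,
    avail_recall = avail_recall,
    avail_ffq = avail_ffq,
    avail_naffq = avail_naffq,
    seed = as.integer(seed)
  )
  validate_generator_params(p)
  structure(p, class = "generator_params")
}

validate_generator_params <- function(p) {
  bad <- function(field, why) {
    stop(sprintf("invalid generator parameter `%s`: %s", field, why),
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      bad(field, "must be a single finite number")
    }
    v
  }
  if (num1("n_participants") < 2) bad("n_participants", "must be >= 2")
  if (num1("mean_true_na") <= 0) bad("mean_true_na", "must be > 0")
  for (f in c("cv_true_na", "day_cv_urine", "recall_day_cv", "ffq_error_cv",
              "spot_noise_cv", "age_sd", "recall_underreport_sd")) {
    if (num1(f) < 0) bad(f, "must be >= 0")
  }
  for (f in c("excretion_fraction", "discretionary_share",
              "incomplete_collection_rate", "pct_male",
              "avail_spot", "avail_recall", "avail_ffq", "avail_naffq",
              "spot_correlation")) {
    v <- num1(f)
    if (v < 0 || v > 1) bad(f, "must be a fraction in [0, 1]")
  }
  for (f in c("recall_underreport_mean", "ffq_underreport_mean",
              "naffq_underreport_mean")) {
    m <- num1(f)
    if (m <= 0 || m > 1.2) bad(f, "must be in (0, 1.2]")
  }
  if (num1("spot_overestimation") <= 0) bad("spot_overestimation", "must be > 0")
  if (num1("age_mean") <= 0) bad("age_mean", "must be > 0")
  s <- p$seed
  if (!is.numeric(s) || length(s) != 1L || is.na(s)) bad("seed", "must be an integer")
  invisible(p)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("<generator_params>\n")
  for (nm in names(x)) cat(sprintf("  %-27s %s\n", nm, format(x[[nm]])))
  invisible(x)
}
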