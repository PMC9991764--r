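# Method-comparison battery against the 24-h collection: bias with paired
# tests routed by a Lilliefors normality check, Pearson/Spearman
# correlations, two-way single-measure ICC with F-based confidence limits,
# and Bland-Altman limits of agreement with proportional-bias regression.
# Sign convention throughout: difference = reference - estimate, so a method
# that overestimates intake has negative bias.

check_paired <- function(reference, estimate, min_n = 3) {
  if (length(reference) != length(estimate)) {
    stop("`reference` and `estimate` must have equal length", call. = FALSE)
  }
  keep <- is.finite(reference) & is.finite(estimate)
  if (sum(keep) < min_n) {
    stop(sprintf("insufficient data: %d complete pairs, need >= %d",
                 sum(keep), min_n), call. = FALSE)
  }
  list(reference = reference[keep], estimate = estimate[keep], n = sum(keep))
}

#' Lilliefors-corrected normality check
#'
#' One-sample Kolmogorov-Smirnov test against a normal distribution with
#' estimated mean and SD, using the Lilliefors correction (the plain KS test
#' with estimated parameters is anticonservative). Used to route paired
#' t-test vs Wilcoxon and to qualify Pearson vs Spearman emphasis; with
#' fewer than 5 values or zero variance the routing falls back to
#' nonparametric with a warning.
#'
#' @param x numeric vector.
#' @param alpha routing threshold on the p-value.
#' @return a list with `p` (possibly `NA`), `normal` (logical) and `route`
#'   (`"parametric"` or `"nonparametric"`).
#' @export
ks_normality <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 5 || sd(x) == 0) {
    warning("normality not assessable (n < 5 or constant); routing nonparametric",
            call. = FALSE)
    return(list(p = NA_real_, normal = FALSE, route = "nonparametric"))
  }
  p <- nortest::lillie.test(x)$p.value
  list(p = p, normal = p >= alpha,
       route = if (p >= alpha) "parametric" else "nonparametric")
}

#' Bias of a method against the reference
#'
#' Differences are `reference - estimate`; the mean and sample SD (n-1) are
#' reported together with a paired-test p-value: a paired t-test when the
#' differences pass the Lilliefors normality check, otherwise a Wilcoxon
#' signed-rank test (exact for n <= 25 without ties or zeros, normal
#' approximation with continuity correction otherwise).
#'
#' @param reference,estimate aligned numeric vectors, mg/day.
#' @return list with `n`, `bias_mean`, `bias_sd`, `p_paired`, `test`.
#' @export
bias_stats <- function(reference, estimate) {
  s <- check_paired(reference, estimate)
  d <- s$reference - s$estimate
  bias_mean <- mean(d)
  bias_sd <- sd(d)
  if (all(d == 0)) {
    return(list(n = s$n, bias_mean = 0, bias_sd = 0, p_paired = 1,
                test = "wilcoxon (degenerate)"))
  }
  route <- suppressWarnings(ks_normality(d)$route)
  if (route == "parametric") {
    p <- t.test(s$reference, s$estimate, paired = TRUE)$p.value
    test <- "paired t"
  } else {
    exact <- s$n <= 25 && !any(d == 0) && !any(duplicated(abs(d)))
    p <- suppressWarnings(
      wilcox.test(d, exact = exact, correct = TRUE)$p.value)
    test <- "wilcoxon"
  }
  list(n = s$n, bias_mean = bias_mean, bias_sd = bias_sd, p_paired = p,
       test = test)
}

#' Pearson and Spearman correlation of a method with the reference
#'
#' Product-moment and rank correlations with p-values; ties receive average
#' ranks. Zero variance in either series yields an explicit undefined
#' result (`NA` with `defined = FALSE`) rather than a silent zero.
#'
#' @param reference,estimate aligned numeric vectors.
#' @return list with `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`,
#'   `defined`.
#' @export
paired_correlations <- function(reference, estimate) {
  s <- check_paired(reference, estimate)
  if (sd(s$reference) == 0 || sd(s$estimate) == 0) {
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                defined = FALSE))
  }
  pe <- cor.test(s$reference, s$estimate, method = "pearson")
  sp <- suppressWarnings(
    cor.test(s$reference, s$estimate, method = "spearman", exact = FALSE))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       defined = TRUE)
}

#' Two-way single-measure intraclass correlation
#'
#' ICC from the two-way mean squares with methods as columns and
#' participants as rows, in either the absolute-agreement form (default;
#' sensitive to systematic offsets between methods) or the consistency
#' form. 95% confidence limits follow the F-distribution formulas of
#' McGraw & Wong; when the error mean square vanishes (e.g. identical
#' series) the interval degenerates and is flagged.
#'
#' @param reference,estimate aligned numeric vectors.
#' @param form `"absolute_agreement"` or `"consistency"`.
#' @param conf_level confidence level of the interval.
#' @return list with `icc`, `ci_low`, `ci_high`, `form`, `degenerate`.
#' @export
icc_estimate <- function(reference, estimate,
                         form = c("absolute_agreement", "consistency"),
                         conf_level = 0.95) {
  form <- match.arg(form)
  s <- check_paired(reference, estimate, min_n = 5)
  x <- cbind(s$reference, s$estimate)
  n <- nrow(x)
  k <- 2
  grand <- mean(x)
  msr <- k * sum((rowMeans(x) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(x) - grand)^2) / (k - 1)
  sse <- sum((x - grand)^2) - (n - 1) * msr - (k - 1) * msc
  mse <- sse / ((n - 1) * (k - 1))
  mse <- max(mse, 0) # numerical guard
  denom_a <- msr + (k - 1) * mse + k / n * (msc - mse)
  denom_c <- msr + (k - 1) * mse
  icc <- if (form == "absolute_agreement") {
    if (denom_a <= 0) 1 else (msr - mse) / denom_a
  } else {
    if (denom_c <= 0) 1 else (msr - mse) / denom_c
  }
  alpha <- 1 - conf_level
  if (mse <= .Machine$double.eps * grand^2 || !is.finite(icc)) {
    return(list(icc = icc, ci_low = icc, ci_high = icc, form = form,
                degenerate = TRUE))
  }
  if (form == "consistency") {
    fv <- msr / mse
    fl <- fv / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- fv * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (fl - 1) / (fl + k - 1)
    hi <- (fu - 1) / (fu + k - 1)
  } else {
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    fl <- qf(1 - alpha / 2, n - 1, v)
    fu <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - fl * mse) /
      (fl * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (fu * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * fu * msr)
  }
  list(icc = icc, ci_low = max(-1, min(lo, icc)),
       ci_high = min(1, max(hi, icc)), form = form, degenerate = FALSE)
}

#' Koo-Li reliability bands for the ICC
#'
#' `< 0.5` poor, `[0.5, 0.75)` moderate, `[0.75, 0.9)` good,
#' `>= 0.9` excellent.
#'
#' @param value numeric ICC values (<= 1).
#' @return character vector of band labels.
#' @examples
#' classify_icc(c(0.49, 0.66, 0.8, 0.95))
#' @export
classify_icc <- function(value) {
  if (any(value > 1 + 1e-12, na.rm = TRUE)) {
    stop("ICC values cannot exceed 1", call. = FALSE)
  }
  cut(value, breaks = c(-Inf, 0.5, 0.75, 0.9, Inf), right = FALSE,
      labels = c("poor", "moderate", "good", "excellent")) |>
    as.character()
}

#' Bland-Altman agreement analysis
#'
#' Per-pair means and differences (`reference - estimate`), limits of
#' agreement `bias_mean +/- 1.96 x bias_sd` (the literal 1.96, matching the
#' conventional arithmetic), and the proportional-bias regression of
#' difference on mean (OLS slope with its p-value).
#'
#' @param reference,estimate aligned numeric vectors.
#' @param participant_id optional identifiers carried into the per-pair data.
#' @return list with `data` (tibble of `mean`/`difference`), `bias_mean`,
#'   `bias_sd`, `loa_lower`, `loa_upper`, `prop_bias_slope`, `prop_bias_p`.
#' @export
bland_altman <- function(reference, estimate, participant_id = NULL) {
  s <- check_paired(reference, estimate)
  d <- s$reference - s$estimate
  m <- (s$reference + s$estimate) / 2
  bias_mean <- mean(d)
  bias_sd <- sd(d)
  loa <- loa_limits(bias_mean, bias_sd)
  if (sd(m) == 0 || sd(d) == 0) {
    slope <- if (sd(d) == 0) 0 else NA_real_
    slope_p <- NA_real_
  } else {
    # a perfect linear relation between difference and mean is legitimate
    # here (e.g. estimate proportional to reference); silence lm's note
    fit <- suppressWarnings(summary(lm(d ~ m)))$coefficients
    slope <- fit["m", "Estimate"]
    slope_p <- fit["m", "Pr(>|t|)"]
  }
  data <- tibble::tibble(mean = m, difference = d)
  if (!is.null(participant_id)) {
    data <- tibble::tibble(participant_id = participant_id[
      is.finite(reference) & is.finite(estimate)], data)
  }
  list(data = data, bias_mean = bias_mean, bias_sd = bias_sd,
       loa_lower = loa[1], loa_upper = loa[2],
       prop_bias_slope = slope, prop_bias_p = slope_p)
}

#' @rdname bland_altman
#' @param bias_mean,bias_sd mean and SD of the paired differences, mg/day.
#' @return `loa_limits()`: numeric length-2 vector `c(lower, upper)`.
#' @examples
#' round(loa_limits(-290.2, 1336.2), 1) # -2909.2 2328.8
#' @export
loa_limits <- function(bias_mean, bias_sd) {
  c(bias_mean - 1.96 * bias_sd, bias_mean + 1.96 * bias_sd)
}

#' Compare every estimation method against the 24-h collection
#'
#' Builds the full per-method comparison table: per-method n
#' (pairwise-complete against the reference), estimate mean/SD, bias with a
#' paired-test p-value, Pearson/Spearman correlations, ICC (chosen form,
#' with the consistency form alongside) with its 95% CI and Koo-Li band,
#' Bland-Altman limits of agreement and the proportional-bias regression.
#' With `sensitivity = TRUE` participants with incomplete collections are
#' excluded first (sensitivity analysis).
#'
#' @param estimates long estimates table (`participant_id`, `method_id`,
#'   `na_mg_per_day`), see [score_cohort()].
#' @param completeness optional tibble `participant_id`/`complete` from
#'   [screen_completeness()] (required when `sensitivity = TRUE`).
#' @param sensitivity drop incomplete collections before comparing.
#' @param icc_form form of the reported ICC, see [icc_estimate()].
#' @param reference method id of the reference, normally `"u24"`.
#' @return a tibble with one row per non-reference method.
#' @export
compare_all <- function(estimates, completeness = NULL, sensitivity = FALSE,
                        icc_form = "absolute_agreement", reference = "u24") {
  if (!reference %in% estimates$method_id) {
    stop(sprintf("reference method `%s` absent from estimates", reference),
         call. = FALSE)
  }
  if (sensitivity) {
    if (is.null(completeness)) {
      stop("`completeness` flags are required for the sensitivity analysis",
           call. = FALSE)
    }
    keep <- completeness$participant_id[as.logical(completeness$complete)]
    estimates <- estimates[estimates$participant_id %in% keep, ]
  }
  ref <- estimates[estimates$method_id == reference, ]
  methods <- setdiff(unique(estimates$method_id), reference)
  methods <- intersect(method_ids(), methods) # stable order
  rows <- lapply(methods, function(mid) {
    est <- estimates[estimates$method_id == mid, ]
    m <- match(ref$participant_id, est$participant_id)
    pair <- tibble::tibble(reference = ref$na_mg_per_day,
                           estimate = est$na_mg_per_day[m])
    pair <- pair[complete.cases(pair), ]
    n <- nrow(pair)
    if (n < 5) {
      return(tibble::tibble(method_id = mid, n = n))
    }
    b <- bias_stats(pair$reference, pair$estimate)
    co <- paired_correlations(pair$reference, pair$estimate)
    ic <- icc_estimate(pair$reference, pair$estimate, form = icc_form)
    icc_c <- icc_estimate(pair$reference, pair$estimate, form = "consistency")
    ba <- bland_altman(pair$reference, pair$estimate)
    tibble::tibble(
      method_id = mid, n = n,
      mean_estimate = mean(pair$estimate), sd_estimate = sd(pair$estimate),
      bias_mean = b$bias_mean, bias_sd = b$bias_sd,
      p_paired = b$p_paired, paired_test = b$test,
      pearson_r = co$pearson_r, pearson_p = co$pearson_p,
      spearman_rho = co$spearman_rho, spearman_p = co$spearman_p,
      icc = ic$icc, icc_ci_low = ic$ci_low, icc_ci_high = ic$ci_high,
      icc_form = ic$form, icc_class = classify_icc(ic$icc),
      icc_consistency = icc_c$icc,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      prop_bias_slope = ba$prop_bias_slope, prop_bias_p = ba$prop_bias_p
    )
  })
  dplyr::bind_rows(rows)
}
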