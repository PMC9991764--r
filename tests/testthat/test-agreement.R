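test_that("bias statistics use the reference-minus-estimate convention", {
  ref <- c(2800, 3100, 2500, 2900, 3300, 2700)
  b <- bias_stats(ref, ref)
  expect_equal(b$bias_mean, 0)
  expect_equal(b$bias_sd, 0)
  expect_equal(b$p_paired, 1)
  # alternating +/-100: mean 0, sample sd sqrt(4 * 100^2 / 3)
  est <- ref[1:4] + c(-100, 100, -100, 100)
  b <- suppressWarnings(bias_stats(ref[1:4], est))
  expect_equal(b$bias_mean, 0)
  expect_equal(b$bias_sd, 115.47, tolerance = 1e-4)
  # a method that overestimates has negative bias
  b <- suppressWarnings(bias_stats(ref, ref * 1.4))
  expect_lt(b$bias_mean, 0)
  expect_error(bias_stats(1:2, 2:3), "insufficient")
})

test_that("paired t-test p-values match the textbook formula on random fixtures", {
  for (seed in 1:20) {
    fx <- oracle_fixture(seed)
    d <- fx$reference - fx$estimate
    got <- t.test(fx$reference, fx$estimate, paired = TRUE)$p.value
    expect_equal(got, oracle_paired_t(fx$reference, fx$estimate)$p,
                 tolerance = 1e-10)
    # the routed statistic reproduces one of the two tests it claims
    b <- bias_stats(fx$reference, fx$estimate)
    if (b$test == "paired t") expect_equal(b$p_paired, got, tolerance = 1e-12)
  }
})

test_that("correlations agree with brute-force implementations", {
  for (seed in 1:50) {
    fx <- oracle_fixture(seed, n = 25)
    co <- paired_correlations(fx$reference, fx$estimate)
    pe <- oracle_pearson(fx$reference, fx$estimate)
    expect_equal(co$pearson_r, pe$r, tolerance = 1e-10)
    expect_equal(co$pearson_p, pe$p, tolerance = 1e-10)
    expect_equal(co$spearman_rho, oracle_spearman(fx$reference, fx$estimate),
                 tolerance = 1e-10)
  }
  # perfect monotone association
  x <- c(1, 2, 3, 5, 8)
  co <- paired_correlations(x, 2 * x)
  expect_equal(co$pearson_r, 1)
  expect_equal(co$spearman_rho, 1)
  expect_equal(paired_correlations(x, rev(x))$spearman_rho, -1)
  # ties get average ranks
  xt <- c(1, 2, 2, 3, 4, 4, 5)
  yt <- c(2, 1, 3, 3, 5, 4, 7)
  expect_equal(paired_correlations(xt, yt)$spearman_rho,
               oracle_spearman(xt, yt), tolerance = 1e-10)
  # zero variance is flagged, not silently zero
  co <- paired_correlations(rep(5, 6), 1:6)
  expect_false(co$defined)
  expect_true(is.na(co$pearson_r))
})

test_that("ICC matches the independently coded ANOVA oracle", {
  for (seed in 1:20) {
    fx <- oracle_fixture(seed, n = 28)
    for (form in c("absolute_agreement", "consistency")) {
      got <- icc_estimate(fx$reference, fx$estimate, form = form)
      expect_equal(got$icc, oracle_icc(fx$reference, fx$estimate, form),
                   tolerance = 1e-10)
      expect_true(got$ci_low <= got$icc && got$icc <= got$ci_high)
    }
  }
})

test_that("ICC forms separate under a systematic offset", {
  fx <- oracle_fixture(3, n = 40)
  shifted <- fx$reference + 1500
  cons <- icc_estimate(fx$reference, shifted, form = "consistency")
  abs_ <- icc_estimate(fx$reference, shifted, form = "absolute_agreement")
  expect_equal(cons$icc, 1)
  expect_lt(abs_$icc, cons$icc)
  # identical series: degenerate perfect agreement
  same <- icc_estimate(fx$reference, fx$reference)
  expect_equal(same$icc, 1)
  expect_true(same$degenerate)
  # offsets persist across fixtures
  for (seed in 4:13) {
    fx <- oracle_fixture(seed, n = 30)
    est <- fx$estimate + 800
    expect_gte(icc_estimate(fx$reference, est, "consistency")$icc,
               icc_estimate(fx$reference, est, "absolute_agreement")$icc)
  }
})

test_that("ICC agrees with pingouin's two-way single-measure forms", {
  fx <- oracle_fixture(8, n = 24)
  csv <- tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(r = fx$reference, e = fx$estimate), csv)
  script <- paste(
    "import sys, pandas as pd, pingouin as pg",
    "d = pd.read_csv(sys.argv[1])",
    "long = pd.DataFrame({",
    "  'subj': list(range(len(d))) * 2,",
    "  'rater': ['r'] * len(d) + ['e'] * len(d),",
    "  'y': list(d.r) + list(d.e)})",
    "icc = pg.intraclass_corr(long, targets='subj', raters='rater',",
    "                         ratings='y')",
    "print(float(icc.loc[icc.Type == 'ICC(A,1)', 'ICC'].iloc[0]))",
    "print(float(icc.loc[icc.Type == 'ICC(C,1)', 'ICC'].iloc[0]))",
    sep = "\n")
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script), shQuote(csv)),
            stdout = TRUE, stderr = FALSE))
  ref_vals <- as.numeric(utils::tail(out, 2))
  expect_equal(icc_estimate(fx$reference, fx$estimate,
                            "absolute_agreement")$icc,
               ref_vals[1], tolerance = 1e-6)
  expect_equal(icc_estimate(fx$reference, fx$estimate, "consistency")$icc,
               ref_vals[2], tolerance = 1e-6)
})

test_that("Koo-Li bands classify ICC values", {
  expect_identical(classify_icc(c(0.49, 0.5, 0.66, 0.75, 0.8, 0.9, 0.95)),
                   c("poor", "moderate", "moderate", "good", "good",
                     "excellent", "excellent"))
  expect_error(classify_icc(1.2), "exceed")
})

test_that("Bland-Altman limits and proportional bias match the oracles", {
  for (seed in 1:20) {
    fx <- oracle_fixture(seed)
    ba <- bland_altman(fx$reference, fx$estimate)
    d <- fx$reference - fx$estimate
    m <- (fx$reference + fx$estimate) / 2
    expect_equal(ba$loa_lower, mean(d) - 1.96 * sd(d), tolerance = 1e-12)
    expect_equal(ba$loa_upper, mean(d) + 1.96 * sd(d), tolerance = 1e-12)
    ols <- oracle_ols(m, d)
    expect_equal(ba$prop_bias_slope, ols$slope, tolerance = 1e-10)
    expect_equal(ba$prop_bias_p, ols$p, tolerance = 1e-10)
  }
  # constant difference: zero-width limits, flat regression
  ref <- c(2000, 2400, 2900, 3300, 3800)
  ba <- bland_altman(ref, ref - 250)
  expect_equal(ba$bias_mean, 250)
  expect_equal(ba$loa_lower, ba$loa_upper)
  expect_equal(ba$prop_bias_slope, 0)
})

test_that("normality routing uses the Lilliefors-corrected KS test", {
  set.seed(61)
  norm <- rnorm(5000, 10, 2)
  expon <- rexp(5000)
  expect_gt(ks_normality(norm)$p, 0.05)
  expect_identical(ks_normality(norm)$route, "parametric")
  expect_lt(ks_normality(expon)$p, 0.05)
  expect_identical(ks_normality(expon)$route, "nonparametric")
  expect_warning(res <- ks_normality(rep(1, 10)), "nonparametric")
  expect_identical(res$route, "nonparametric")
  expect_warning(ks_normality(c(1, 2, 3)), "nonparametric")
})

test_that("comparison statistics are invariant to row order and relabelling", {
  co <- generate_cohort(generator_params(n_participants = 80, seed = 31))
  est <- score_cohort(co)
  flags <- screen_completeness(co$urine24, co$profiles)
  base <- compare_all(est, flags)
  # shuffle rows
  set.seed(1)
  shuffled <- est[sample(nrow(est)), ]
  expect_equal(compare_all(shuffled, flags), base)
  # relabel participants consistently
  map <- setNames(sprintf("Z%03d", seq_along(unique(est$participant_id))),
                  sort(unique(est$participant_id)))
  relab <- dplyr::mutate(est, participant_id = unname(map[participant_id]))
  flags2 <- dplyr::mutate(flags, participant_id = unname(map[participant_id]))
  relabelled <- compare_all(relab, flags2)
  expect_equal(dplyr::select(relabelled, -1), dplyr::select(base, -1))
})

test_that("compare_all reports per-method pairwise-complete sample sizes", {
  co <- generate_cohort(generator_params(n_participants = 200, seed = 8))
  est <- score_cohort(co)
  flags <- screen_completeness(co$urine24, co$profiles)
  comp <- compare_all(est, flags)
  counts <- table(est$method_id)
  for (i in seq_len(nrow(comp))) {
    expect_equal(comp$n[i], unname(counts[comp$method_id[i]]))
  }
  # the LoA identity holds exactly for every stored row
  expect_equal(comp$loa_lower, comp$bias_mean - 1.96 * comp$bias_sd)
  expect_equal(comp$loa_upper, comp$bias_mean + 1.96 * comp$bias_sd)
  expect_true(all(comp$icc_ci_low <= comp$icc & comp$icc <= comp$icc_ci_high))
  expect_true(all(abs(comp$pearson_r) <= 1 & abs(comp$spearman_rho) <= 1))
  expect_error(compare_all(est[est$method_id != "u24", ], flags), "u24")
})

test_that("the sensitivity analysis only drops incomplete collections", {
  co <- generate_cohort(generator_params(n_participants = 120, seed = 55,
                                         incomplete_collection_rate = 0))
  est <- score_cohort(co)
  flags <- screen_completeness(co$urine24, co$profiles)
  expect_true(all(flags$complete))
  expect_equal(compare_all(est, flags, sensitivity = TRUE),
               compare_all(est, flags, sensitivity = FALSE))
  expect_error(compare_all(est, NULL, sensitivity = TRUE), "completeness")
  # with injected incompleteness the sensitivity n shrinks accordingly
  co2 <- generate_cohort(generator_params(n_participants = 150, seed = 56,
                                          incomplete_collection_rate = 0.2))
  est2 <- score_cohort(co2)
  flags2 <- screen_completeness(co2$urine24, co2$profiles)
  full <- compare_all(est2, flags2)
  sens <- compare_all(est2, flags2, sensitivity = TRUE)
  expect_true(all(sens$n <= full$n[match(sens$method_id, full$method_id)]))
  expect_lt(sens$n[sens$method_id == "dr24"],
            full$n[full$method_id == "dr24"])
})
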