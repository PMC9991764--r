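test_that("invalid generator parameters are rejected by field name", {
  expect_error(generator_params(n_participants = 1), "n_participants")
  expect_error(generator_params(excretion_fraction = 1.2),
               "excretion_fraction")
  expect_error(generator_params(cv_true_na = -0.1), "cv_true_na")
  expect_error(generator_params(discretionary_share = 2),
               "discretionary_share")
  expect_error(generator_params(recall_underreport_mean = 0),
               "recall_underreport_mean")
  expect_error(generator_params(pct_male = -0.5), "pct_male")
  # the stated default excretion fraction
  expect_equal(generator_params()$excretion_fraction, 0.90)
  expect_equal(generator_params()$discretionary_share, 0.15)
  expect_equal(generator_params()$incomplete_collection_rate, 0.074)
})

test_that("generation is deterministic for a fixed seed and streams are independent", {
  p <- generator_params(n_participants = 60, seed = 42)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  for (nm in names(a)) expect_identical(a[[nm]], b[[nm]], label = nm)
  c <- generate_cohort(generator_params(n_participants = 60, seed = 43))
  expect_false(identical(a$truth$true_usual_na, c$truth$true_usual_na))
  # perturbing one stream's parameters leaves the other streams untouched
  d <- generate_cohort(generator_params(n_participants = 60, seed = 42,
                                        ffq_error_cv = 0.7))
  expect_identical(a$urine24, d$urine24)
  expect_identical(a$profiles, d$profiles)
  expect_identical(a$recalls, d$recalls)
})

test_that("truth decomposes into food and discretionary sodium", {
  co <- generate_cohort(generator_params(n_participants = 80, seed = 9))
  tr <- co$truth
  expect_equal(tr$true_usual_na, tr$true_food_na + tr$true_discretionary_na)
  expect_true(all(tr$true_usual_na >= 0))
  expect_true(all(tr$true_discretionary_na >= 0))
})

test_that("a default cohort matches its demographic targets", {
  co <- generate_cohort(generator_params(seed = 1))
  expect_equal(nrow(co$profiles), 122)
  n_male <- sum(co$profiles$sex == "M")
  se <- sqrt(0.557 * 0.443 * 122)
  expect_lt(abs(n_male - 0.557 * 122), 3 * se)
  expect_lt(abs(mean(co$profiles$age_y) - 56.0), 2 * 12.6 / sqrt(122))
})

test_that("generated quantities are calibrated to their programmed values", {
  n <- 10000
  co <- generate_cohort(generator_params(n_participants = n, seed = 20260))
  p <- attr(co, "params")
  tr <- co$truth$true_usual_na
  expect_lt(abs(mean(tr) - p$mean_true_na), 3 * sd(tr) / sqrt(n))
  expect_lt(abs(sd(tr) / mean(tr) - p$cv_true_na),
            3 * p$cv_true_na / sqrt(2 * n))
  # urinary excretion recovers the excretion fraction
  ratio <- compute_24h_urinary_na(co$urine24) / tr
  expect_lt(abs(mean(ratio) - p$excretion_fraction), 3 * sd(ratio) / sqrt(n))
  # injected incompleteness at the programmed rate, and screening agrees
  inc <- mean(co$urine24$complete == 0)
  expect_lt(abs(inc - 0.074), 3 * sqrt(0.074 * 0.926 / n))
  screened <- screen_completeness(co$urine24, co$profiles)
  expect_equal(mean(!screened$complete), inc, tolerance = 0.01)
  # demographics
  expect_lt(abs(mean(co$profiles$sex == "M") - 0.557),
            3 * sqrt(0.557 * 0.443 / n))
  expect_lt(abs(mean(co$profiles$age_y) - 56.0), 0.15 + 3 * 12.6 / sqrt(n))
})

test_that("downstream recall bias matches its generative expectation", {
  p <- generator_params(n_participants = 4000, seed = 77)
  co <- generate_cohort(p)
  est <- estimates_wide(score_cohort(co))
  d <- est$u24 - est$dr24
  d <- d[!is.na(d)]
  expected <- (p$excretion_fraction -
                 p$recall_underreport_mean * (1 - p$discretionary_share)) *
    p$mean_true_na
  expect_lt(abs(mean(d) - expected), 3 * sd(d) / sqrt(length(d)))
})

test_that("zero-noise configurations are recovered exactly by the matched methods", {
  co <- generate_cohort(zero_noise_params(n = 40, seed = 99))
  truth <- co$truth$true_usual_na
  est <- estimates_wide(score_cohort(co))
  est <- est[match(co$truth$participant_id, est$participant_id), ]
  expect_equal(est$u24, truth, tolerance = 1e-9)
  expect_equal(est$dr24, truth, tolerance = 1e-9)
  expect_equal(est$dr24_sq, truth, tolerance = 1e-9)
  expect_equal(est$ffq, truth, tolerance = 1e-9)
  expect_equal(est$naffq, truth, tolerance = 1e-9)
  # the fixed-share correction applies its structural 1/0.85 markup
  expect_equal(est$dr24_p15, truth / 0.85, tolerance = 1e-9)
  # spot estimates are deterministic functions of the day's excretion
  co2 <- generate_cohort(zero_noise_params(n = 40, seed = 99))
  expect_identical(co$spot, co2$spot)
})

test_that("with discretionary salt, the salt questions recover intake to grid precision", {
  # zero-noise but with a 15% discretionary share: the quantised Q1/Q2
  # answers reconstruct discretionary sodium up to half a Q1 band
  co <- generate_cohort(zero_noise_params(n = 60, seed = 13, share = 0.15))
  truth <- co$truth
  est <- estimates_wide(score_cohort(co))
  est <- est[match(truth$participant_id, est$participant_id), ]
  expect_equal(est$dr24, truth$true_food_na, tolerance = 1e-9)
  # Q1 grid: at most 150 mg/100 g from a band midpoint on 11.5 x 100 g of
  # food, plus one 775 mg table-salt rounding
  max_err <- 150 * 11.5 + 775
  expect_true(all(abs(est$dr24_sq - truth$true_usual_na) <= max_err))
  # nearest-band property: quantisation can never do worse than ignoring
  # discretionary sodium altogether
  expect_true(all(abs(est$naffq - truth$true_usual_na) <=
                    truth$true_discretionary_na + 1e-6))
})

test_that("cohorts round-trip through delimited text", {
  co <- generate_cohort(generator_params(n_participants = 5, seed = 4))
  dir <- withr::local_tempdir()
  paths <- write_cohort(co, dir)
  expect_setequal(basename(unname(paths)),
                  c("profiles.csv", "truth.csv", "urine24.csv", "spot.csv",
                    "recalls.csv", "ffq.csv", "params.yaml"))
  # per-participant files carry one row per participant
  expect_equal(nrow(readr::read_csv(paths[["profiles"]], show_col_types = FALSE)), 5)
  expect_equal(nrow(readr::read_csv(paths[["truth"]], show_col_types = FALSE)), 5)
  expect_equal(nrow(readr::read_csv(paths[["urine24"]], show_col_types = FALSE)), 5)
  back <- read_cohort(dir)
  for (nm in c("profiles", "truth", "urine24", "spot", "recalls", "ffq")) {
    expect_equal(as.data.frame(back[[nm]]), as.data.frame(co[[nm]]),
                 tolerance = 1e-9, label = nm)
  }
  expect_equal(unclass(attr(back, "params")), unclass(attr(co, "params")),
               tolerance = 1e-12)
})

test_that("an empty bundle writes header-only files without error", {
  co <- generate_cohort(generator_params(n_participants = 2, seed = 1))
  for (nm in c("profiles", "truth", "urine24", "spot", "recalls", "ffq")) {
    co[[nm]] <- co[[nm]][0, ]
  }
  dir <- withr::local_tempdir()
  expect_no_error(write_cohort(co, dir))
  back <- read_cohort(dir)
  expect_equal(nrow(back$profiles), 0)
  expect_equal(nrow(back$recalls), 0)
})
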