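# Brute-force reference implementations, coded independently of the package
# internals, used to verify the agreement statistics to tight tolerances.

# paired t-test from the textbook definition
oracle_paired_t <- function(reference, estimate) {
  d <- reference - estimate
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  t <- m / (s / sqrt(n))
  list(t = t, p = 2 * stats::pt(-abs(t), df = n - 1))
}

# product-moment correlation from explicit sums; p via the t transform
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  r <- sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# average ranks computed from first principles (no rank())
oracle_avg_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, 0)
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_avg_ranks(x), oracle_avg_ranks(y))$r
}

# OLS of y on x by the normal equations; slope p via the t distribution
oracle_ols <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxx <- sum((x - mx)^2)
  beta <- sum((x - mx) * (y - my)) / sxx
  alpha <- my - beta * mx
  resid <- y - alpha - beta * x
  se <- sqrt(sum(resid^2) / (n - 2) / sxx)
  t <- beta / se
  list(slope = beta, p = 2 * stats::pt(-abs(t), df = n - 2))
}

# two-way single-measure ICC recomputed from an independently coded ANOVA
# decomposition (explicit loops over cells)
oracle_icc <- function(reference, estimate, form) {
  x <- cbind(reference, estimate)
  n <- nrow(x)
  k <- ncol(x)
  grand <- sum(x) / (n * k)
  row_m <- numeric(n)
  for (i in seq_len(n)) row_m[i] <- sum(x[i, ]) / k
  col_m <- numeric(k)
  for (j in seq_len(k)) col_m[j] <- sum(x[, j]) / n
  ssr <- 0
  for (i in seq_len(n)) ssr <- ssr + k * (row_m[i] - grand)^2
  ssc <- 0
  for (j in seq_len(k)) ssc <- ssc + n * (col_m[j] - grand)^2
  sse <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      sse <- sse + (x[i, j] - row_m[i] - col_m[j] + grand)^2
    }
  }
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  unname(if (form == "consistency") {
    (msr - mse) / (msr + (k - 1) * mse)
  } else {
    (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  })
}

# seeded random paired series for oracle-equivalence fixtures
oracle_fixture <- function(seed, n = 30) {
  set.seed(seed)
  reference <- stats::rlnorm(n, log(2800), 0.4)
  estimate <- 0.8 * reference + stats::rnorm(n, 300, 400)
  list(reference = reference, estimate = estimate)
}

zero_noise_params <- function(n = 40, seed = 99, share = 0) {
  generator_params(
    n_participants = n, seed = seed,
    cv_true_na = 0.3, day_cv_urine = 0, recall_day_cv = 0,
    ffq_error_cv = 0, spot_noise_cv = 0,
    excretion_fraction = 1,
    recall_underreport_mean = 1, recall_underreport_sd = 0,
    ffq_underreport_mean = 1, naffq_underreport_mean = 1,
    discretionary_share = share, incomplete_collection_rate = 0,
    avail_spot = 1, avail_recall = 1, avail_ffq = 1, avail_naffq = 1
  )
}

estimates_wide <- function(estimates) {
  tidyr::pivot_wider(estimates, names_from = "method_id",
                     values_from = "na_mg_per_day")
}
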