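# Synthetic cohort with a known measurement-error structure.
#
# Generative model, per participant i:
#   true_i            ~ logNormal(mean = mean_true_na, cv = cv_true_na)
#   disc_i            = discretionary_share * true_i      (cooking + table salt)
#   u24Na_i           = excretion_fraction * true_i * e_i, e_i mean-one LN(day_cv_urine)
#   recall_total_ir   = (1 - discretionary_share) * true_i * u_i * m_ir
#                       u_i  ~ truncNormal(recall_underreport_mean, sd; (0, 1.2])
#                       m_ir mean-one LN(recall_day_cv)
#   ffq_total_i       = (1 - discretionary_share) * true_i * f_i, f_i LN(ffq_error_cv)
#   spot conc         = median * (same-day excretion / its mean)^spot_correlation
#                       * LN(spot_noise_cv) * spot_overestimation  (sodium only)
# Discretionary answers (salt questions Q1/Q2, NaFFQ question b) are the
# quantised inverse of their scoring maps, so scoring them approximately
# recovers disc_i. Incomplete collections have their recorded volume scaled
# below the completeness threshold with concentrations recomputed, so the
# collection's total sodium is preserved (a recording-error model).

MEAL_NAMES <- c("breakfast", "lunch", "dinner", "other")
MEAL_SHARES <- c(breakfast = 0.20, lunch = 0.35, dinner = 0.30, other = 0.15)
MEAL_GRAMS <- c(breakfast = 300, lunch = 450, dinner = 400, other = 250)
ITEM_SPLITS <- c(0.6, 0.4)
TABLE_SALT_FRACTION <- 0.3 # share of discretionary sodium assumed to be table salt

#' Generate a synthetic high-CVD-risk cohort
#'
#' Draws a complete cohort bundle - participant profiles, per-participant
#' truths, 24-h urine collections, spot urine samples, itemised 24-h dietary
#' recalls with per-meal salt questions, and FFQ/NaFFQ responses - from the
#' generative model described in the package vignette. The generation is
#' deterministic for a fixed `params$seed`; each data type uses an
#' independent named substream of the root seed.
#'
#' @param params a [generator_params()] object.
#' @return an object of class `na_cohort`: a list of tibbles `profiles`,
#'   `truth`, `urine24`, `spot`, `recalls`, `ffq`, with `params` attached as
#'   an attribute.
#' @examples
#' cohort <- generate_cohort(generator_params(n_participants = 20, seed = 7))
#' names(cohort)
#' @export
generate_cohort <- function(params) {
  if (!inherits(params, "generator_params")) {
    params <- do.call(generator_params, params)
  }
  validate_generator_params(params)
  p <- params
  n <- as.integer(p$n_participants)
  ids <- sprintf("P%05d", seq_len(n))

  profiles <- with_stream(p$seed, "profiles", {
    male <- runif(n) < p$pct_male
    age <- pmin(90, pmax(18, rnorm(n, p$age_mean, p$age_sd)))
    weight <- ifelse(male, rnorm(n, 85, 14), rnorm(n, 72, 13))
    height <- ifelse(male, rnorm(n, 175, 7), rnorm(n, 162, 6.5))
    tibble::tibble(
      participant_id = ids,
      age_y = round(age, 1),
      sex = ifelse(male, "M", "F"),
      weight_kg = round(pmin(150, pmax(40, weight)), 1),
      height_cm = round(pmin(200, pmax(140, height)), 1)
    )
  })

  truth <- with_stream(p$seed, "truth", {
    true_na <- rlnorm_mean_cv(n, p$mean_true_na, p$cv_true_na)
    disc <- p$discretionary_share * true_na
    tibble::tibble(
      participant_id = ids,
      true_usual_na = true_na,
      true_food_na = true_na - disc,
      true_discretionary_na = disc
    )
  })

  urine <- with_stream(p$seed, "urine24", {
    na_mg <- p$excretion_fraction * truth$true_usual_na * rnoise(n, p$day_cv_urine)
    volume <- rlnorm_mean_cv(n, 1.6, min(p$day_cv_urine, 0.30))
    creat_cv <- if (p$day_cv_urine > 0) 0.08 else 0
    creat_per_kg <- ifelse(profiles$sex == "M",
                           rnorm(n, 24, 24 * creat_cv),
                           rnorm(n, 18, 18 * creat_cv))
    creat_mg_day <- profiles$weight_kg * creat_per_kg
    k_mg_day <- rlnorm_mean_cv(n, 2540, p$day_cv_urine)
    incomplete <- runif(n) < p$incomplete_collection_rate
    volume[incomplete] <- runif(sum(incomplete), 0.15, 0.45)
    list(
      records = tibble::tibble(
        participant_id = ids,
        volume_l = volume,
        na_mmol_l = na_mg_to_mmol(na_mg) / volume,
        k_mmol_l = k_mg_day / 39.1 / volume,
        creat_mg_dl = creat_mg_day / volume / 10,
        complete = as.integer(!incomplete)
      ),
      na_mg = na_mg, creat_mg_day = creat_mg_day, k_mg_day = k_mg_day
    )
  })

  spot <- with_stream(p$seed, "spot", {
    avail <- runif(n) < p$avail_spot
    rel <- function(x) x / mean(x)
    rho <- p$spot_correlation
    na_conc <- 100 * rel(urine$na_mg)^rho * rnoise(n, p$spot_noise_cv) *
      p$spot_overestimation
    cr_conc <- 140 * rel(urine$creat_mg_day)^rho * rnoise(n, p$spot_noise_cv)
    k_conc <- 55 * rel(urine$k_mg_day)^rho * rnoise(n, p$spot_noise_cv)
    tibble::tibble(
      participant_id = ids,
      na_mmol_l = na_conc,
      k_mmol_l = k_conc,
      creat_mg_dl = cr_conc
    )[avail, ]
  })

  recalls <- with_stream(p$seed, "recalls", {
    avail <- runif(n) < p$avail_recall
    u_i <- rtrunc_norm(n, p$recall_underreport_mean, p$recall_underreport_sd)
    disc <- truth$true_discretionary_na
    # table salt: stochastic rounding keeps the expected quantified sodium
    # equal to its target share of discretionary intake
    t_yes <- TABLE_SALT_FRACTION * disc / q2_dash_na(2)
    n_yes <- pmin(3L, floor(t_yes) + as.integer(runif(n) < (t_yes - floor(t_yes))))
    cooking <- pmax(0, disc - n_yes * q2_dash_na(2))
    solid_g3 <- sum(MEAL_GRAMS[c("breakfast", "lunch", "dinner")])
    q1_answer <- nearest_label(cooking / (solid_g3 / 100), q1_rates())
    day_factor <- matrix(rnoise(n * 3, p$recall_day_cv), n, 3)
    idx <- which(avail)
    build_recall_rows(idx, ids, truth$true_usual_na, u_i, day_factor,
                      p$discretionary_share, q1_answer, n_yes)
  })

  ffq <- with_stream(p$seed, "ffq", {
    comp <- food_composition()
    avail_std <- runif(n) < p$avail_ffq
    avail_na <- runif(n) < p$avail_naffq
    f_std <- p$ffq_underreport_mean * rnoise(n, p$ffq_error_cv)
    f_na <- p$naffq_underreport_mean * rnoise(n, p$ffq_error_cv)
    food_target <- (1 - p$discretionary_share) * truth$true_usual_na
    std <- build_ffq_rows(which(avail_std), ids, comp, version = "standard",
                          target = food_target * f_std, disc = NULL)
    naf <- build_ffq_rows(which(avail_na), ids, comp, version = "naffq",
                          target = food_target * f_na,
                          disc = truth$true_discretionary_na)
    dplyr::bind_rows(std, naf)
  })

  structure(
    list(profiles = profiles, truth = truth, urine24 = urine$records,
         spot = spot, recalls = recalls, ffq = ffq),
    params = p, class = "na_cohort"
  )
}

# nearest scoring category for a continuous mg/100 g rate (quantised inverse)
nearest_label <- function(x, rates) {
  names(rates)[max.col(-abs(outer(x, unname(rates), "-")), ties.method = "first")]
}

build_recall_rows <- function(idx, ids, true_na, u_i, day_factor, share,
                              q1_answer, n_yes) {
  if (!length(idx)) return(empty_recalls())
  per <- length(MEAL_NAMES) * length(ITEM_SPLITS) # rows per recall
  grid <- expand.grid(item = seq_along(ITEM_SPLITS), meal = MEAL_NAMES,
                      recall_idx = 1:3, i = idx, stringsAsFactors = FALSE)
  i <- grid$i
  meal <- as.character(grid$meal)
  total <- (1 - share) * true_na[i] * u_i[i] *
    day_factor[cbind(i, grid$recall_idx)]
  meal_na <- total * MEAL_SHARES[meal]
  grams <- MEAL_GRAMS[meal] * ITEM_SPLITS[grid$item]
  na100 <- meal_na / (MEAL_GRAMS[meal] / 100) # shared density within a meal
  main_meal <- meal != "other"
  meal_rank <- match(meal, c("breakfast", "lunch", "dinner"))
  tibble::tibble(
    participant_id = ids[i],
    recall_idx = grid$recall_idx,
    meal = meal,
    item_grams = unname(grams),
    item_na_mg_per_100g = unname(na100),
    q1 = ifelse(main_meal, q1_answer[i], NA_character_),
    q2 = ifelse(main_meal, ifelse(meal_rank <= n_yes[i], "yes", "no"),
                NA_character_)
  )
}

empty_recalls <- function() {
  tibble::tibble(participant_id = character(), recall_idx = integer(),
                 meal = character(), item_grams = numeric(),
                 item_na_mg_per_100g = numeric(), q1 = character(),
                 q2 = character())
}

build_ffq_rows <- function(idx, ids, comp, version, target, disc) {
  if (!length(idx)) return(empty_ffq())
  cats <- names(frequency_weights())
  cat_prob <- c(0.10, 0.20, 0.25, 0.20, 0.15, 0.10)
  std_pool <- comp$item_id[!comp$naffq_only]
  extra <- comp$item_id[comp$naffq_only]
  forced_cooked <- c("rice_cooked", "vegetables_raw_salad")
  m <- length(idx)
  if (version == "standard") {
    n_items <- 15L
    item_mat <- vapply(idx, function(i) sample(std_pool, n_items),
                       character(n_items))
    forced_rows <- integer()
  } else {
    rest_pool <- setdiff(std_pool, forced_cooked)
    n_items <- length(extra) + 2L + 11L
    item_mat <- vapply(idx, function(i) {
      c(extra, forced_cooked, sample(rest_pool, 11))
    }, character(n_items))
    forced_rows <- length(extra) + 1:2
  }
  freq_mat <- matrix(sample(cats, n_items * m, replace = TRUE, prob = cat_prob),
                     n_items, m)
  # forced cooked items must consume (question b applies to them)
  if (length(forced_rows)) {
    freq_mat[forced_rows, ] <- sample(cats[-1], length(forced_rows) * m,
                                      replace = TRUE)
  }
  pid <- rep(ids[idx], each = n_items)
  out <- tibble::tibble(
    participant_id = pid, version = version,
    item_id = as.vector(item_mat), freq_cat = as.vector(freq_mat),
    portion_g = runif(n_items * m, 40, 250))
  na100 <- comp$na_mg_per_100g[match(out$item_id, comp$item_id)]
  grp <- rep(seq_len(m), each = n_items)
  w <- unname(frequency_weights()[out$freq_cat])
  base <- as.vector(rowsum(w * out$portion_g * na100 / 100, grp))
  # degenerate all-"never" draws: force the first item to daily consumption
  zero <- which(base <= 0)
  if (length(zero)) {
    first <- (zero - 1L) * n_items + 1L
    out$freq_cat[first] <- "1_per_day"
    w <- unname(frequency_weights()[out$freq_cat])
    base <- as.vector(rowsum(w * out$portion_g * na100 / 100, grp))
  }
  out$portion_g <- out$portion_g * (target[idx] / base)[grp]
  if (version == "naffq") {
    cooked <- comp$is_cooked_meal_or_salad[match(out$item_id, comp$item_id)] == 1
    w <- unname(frequency_weights()[out$freq_cat])
    cooked_g <- as.vector(rowsum(ifelse(cooked, w * out$portion_g, 0), grp))
    rate <- disc[idx] / (pmax(cooked_g, 1e-9) / 100)
    out$question_b <- nearest_label(rate, question_b_rates())[grp]
  } else {
    out$question_b <- NA_character_
  }
  out
}

empty_ffq <- function() {
  tibble::tibble(participant_id = character(), version = character(),
                 item_id = character(), freq_cat = character(),
                 portion_g = numeric(), question_b = character())
}

#' Write / read a cohort bundle as delimited text
#'
#' `write_cohort()` serialises a cohort to comma-separated UTF-8 files
#' (`profiles.csv`, `truth.csv`, `urine24.csv`, `spot.csv`, `recalls.csv`,
#' `ffq.csv`) plus `params.yaml` echoing the generator parameters.
#' `read_cohort()` reverses the operation; non-floating fields round-trip
#' bit-exactly and floats to better than 1e-9 relative error.
#'
#' @param cohort an `na_cohort` bundle from [generate_cohort()].
#' @param dir directory to write into (created if missing).
#' @return `write_cohort()` returns the file paths invisibly;
#'   `read_cohort()` returns an `na_cohort`.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "na_cohort"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  }
  paths <- character()
  for (nm in c("profiles", "truth", "urine24", "spot", "recalls", "ffq")) {
    path <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(cohort[[nm]], path)
    paths[nm] <- path
  }
  params <- attr(cohort, "params")
  if (!is.null(params)) {
    yaml::write_yaml(unclass(params), file.path(dir, "params.yaml"),
                     precision = 15)
    paths["params"] <- file.path(dir, "params.yaml")
  }
  invisible(paths)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(dir) {
  rd <- function(nm, types) {
    readr::read_csv(file.path(dir, paste0(nm, ".csv")), col_types = types,
                    progress = FALSE)
  }
  bundle <- list(
    profiles = rd("profiles", "cdcdd"),
    truth = rd("truth", "cddd"),
    urine24 = rd("urine24", "cddddi"),
    spot = rd("spot", "cddd"),
    recalls = rd("recalls", "cicddcc"),
    ffq = rd("ffq", readr::cols(
      participant_id = "c", version = "c", item_id = "c",
      freq_cat = "c", portion_g = "d", question_b = "c"))
  )
  params_path <- file.path(dir, "params.yaml")
  params <- NULL
  if (file.exists(params_path)) {
    params <- do.call(generator_params, yaml::read_yaml(params_path))
  }
  structure(bundle, params = params, class = "na_cohort")
}

#' @export
print.na_cohort <- function(x, ...) {
  cat(sprintf("<na_cohort> %d participants\n", nrow(x$profiles)))
  for (nm in setdiff(names(x), "profiles")) {
    cat(sprintf("  %-8s %5d rows\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}
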