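# Dietary instruments: 24-h recall scoring, the two discretionary-salt
# corrections, and frequency-weighted FFQ / NaFFQ scoring.

# scoring constants ---------------------------------------------------------

#' Frequency-category weights of the FFQ
#'
#' The six consumption-frequency categories and their daily weights:
#' never = 0, 1-3 times/month = 0.07, 1-2 times/week = 0.21,
#' 3-6 times/week = 0.64, once a day = 1, twice or more a day = 2.
#'
#' @return a named numeric vector of length six.
#' @export
frequency_weights <- function() {
  c(never = 0, "1-3_per_month" = 0.07, "1-2_per_week" = 0.21,
    "3-6_per_week" = 0.64, "1_per_day" = 1, "2plus_per_day" = 2)
}

#' @rdname frequency_weights
#' @param cat character vector of category labels.
#' @return `frequency_weight()`: times/day, one per label.
#' @examples
#' frequency_weight("1-2_per_week") # 0.21
#' @export
frequency_weight <- function(cat) {
  w <- frequency_weights()
  bad <- !cat %in% names(w)
  if (any(bad)) {
    stop("unknown frequency category: ",
         paste(unique(cat[bad]), collapse = ", "), call. = FALSE)
  }
  unname(w[cat])
}

# cooking-salt question (Q1): mg of sodium per 100 g of meal food, banded by
# the food-authority low/medium/high salt cut-offs
q1_rates <- function() c(none = 0, little = 50, moderate = 350, a_lot = 600)

# NaFFQ question b: same bands plus a "very much" level
question_b_rates <- function() {
  c(none = 0, little = 50, moderate = 350, much = 600, very_much = 900)
}

# table-salt question (Q2): sodium per two dashes of salt
q2_dash_na <- function(dashes = 2) 775 / 2 * dashes

# recall scoring ------------------------------------------------------------

#' Sodium of one 24-h dietary recall
#'
#' Sums `grams x sodium density / 100` over all reported items.
#'
#' @param recall data frame of items with columns `item_grams` and
#'   `item_na_mg_per_100g`.
#' @return total sodium, mg.
#' @examples
#' recall_na(data.frame(item_grams = 250, item_na_mg_per_100g = 400)) # 1000
#' @export
recall_na <- function(recall) {
  if (!nrow(recall)) return(0)
  check_nonnegative(recall$item_grams, "item_grams")
  check_nonnegative(recall$item_na_mg_per_100g, "item_na_mg_per_100g")
  sum(recall$item_grams * recall$item_na_mg_per_100g / 100)
}

#' Mean sodium over the available 24-h recalls
#'
#' Averages recall totals over however many recalls (1-3) a participant
#' completed; with no recalls the result is missing, not zero.
#'
#' @param recalls item-level data frame for one participant with a
#'   `recall_idx` column.
#' @return mean sodium per day, mg, or `NA_real_` when no recalls exist.
#' @export
mean_recall_na <- function(recalls) {
  if (is.null(recalls) || !nrow(recalls)) return(NA_real_)
  totals <- tapply(recalls$item_grams * recalls$item_na_mg_per_100g / 100,
                   recalls$recall_idx, sum)
  mean(totals)
}

#' Discretionary-salt questions of the improved 24-h recall
#'
#' `q1_na()` quantifies the cooking-salt question ("How much salt did you use
#' during the preparation of your meal?") as a sodium density applied to the
#' meal's food weight: none = 0, a little = 50, moderate = 350, a lot =
#' 600 mg per 100 g. `q2_na()` quantifies the table-salt question ("Did you
#' add extra salt on your plate?"): yes = 775 mg (two dashes of salt;
#' `dashes_per_yes = 1` halves it), no = 0.
#'
#' @param answer character vector of answers (`q1`: none/little/moderate/
#'   a_lot; `q2`: yes/no). `NA` answers score 0 with a warning.
#' @param meal_food_grams grams of food the meal contained.
#' @param dashes_per_yes how many dashes of salt a "yes" represents (1 or 2).
#' @return sodium, mg.
#' @examples
#' q1_na("moderate", 200) # 700
#' q2_na("yes")           # 775
#' @export
q1_na <- function(answer, meal_food_grams) {
  check_nonnegative(meal_food_grams, "meal_food_grams")
  rates <- q1_rates()
  bad <- !is.na(answer) & !answer %in% names(rates)
  if (any(bad)) {
    stop("unknown Q1 answer: ", paste(unique(answer[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(answer)) {
    warning("missing Q1 answer(s) scored as 0 mg", call. = FALSE)
  }
  rate <- ifelse(is.na(answer), 0, rates[answer])
  unname(rate * meal_food_grams / 100)
}

#' @rdname q1_na
#' @export
q2_na <- function(answer, dashes_per_yes = 2) {
  if (!dashes_per_yes %in% c(1, 2)) {
    stop("`dashes_per_yes` must be 1 or 2", call. = FALSE)
  }
  bad <- !is.na(answer) & !answer %in% c("yes", "no")
  if (any(bad)) {
    stop("unknown Q2 answer: ", paste(unique(answer[bad]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(answer)) {
    warning("missing Q2 answer(s) scored as 0 mg", call. = FALSE)
  }
  unname(ifelse(!is.na(answer) & answer == "yes", q2_dash_na(dashes_per_yes), 0))
}

#' 24-h recall sodium plus quantified salt questions
#'
#' The improved recall estimate: mean recall sodium plus the mean (over
#' recalls) of the quantified cooking- and table-salt questions summed over
#' breakfast, lunch and dinner. The Q1 density is applied to the meal's
#' total food weight; missing answers contribute 0 with a warning.
#'
#' @param recalls item-level data frame for one participant (columns
#'   `recall_idx`, `meal`, `item_grams`, `item_na_mg_per_100g`, `q1`, `q2`).
#' @param dashes_per_yes passed to [q2_na()].
#' @return estimated sodium intake, mg/day.
#' @export
dr_plus_sq_na <- function(recalls, dashes_per_yes = 2) {
  base <- mean_recall_na(recalls)
  if (is.na(base)) return(NA_real_)
  main <- recalls[recalls$meal %in% c("breakfast", "lunch", "dinner"), ]
  if (!nrow(main)) return(base)
  key <- paste(main$recall_idx, main$meal)
  grams <- tapply(main$item_grams, key, sum)
  first <- !duplicated(key)
  q1 <- main$q1[first][match(names(grams), key[first])]
  q2 <- main$q2[first][match(names(grams), key[first])]
  ridx <- main$recall_idx[first][match(names(grams), key[first])]
  disc <- q1_na(q1, as.numeric(grams)) + q2_na(q2, dashes_per_yes)
  base + mean(tapply(disc, ridx, sum))
}

#' 24-h recall sodium corrected for a fixed discretionary share
#'
#' Adjusts mean recall sodium under the assumption that discretionary salt
#' (cooking and table) makes up `share` of total intake. In the default
#' `"share_of_total"` mode the recall total is divided by `1 - share`
#' (the 15% is a share of the *total*); `"markup"` multiplies by
#' `1 + share` instead.
#'
#' @param mean_dr mean recall sodium, mg/day.
#' @param share discretionary share of total intake, in `[0, 0.5)`.
#' @param mode `"share_of_total"` (default) or `"markup"`.
#' @return corrected sodium intake, mg/day.
#' @examples
#' dr_plus_15_na(2550) # 3000
#' @export
dr_plus_15_na <- function(mean_dr, share = 0.15,
                          mode = c("share_of_total", "markup")) {
  mode <- match.arg(mode)
  check_nonnegative(mean_dr[!is.na(mean_dr)], "mean_dr")
  if (!is.numeric(share) || share < 0 || share >= 0.5) {
    stop("`share` must be a fraction in [0, 0.5)", call. = FALSE)
  }
  if (mode == "share_of_total") mean_dr / (1 - share) else mean_dr * (1 + share)
}

# FFQ scoring ---------------------------------------------------------------

#' Bundled food-composition table
#'
#' The package's default food-group composition table (sodium mg per 100 g,
#' cooked-meal/salad flag, food group, NaFFQ-extension flag). Bundled as an
#' editable CSV so scoring is reproducible without any live database lookup;
#' replace it via `path` to use a local table.
#'
#' @param path optional path to an alternative composition CSV with columns
#'   `item_id`, `label`, `na_mg_per_100g`, `is_cooked_meal_or_salad`,
#'   `food_group`, `naffq_only`.
#' @return a tibble.
#' @export
food_composition <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_cache$composition)) return(.registry_cache$composition)
    path <- system.file("extdata", "food_composition.csv", package = "sodium24")
    comp <- readr::read_csv(path, col_types = "ccdicl", progress = FALSE)
    .registry_cache$composition <- comp
    return(comp)
  }
  readr::read_csv(path, col_types = readr::cols(na_mg_per_100g = "d",
                                                is_cooked_meal_or_salad = "i",
                                                naffq_only = "l",
                                                .default = "c"),
                  progress = FALSE)
}

#' Daily sodium of one FFQ item
#'
#' `frequency weight x portion x sodium density / 100`.
#'
#' @param freq_cat frequency-category label, see [frequency_weights()].
#' @param portion_g portion size, grams.
#' @param na_per_100g sodium density, mg per 100 g.
#' @return sodium, mg/day.
#' @examples
#' ffq_item_na("1_per_day", 150, 300) # 450
#' @export
ffq_item_na <- function(freq_cat, portion_g, na_per_100g) {
  check_nonnegative(portion_g, "portion_g")
  check_nonnegative(na_per_100g, "na_per_100g")
  frequency_weight(freq_cat) * portion_g * na_per_100g / 100
}

#' Total FFQ / NaFFQ sodium
#'
#' Scores a participant's FFQ response against a composition table. For the
#' sodium-extended version (`version = "naffq"`) the quantified answer to
#' question b ("How much salt do you use in your cooked meals and salads?",
#' none = 0, a little = 50, moderate = 350, much = 600, very much = 900 mg
#' per 100 g) is additionally applied to the daily grams of every item
#' flagged as a cooked meal or salad.
#'
#' @param items data frame with `item_id`, `freq_cat`, `portion_g`.
#' @param composition a composition table, see [food_composition()].
#' @param version `"standard"` or `"naffq"`.
#' @param question_b answer label for the NaFFQ salt question; required when
#'   `version = "naffq"`, ignored otherwise.
#' @return estimated sodium intake, mg/day.
#' @export
ffq_total_na <- function(items, composition = food_composition(),
                         version = c("standard", "naffq"),
                         question_b = NULL) {
  version <- match.arg(version)
  m <- match(items$item_id, composition$item_id)
  if (anyNA(m)) {
    stop("unresolvable FFQ item(s): ",
         paste(unique(items$item_id[is.na(m)]), collapse = ", "),
         call. = FALSE)
  }
  na100 <- composition$na_mg_per_100g[m]
  daily_g <- frequency_weight(items$freq_cat) * items$portion_g
  total <- sum(daily_g * na100 / 100)
  if (version == "naffq") {
    if (is.null(question_b) || is.na(question_b[1])) {
      stop("`question_b` is required for the naffq version", call. = FALSE)
    }
    rates <- question_b_rates()
    if (!question_b[1] %in% names(rates)) {
      stop("unknown question_b answer: ", question_b[1], call. = FALSE)
    }
    cooked <- composition$is_cooked_meal_or_salad[m] == 1
    total <- total + sum(rates[question_b[1]] * daily_g[cooked] / 100)
  }
  unname(total)
}
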