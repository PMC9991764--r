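#' Sodium excreted in a 24-h urine collection
#'
#' The reference measurement: urinary sodium concentration times collection
#' volume, converted to mg/day. Linear in both arguments.
#'
#' @param urine a data frame with columns `na_mmol_l` and `volume_l`
#'   (e.g. the `urine24` table of a cohort bundle), or a numeric vector of
#'   sodium concentrations in mmol/L.
#' @param volume_l collection volumes in litres (only when `urine` is a
#'   numeric vector).
#' @param molar_mass sodium molar mass in mg/mmol, see [na_mmol_to_mg()].
#' @return mg of sodium per day, one value per collection.
#' @examples
#' compute_24h_urinary_na(120, 1.5) # 4140
#' @export
compute_24h_urinary_na <- function(urine, volume_l = NULL, molar_mass = 23.0) {
  if (is.data.frame(urine)) {
    for (col in c("na_mmol_l", "volume_l")) {
      if (!col %in% names(urine)) {
        stop(sprintf("`urine` is missing column `%s`; a 24-h collection table is required", col),
             call. = FALSE)
      }
    }
    conc <- urine$na_mmol_l
    vol <- urine$volume_l
  } else {
    if (is.null(volume_l)) stop("`volume_l` is required", call. = FALSE)
    conc <- urine
    vol <- volume_l
  }
  check_nonnegative(conc, "na_mmol_l")
  if (any(vol <= 0, na.rm = TRUE)) {
    stop("`volume_l` must be > 0 for a 24-h collection", call. = FALSE)
  }
  na_mmol_to_mg(conc * vol, molar_mass)
}

#' Completeness rules for 24-h urine collections
#'
#' A switchable rule set used by [screen_completeness()]. Defaults follow
#' the criteria commonly used in the urinary-sodium literature: a minimum
#' collection volume of 0.5 L, and 24-h creatinine excretion per kg of body
#' weight inside 14.4-33.6 mg/kg/d for men and 10.8-25.2 mg/kg/d for women.
#' Any rule can be disabled via `enabled_rules`.
#'
#' @param min_volume minimum acceptable volume, litres.
#' @param creat_per_kg_bounds_male,creat_per_kg_bounds_female length-2
#'   numeric ranges, mg/kg/day.
#' @param enabled_rules character subset of
#'   `c("min_volume", "creatinine_per_kg")`.
#' @return an object of class `completeness_rules`.
#' @export
completeness_rules <- function(min_volume = 0.5,
                               creat_per_kg_bounds_male = c(14.4, 33.6),
                               creat_per_kg_bounds_female = c(10.8, 25.2),
                               enabled_rules = c("min_volume", "creatinine_per_kg")) {
  check_bounds <- function(b, name) {
    if (length(b) != 2 || !is.numeric(b) || b[1] >= b[2]) {
      stop(sprintf("`%s` must be an increasing length-2 numeric range", name),
           call. = FALSE)
    }
  }
  check_bounds(creat_per_kg_bounds_male, "creat_per_kg_bounds_male")
  check_bounds(creat_per_kg_bounds_female, "creat_per_kg_bounds_female")
  known <- c("min_volume", "creatinine_per_kg")
  if (!all(enabled_rules %in% known)) {
    stop("unknown completeness rule: ",
         paste(setdiff(enabled_rules, known), collapse = ", "), call. = FALSE)
  }
  structure(list(min_volume = min_volume,
                 creat_per_kg_bounds_male = creat_per_kg_bounds_male,
                 creat_per_kg_bounds_female = creat_per_kg_bounds_female,
                 enabled_rules = enabled_rules),
            class = "completeness_rules")
}

#' Screen 24-h collections for completeness
#'
#' Evaluates every enabled rule on each collection and flags the collection
#' complete iff none is violated. A pure function of its inputs: re-screening
#' never depends on the generator's own `complete` column.
#'
#' @param urine 24-h collection table (`participant_id`, `volume_l`,
#'   `creat_mg_dl`).
#' @param profiles participant table (`participant_id`, `sex`, `weight_kg`);
#'   required when the creatinine rule is enabled.
#' @param rules a [completeness_rules()] object.
#' @return a tibble with `participant_id`, `complete` (logical) and
#'   `violations` (comma-separated rule names, `""` when complete).
#' @export
screen_completeness <- function(urine, profiles = NULL,
                                rules = completeness_rules()) {
  stopifnot(inherits(rules, "completeness_rules"))
  n <- nrow(urine)
  viol <- vector("list", n)
  if ("min_volume" %in% rules$enabled_rules) {
    bad <- urine$volume_l < rules$min_volume
    viol <- add_violation(viol, bad, "min_volume")
  }
  if ("creatinine_per_kg" %in% rules$enabled_rules) {
    if (is.null(profiles)) {
      stop("creatinine_per_kg rule requires `profiles` (sex and weight)",
           call. = FALSE)
    }
    m <- match(urine$participant_id, profiles$participant_id)
    if (anyNA(m)) {
      stop("profiles missing for participants: ",
           paste(utils::head(urine$participant_id[is.na(m)], 5), collapse = ", "),
           call. = FALSE)
    }
    weight <- profiles$weight_kg[m]
    sex <- profiles$sex[m]
    if (anyNA(weight)) {
      stop("missing weight while the creatinine_per_kg rule is enabled",
           call. = FALSE)
    }
    creat_mg_day <- urine$creat_mg_dl * 10 * urine$volume_l
    per_kg <- creat_mg_day / weight
    lo <- ifelse(sex == "M", rules$creat_per_kg_bounds_male[1],
                 rules$creat_per_kg_bounds_female[1])
    hi <- ifelse(sex == "M", rules$creat_per_kg_bounds_male[2],
                 rules$creat_per_kg_bounds_female[2])
    viol <- add_violation(viol, per_kg < lo | per_kg > hi, "creatinine_per_kg")
  }
  tibble::tibble(
    participant_id = urine$participant_id,
    complete = lengths(viol) == 0,
    violations = vapply(viol, paste, "", collapse = ",")
  )
}

add_violation <- function(viol, bad, name) {
  bad[is.na(bad)] <- FALSE
  for (i in which(bad)) viol[[i]] <- c(viol[[i]], name)
  viol
}
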