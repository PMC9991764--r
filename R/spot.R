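# Spot-urine conversion equations. Every coefficient lives in the shipped
# registry (inst/extdata/spot_equations.csv) with a provenance note citing
# the original publication; nothing numeric is hard-coded here. The Kawasaki,
# Tanaka, Mage and Toft methods first predict 24-h creatinine excretion from
# the participant profile and scale the spot sodium/creatinine ratio; the two
# INTERSALT forms are direct linear models in spot concentrations, BMI and
# age with sex-specific coefficients.

SPOT_EQUATION_IDS <- c("kawasaki", "tanaka", "intersalt_with_k",
                       "intersalt_without_k", "mage", "toft")

.registry_cache <- new.env(parent = emptyenv())

#' The spot-equation coefficient registry
#'
#' Returns the registry of conversion-equation coefficients shipped with the
#' package as a human-readable CSV (`equation_id`, `sex`, `component`,
#' `term`, `coefficient`, `unit`, `provenance`). [estimate_spot_24h_na()]
#' and [predicted_creatinine_24h()] evaluate their formulas against this
#' table, so the transcription is auditable and replaceable in one place.
#'
#' @param path optional path to an alternative registry file.
#' @return a tibble.
#' @export
spot_equation_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.registry_cache$default)) return(.registry_cache$default)
    path <- system.file("extdata", "spot_equations.csv", package = "sodium24")
    reg <- readr::read_csv(path, col_types = "ccccdcc", progress = FALSE)
    reg$coefficient <- as.numeric(reg$coefficient)
    .registry_cache$default <- reg
    return(reg)
  }
  readr::read_csv(path, col_types = readr::cols(coefficient = "d",
                                                .default = "c"),
                  progress = FALSE)
}

# coefficient for one (equation, component, term), resolved per row by sex;
# rows tagged sex = "any" apply to both sexes. Missing term -> 0 only when
# `optional`, otherwise an error naming the term.
reg_coef <- function(reg, equation_id, component, term, sex, optional = FALSE) {
  rows <- reg[reg$equation_id == equation_id & reg$component == component &
                reg$term == term, ]
  if (!nrow(rows)) {
    if (optional) return(rep(0, length(sex)))
    stop(sprintf("registry has no term `%s` (%s) for equation `%s`",
                 term, component, equation_id), call. = FALSE)
  }
  if (any(rows$sex == "any")) return(rep(rows$coefficient[rows$sex == "any"][1],
                                         length(sex)))
  out <- rows$coefficient[match(sex, rows$sex)]
  if (anyNA(out)) {
    if (optional) return(ifelse(is.na(out), 0, out))
    stop(sprintf("registry term `%s` of `%s` lacks a coefficient for sex %s",
                 term, equation_id,
                 paste(unique(sex[is.na(out)]), collapse = ",")), call. = FALSE)
  }
  out
}

#' Predicted 24-h creatinine excretion
#'
#' Evaluates the creatinine sub-model of a ratio-based spot equation on
#' participant profiles. Kawasaki and Toft use sex-specific linear models in
#' age/weight(/height); Tanaka uses a single linear model; Mage scales
#' weight^1.5 x sqrt(height in metres) with a sex-specific constant.
#'
#' @param equation_id one of `"kawasaki"`, `"tanaka"`, `"mage"`, `"toft"`.
#' @param profile data frame with `age_y`, `sex`, `weight_kg`, `height_cm`.
#' @param registry coefficient table, see [spot_equation_registry()].
#' @return predicted creatinine excretion, mg/day.
#' @export
predicted_creatinine_24h <- function(equation_id, profile,
                                     registry = spot_equation_registry()) {
  equation_id <- match.arg(equation_id, c("kawasaki", "tanaka", "mage", "toft"))
  need <- c("age_y", "sex", "weight_kg", "height_cm")
  if (equation_id == "toft") need <- setdiff(need, "height_cm")
  missing_cols <- setdiff(need, names(profile))
  if (length(missing_cols)) {
    stop("profile is missing covariates: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  sex <- profile$sex
  cf <- function(term, component = "predicted_creatinine", optional = FALSE) {
    reg_coef(registry, equation_id, component, term, sex, optional)
  }
  if (equation_id == "mage") {
    return(cf("scale") * profile$weight_kg^1.5 * sqrt(profile$height_cm / 100))
  }
  out <- cf("intercept") +
    cf("age") * profile$age_y +
    cf("weight") * profile$weight_kg +
    cf("height", optional = equation_id == "toft") *
      (if (equation_id == "toft") 0 else profile$height_cm)
  out
}

#' Estimate 24-h sodium excretion from a spot urine sample
#'
#' Applies one of the six published conversion equations to spot-urine
#' concentrations and participant covariates and returns the estimated 24-h
#' sodium excretion in mg/day. Negative outputs of the linear INTERSALT
#' forms are floored at zero and flagged through the `"floored"` attribute.
#'
#' @param equation_id one of
#'   `r paste0('\x60"', SPOT_EQUATION_IDS, '"\x60', collapse = ", ")`.
#' @param spot data frame with `na_mmol_l`, `creat_mg_dl` and, for the
#'   INTERSALT-with-potassium equation, `k_mmol_l`.
#' @param profile data frame, aligned row-wise with `spot`, carrying
#'   `age_y`, `sex`, `weight_kg`, `height_cm`.
#' @param registry coefficient table, see [spot_equation_registry()].
#' @param molar_mass sodium molar mass used for the mmol -> mg conversion.
#' @return estimated sodium excretion, mg/day, with attribute `floored`
#'   (logical vector marking estimates clipped at zero).
#' @examples
#' prof <- data.frame(age_y = 56, sex = "M", weight_kg = 85, height_cm = 175)
#' spot <- data.frame(na_mmol_l = 100, k_mmol_l = 55, creat_mg_dl = 150)
#' estimate_spot_24h_na("tanaka", spot, prof)
#' @export
estimate_spot_24h_na <- function(equation_id, spot, profile,
                                 registry = spot_equation_registry(),
                                 molar_mass = 23.0) {
  equation_id <- match.arg(equation_id, SPOT_EQUATION_IDS)
  need_spot <- c("na_mmol_l", "creat_mg_dl")
  if (equation_id == "intersalt_with_k") need_spot <- c(need_spot, "k_mmol_l")
  missing_cols <- setdiff(need_spot, names(spot))
  if (length(missing_cols)) {
    stop(sprintf("spot sample is missing `%s` required by %s",
                 paste(missing_cols, collapse = ", "), equation_id),
         call. = FALSE)
  }
  for (col in need_spot) check_nonnegative(spot[[col]], col)
  sex <- profile$sex
  na <- spot$na_mmol_l
  cr_mg_l <- spot$creat_mg_dl * 10
  mmol <- switch(
    equation_id,
    kawasaki = {
      pr_cr <- predicted_creatinine_24h("kawasaki", profile, registry)
      reg_coef(registry, "kawasaki", "main", "scale", sex) *
        sqrt(na / cr_mg_l * pr_cr)
    },
    tanaka = {
      pr_cr <- predicted_creatinine_24h("tanaka", profile, registry)
      reg_coef(registry, "tanaka", "main", "scale", sex) *
        (na / cr_mg_l * pr_cr)^reg_coef(registry, "tanaka", "main", "exponent", sex)
    },
    mage = na / cr_mg_l * predicted_creatinine_24h("mage", profile, registry),
    toft = na / cr_mg_l * predicted_creatinine_24h("toft", profile, registry),
    intersalt_linear(equation_id, spot, profile, registry)
  )
  floored <- !is.na(mmol) & mmol < 0
  if (any(floored)) {
    warning(sprintf("%d negative %s estimate(s) floored at 0",
                    sum(floored), equation_id), call. = FALSE)
    mmol[floored] <- 0
  }
  out <- na_mmol_to_mg(mmol, molar_mass)
  attr(out, "floored") <- floored
  out
}

intersalt_linear <- function(equation_id, spot, profile, registry) {
  for (col in c("age_y", "sex", "weight_kg", "height_cm")) {
    if (!col %in% names(profile)) {
      stop(sprintf("profile is missing `%s` required by %s", col, equation_id),
           call. = FALSE)
    }
  }
  sex <- profile$sex
  bmi <- profile$weight_kg / (profile$height_cm / 100)^2
  cf <- function(term, optional = FALSE) {
    reg_coef(registry, equation_id, "main", term, sex, optional)
  }
  out <- cf("intercept") +
    cf("spot_na") * spot$na_mmol_l +
    cf("spot_cr_mmol") * creat_mg_dl_to_mmol_l(spot$creat_mg_dl) +
    cf("bmi") * bmi +
    cf("age") * profile$age_y +
    cf("age_sq", optional = TRUE) * ifelse(sex == "F", profile$age_y^2, 0)
  if (equation_id == "intersalt_with_k") {
    out <- out + cf("spot_k") * spot$k_mmol_l
  }
  out
}
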