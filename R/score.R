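#' Method identifiers of the estimation battery
#'
#' The twelve estimators the pipeline scores: the reference 24-h collection
#' (`u24`), the six spot-urine conversions, mean recall sodium (`dr24`), its
#' two discretionary-salt corrections (`dr24_sq`, `dr24_p15`), and the two
#' FFQ versions (`ffq`, `naffq`).
#'
#' @return character vector of method ids.
#' @export
method_ids <- function() {
  c("u24", "spot_kawasaki", "spot_tanaka", "spot_intersalt_k",
    "spot_intersalt_nok", "spot_mage", "spot_toft",
    "dr24", "dr24_sq", "dr24_p15", "ffq", "naffq")
}

spot_method_map <- function() {
  c(spot_kawasaki = "kawasaki", spot_tanaka = "tanaka",
    spot_intersalt_k = "intersalt_with_k",
    spot_intersalt_nok = "intersalt_without_k",
    spot_mage = "mage", spot_toft = "toft")
}

#' Score every estimation method on a cohort
#'
#' Runs the full battery - 24-h collection, six spot equations, mean recall,
#' recall + salt questions, recall + fixed 15% share, FFQ and NaFFQ - and
#' returns one long estimates table. Participants lacking an instrument
#' simply have no row for its methods, reproducing per-method sample sizes.
#'
#' @param cohort an `na_cohort` bundle, see [generate_cohort()].
#' @param composition food-composition table for FFQ scoring.
#' @param dashes_per_yes dashes of salt a table-salt "yes" represents (1 or 2).
#' @param dr15_share,dr15_mode parameters of [dr_plus_15_na()].
#' @param registry spot-equation coefficient registry.
#' @return a tibble `participant_id`, `method_id`, `na_mg_per_day`.
#' @export
score_cohort <- function(cohort, composition = food_composition(),
                         dashes_per_yes = 2, dr15_share = 0.15,
                         dr15_mode = "share_of_total",
                         registry = spot_equation_registry()) {
  out <- list()
  out$u24 <- tibble::tibble(
    participant_id = cohort$urine24$participant_id,
    method_id = "u24",
    na_mg_per_day = compute_24h_urinary_na(cohort$urine24)
  )

  if (nrow(cohort$spot)) {
    prof <- cohort$profiles[match(cohort$spot$participant_id,
                                  cohort$profiles$participant_id), ]
    map <- spot_method_map()
    for (mid in names(map)) {
      est <- estimate_spot_24h_na(map[[mid]], cohort$spot, prof, registry)
      out[[mid]] <- tibble::tibble(
        participant_id = cohort$spot$participant_id,
        method_id = mid,
        na_mg_per_day = as.numeric(est)
      )
    }
  }

  if (nrow(cohort$recalls)) {
    rec <- cohort$recalls
    # recall totals, then per-participant means (base aggregation: the
    # recall table can run to hundreds of thousands of rows)
    key_pr <- paste(rec$participant_id, rec$recall_idx)
    totals_pr <- rowsum(rec$item_grams * rec$item_na_mg_per_100g / 100, key_pr)
    pid_pr <- sub(" .*", "", rownames(totals_pr))
    dr24 <- tapply(as.vector(totals_pr), pid_pr, mean)
    # quantified salt questions: q1/q2 are per (recall, meal), grams summed
    main <- rec[rec$meal %in% c("breakfast", "lunch", "dinner"), ]
    disc_mean <- NULL
    if (nrow(main)) {
      key_m <- paste(main$participant_id, main$recall_idx, main$meal)
      grams_m <- rowsum(main$item_grams, key_m)
      first <- !duplicated(key_m)
      ord <- match(rownames(grams_m), key_m[first])
      disc_na <- suppressWarnings(
        q1_na(main$q1[first][ord], as.vector(grams_m)) +
          q2_na(main$q2[first][ord], dashes_per_yes))
      key_r <- paste(main$participant_id, main$recall_idx)[first][ord]
      disc_r <- rowsum(disc_na, key_r)
      disc_mean <- tapply(as.vector(disc_r),
                          sub(" .*", "", rownames(disc_r)), mean)
    }
    pid <- names(dr24)
    disc_of <- rep(0, length(pid))
    if (!is.null(disc_mean)) {
      m <- match(pid, names(disc_mean))
      disc_of <- ifelse(is.na(m), 0, disc_mean[m])
    }
    out$dr24 <- tibble::tibble(participant_id = pid, method_id = "dr24",
                               na_mg_per_day = as.numeric(dr24))
    out$dr24_sq <- tibble::tibble(
      participant_id = pid, method_id = "dr24_sq",
      na_mg_per_day = as.numeric(dr24) + as.numeric(disc_of))
    out$dr24_p15 <- tibble::tibble(
      participant_id = pid, method_id = "dr24_p15",
      na_mg_per_day = dr_plus_15_na(as.numeric(dr24), dr15_share, dr15_mode))
  }

  if (nrow(cohort$ffq)) {
    ffq <- cohort$ffq
    m <- match(ffq$item_id, composition$item_id)
    if (anyNA(m)) {
      stop("unresolvable FFQ item(s): ",
           paste(unique(ffq$item_id[is.na(m)]), collapse = ", "), call. = FALSE)
    }
    daily_g <- frequency_weight(ffq$freq_cat) * ffq$portion_g
    food_na <- daily_g * composition$na_mg_per_100g[m] / 100
    cooked <- composition$is_cooked_meal_or_salad[m] == 1
    qb_rate <- ifelse(is.na(ffq$question_b), 0,
                      question_b_rates()[ffq$question_b])
    disc_na <- ifelse(ffq$version == "naffq" & cooked,
                      qb_rate * daily_g / 100, 0)
    for (v in c("standard", "naffq")) {
      sel <- ffq$version == v
      if (!any(sel)) next
      tot <- rowsum((food_na + disc_na)[sel], ffq$participant_id[sel])
      mid <- if (v == "standard") "ffq" else "naffq"
      out[[mid]] <- tibble::tibble(participant_id = rownames(tot),
                                   method_id = mid,
                                   na_mg_per_day = as.vector(tot))
    }
  }

  est <- dplyr::bind_rows(out)
  est$method_id <- factor(est$method_id, levels = method_ids())
  dplyr::arrange(est, .data$method_id, .data$participant_id) |>
    dplyr::mutate(method_id = as.character(.data$method_id))
}
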