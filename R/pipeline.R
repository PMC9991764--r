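#' Configuration of a full pipeline run
#'
#' A run is a pure function of its configuration: generator parameters,
#' completeness rules, scoring switches, the output directory and a log
#' level. Fully serialisable to YAML (see [read_run_config()]), so the
#' manifest written by [run_pipeline()] suffices to reproduce a run.
#'
#' @param generator a [generator_params()] object (or a list of overrides).
#' @param completeness a [completeness_rules()] object.
#' @param dashes_per_yes table-salt quantification switch, see [q2_na()].
#' @param dr15_share,dr15_mode fixed-share correction switches, see
#'   [dr_plus_15_na()].
#' @param icc_form reported ICC form, see [icc_estimate()].
#' @param sensitivity also produce the complete-collections-only comparison.
#' @param out_dir output directory.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return an object of class `run_config`.
#' @export
run_config <- function(generator = generator_params(),
                       completeness = completeness_rules(),
                       dashes_per_yes = 2,
                       dr15_share = 0.15,
                       dr15_mode = "share_of_total",
                       icc_form = "absolute_agreement",
                       sensitivity = TRUE,
                       out_dir = "sodium24_run",
                       log_level = "info") {
  if (!inherits(generator, "generator_params")) {
    generator <- do.call(generator_params, as.list(generator))
  }
  if (!inherits(completeness, "completeness_rules")) {
    completeness <- do.call(completeness_rules, as.list(completeness))
  }
  structure(list(generator = generator, completeness = completeness,
                 dashes_per_yes = dashes_per_yes, dr15_share = dr15_share,
                 dr15_mode = dr15_mode, icc_form = icc_form,
                 sensitivity = isTRUE(sensitivity), out_dir = out_dir,
                 log_level = log_level),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with top-level keys mirroring the arguments.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$generator)) args$generator <- do.call(generator_params, raw$generator)
  if (!is.null(raw$completeness)) args$completeness <- do.call(completeness_rules, raw$completeness)
  for (nm in c("dashes_per_yes", "dr15_share", "dr15_mode", "icc_form",
               "sensitivity", "out_dir", "log_level")) {
    if (!is.null(raw[[nm]])) args[[nm]] <- raw[[nm]]
  }
  do.call(run_config, args)
}

pipeline_log <- function(config, level, fmt, ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[config$log_level]] >= levels[[level]]) {
    message(sprintf("[sodium24] %s", sprintf(fmt, ...)))
  }
}

#' Run the simulate -> score -> compare -> report pipeline
#'
#' Generates a cohort, writes it to disk, scores all twelve methods,
#' screens collection completeness, builds the method-comparison table
#' (plus the complete-collections-only sensitivity table when requested),
#' writes per-method Bland-Altman plot data, and renders a human-readable
#' report next to a machine-readable full-precision companion. A manifest
#' (configuration echo, seed, package version) makes the run reproducible;
#' identical configurations produce bit-identical outputs.
#'
#' @param config a [run_config()].
#' @return the report bundle (cohort, estimates, completeness, comparison
#'   tables, output paths), invisibly.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage `%s` failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cohort <- stage("simulate", generate_cohort(config$generator))
  pipeline_log(config, "info", "simulate: %d participants (seed %d)",
               nrow(cohort$profiles), config$generator$seed)
  cohort_dir <- file.path(out_dir, "cohort")
  stage("simulate", write_cohort(cohort, cohort_dir))

  estimates <- stage("score", score_cohort(
    cohort, dashes_per_yes = config$dashes_per_yes,
    dr15_share = config$dr15_share, dr15_mode = config$dr15_mode))
  readr::write_csv(estimates, file.path(out_dir, "estimates.csv"))
  pipeline_log(config, "info", "score: %d estimate rows, %d methods",
               nrow(estimates), length(unique(estimates$method_id)))

  completeness <- stage("screen", screen_completeness(
    cohort$urine24, cohort$profiles, config$completeness))
  pipeline_log(config, "info", "screen: %d of %d collections incomplete",
               sum(!completeness$complete), nrow(completeness))

  comparison <- stage("compare", compare_all(
    estimates, completeness, sensitivity = FALSE, icc_form = config$icc_form))
  readr::write_csv(comparison, file.path(out_dir, "comparison_table.csv"))
  comparison_sens <- NULL
  if (config$sensitivity) {
    comparison_sens <- stage("compare", compare_all(
      estimates, completeness, sensitivity = TRUE, icc_form = config$icc_form))
    readr::write_csv(comparison_sens,
                     file.path(out_dir, "comparison_table_sensitivity.csv"))
  }

  stage("report", {
    ref <- estimates[estimates$method_id == "u24", ]
    for (mid in setdiff(unique(estimates$method_id), "u24")) {
      est <- estimates[estimates$method_id == mid, ]
      m <- match(ref$participant_id, est$participant_id)
      ok <- !is.na(m)
      if (sum(ok) < 3) next
      ba <- bland_altman(ref$na_mg_per_day[ok], est$na_mg_per_day[m[ok]],
                         ref$participant_id[ok])
      readr::write_csv(ba$data,
                       file.path(out_dir, sprintf("bland_altman_%s.csv", mid)))
    }
    writeLines(render_report(comparison, comparison_sens),
               file.path(out_dir, "report.txt"))
    jsonlite::write_json(
      list(comparison = comparison, sensitivity = comparison_sens),
      file.path(out_dir, "report.json"),
      dataframe = "rows", digits = NA, auto_unbox = TRUE, null = "null")
    jsonlite::write_json(
      manifest(config),
      file.path(out_dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  })
  pipeline_log(config, "info", "report: written to %s", out_dir)

  invisible(list(cohort = cohort, estimates = estimates,
                 completeness = completeness, comparison = comparison,
                 comparison_sensitivity = comparison_sens,
                 out_dir = out_dir))
}

manifest <- function(config) {
  list(
    package = "sodium24",
    version = as.character(packageVersion("sodium24")),
    seed = config$generator$seed,
    config = list(
      generator = unclass(config$generator),
      completeness = unclass(config$completeness),
      dashes_per_yes = config$dashes_per_yes,
      dr15_share = config$dr15_share, dr15_mode = config$dr15_mode,
      icc_form = config$icc_form, sensitivity = config$sensitivity
    )
  )
}

#' Render the comparison table as a text report
#'
#' Human-readable tables with values rounded to one decimal (every printed
#' cell equals the full-precision value rounded to one decimal; the
#' machine-readable JSON companion keeps full precision) and ICC
#' reliability labels. No multiple-testing adjustment is applied to the
#' reported p-values.
#'
#' @param comparison comparison table from [compare_all()].
#' @param sensitivity optional sensitivity comparison table.
#' @return character vector of report lines.
#' @export
render_report <- function(comparison, sensitivity = NULL) {
  lines <- c("Sodium estimation methods vs 24-h urine collection",
             "difference = reference - estimate (negative bias = overestimation)",
             "p-values unadjusted for multiple testing", "")
  lines <- c(lines, render_comparison_block(comparison))
  if (!is.null(sensitivity)) {
    lines <- c(lines, "", "Sensitivity analysis (complete collections only)",
               render_comparison_block(sensitivity))
  }
  lines
}

render_comparison_block <- function(tab) {
  header <- sprintf(
    "%-18s %5s %10s %10s %8s %9s %8s %8s %10s %10s %-9s",
    "method", "n", "mean", "bias", "p", "r", "rho", "ICC",
    "LoA.lo", "LoA.hi", "class")
  if (is.null(tab) || !nrow(tab)) return(c(header, "  (no rows)"))
  fmt1 <- function(x) ifelse(is.na(x), "-", sprintf("%.1f", round(x, 1)))
  fmt3 <- function(x) ifelse(is.na(x), "-", sprintf("%.3f", x))
  rows <- vapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (!"bias_mean" %in% names(r) || is.na(r$bias_mean %||% NA)) {
      return(sprintf("%-18s %5d   (insufficient pairs)", r$method_id, r$n))
    }
    sprintf("%-18s %5d %10s %10s %8s %9s %8s %8s %10s %10s %-9s",
            r$method_id, r$n, fmt1(r$mean_estimate), fmt1(r$bias_mean),
            fmt3(r$p_paired), fmt3(r$pearson_r), fmt3(r$spearman_rho),
            sprintf("%.2f", r$icc), fmt1(r$loa_lower), fmt1(r$loa_upper),
            r$icc_class)
  }, "")
  c(header, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
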