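#' Unit bridges for sodium and salt
#'
#' Convert urinary sodium between mmol and mg, and sodium mass to the
#' equivalent mass of salt (NaCl). The sodium molar mass defaults to the
#' conventional 23.0 mg/mmol used in dietary work; pass
#' `molar_mass = 22.9898` for the exact atomic weight. The salt conversion
#' uses the ratio 2.5 g salt per 1 g sodium (0.6 g sodium = 1.5 g salt).
#'
#' @param x numeric vector, non-negative (mmol for [na_mmol_to_mg()], mg for
#'   the others).
#' @param molar_mass sodium molar mass in mg/mmol.
#' @return numeric vector in the target unit.
#' @examples
#' na_mmol_to_mg(100)      # 2300
#' na_mg_to_salt_g(600)    # 1.5
#' @export
na_mmol_to_mg <- function(x, molar_mass = 23.0) {
  check_nonnegative(x, "x")
  x * molar_mass
}

#' @rdname na_mmol_to_mg
#' @export
na_mg_to_mmol <- function(x, molar_mass = 23.0) {
  check_nonnegative(x, "x")
  x / molar_mass
}

#' @rdname na_mmol_to_mg
#' @export
na_mg_to_salt_g <- function(x) {
  check_nonnegative(x, "x")
  x * 2.5 / 1000
}

# creatinine: mg/dL -> mmol/L (molar mass 113.12 g/mol)
creat_mg_dl_to_mmol_l <- function(x) x * 10 / 113.12

check_nonnegative <- function(x, name) {
  if (!is.numeric(x)) stop(sprintf("`%s` must be numeric", name), call. = FALSE)
  if (any(x < 0, na.rm = TRUE)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}
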