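#' Drinking-water guideline limits
#'
#' Philippine National Standards for Drinking Water (PNSDW 2017) and WHO
#' guideline values for the survey schema. Heavy metals in ppm, TDS in
#' mg/L, EC in uS/cm; pH is a range. `NA` where a body sets no limit.
#'
#' @return A tibble with `parameter`, `pnsdw_lo`, `pnsdw_hi`, `who_lo`,
#'   `who_hi`. For single-sided limits the `_lo` entry is `NA` and the
#'   `_hi` entry is the maximum allowed value.
#' @export
guideline_table <- function() {
  tibble::tribble(
    ~parameter, ~pnsdw_lo, ~pnsdw_hi, ~who_lo, ~who_hi,
    "pH",       6.5,       8.5,       6.5,     9.2,
    "EC",       NA,        NA,        NA,      1500,
    "TDS",      NA,        600,       NA,      1200,
    "Cr",       NA,        0.050,     NA,      0.050,
    "Cd",       NA,        0.003,     NA,      0.003,
    "Fe",       NA,        1.000,     NA,      0.300,
    "Mn",       NA,        0.400,     NA,      0.400,
    "Ni",       NA,        0.070,     NA,      0.070,
    "Pb",       NA,        0.010,     NA,      0.010,
    "Zn",       NA,        5.000,     NA,      3.000,
    "Cu",       NA,        1.000,     NA,      2.000
  )
}

flag_one <- function(values, lo, hi) {
  # exceed = outside the permitted interval (one- or two-sided)
  below <- if (is.na(lo)) rep(FALSE, length(values)) else values < lo
  above <- if (is.na(hi)) rep(FALSE, length(values)) else values > hi
  below | above
}

#' Flag guideline exceedances
#'
#' Compares each parameter's mean (and individual stations) against the
#' PNSDW 2017 and WHO limits. For pH, membership of the permitted range is
#' tested; for the other parameters the upper limit applies.
#'
#' @param s Survey tibble.
#' @param guidelines Guideline tibble, by default [guideline_table()].
#' @param parameters Parameters to screen (default: all present in both).
#' @return Tibble with one row per parameter: `mean`, `exceeds_pnsdw`,
#'   `exceeds_who` (mean vs limit, `NA` if no limit), and
#'   `n_above_pnsdw`/`n_above_who` station counts.
#' @export
guideline_flags <- function(s, guidelines = guideline_table(),
                            parameters = NULL) {
  present <- intersect(.gw_parameters, names(s))
  parameters <- parameters %||% present
  skipped <- setdiff(parameters, guidelines$parameter)
  if (length(skipped) > 0) {
    warn(paste0("no guideline for parameter(s), skipped: ",
                paste(skipped, collapse = ", ")))
  }
  parameters <- intersect(parameters, guidelines$parameter)
  purrr::map_dfr(parameters, function(p) {
    v <- s[[p]][!is.na(s[[p]])]
    g <- guidelines[guidelines$parameter == p, ]
    m <- mean(v)
    has_pnsdw <- !is.na(g$pnsdw_lo) || !is.na(g$pnsdw_hi)
    has_who <- !is.na(g$who_lo) || !is.na(g$who_hi)
    tibble(
      parameter = p, n = length(v), mean = m,
      exceeds_pnsdw = if (has_pnsdw) flag_one(m, g$pnsdw_lo, g$pnsdw_hi) else NA,
      exceeds_who = if (has_who) flag_one(m, g$who_lo, g$who_hi) else NA,
      n_above_pnsdw = if (has_pnsdw) sum(flag_one(v, g$pnsdw_lo, g$pnsdw_hi)) else NA_integer_,
      n_above_who = if (has_who) sum(flag_one(v, g$who_lo, g$who_hi)) else NA_integer_
    )
  })
}
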