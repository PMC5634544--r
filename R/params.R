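#' Model parameters for the energy allocation model
#'
#' Bundles the full parameter set for one scenario of the energy allocation
#' (EA) model of sleep: the two price constants, the circadian mean and
#' amplitude, the sleep quota, and the four phase-specific energy rates.
#' Defaults are the model's standard parameters (`p_W = 1.3`, `p_B1 = 0.7`,
#' `m_C = 5`, `A = 2.5`) with an 8 h sleep quota and all four energy rates
#' at 0.5 energy units per day.
#'
#' Time is measured in days, so one wake-sleep period has length 1; the
#' sleep quota is entered in hours and converted internally via `TST_h/24`.
#' The day begins with wake on `[0, 1 - TST_h/24)` followed by sleep on
#' `[1 - TST_h/24, 1]`; the switch time itself belongs to sleep.
#'
#' @param p_W Price of waking effort (dimensionless multiplier, >= 0).
#' @param p_B1 Proportionality constant of the biological-investment price
#'   `p_B(t) = p_B1 * BD(t)` (dimensionless, >= 0).
#' @param m_C Circadian mean level (dimensionless, > 0).
#' @param A Circadian amplitude, half the peak-to-trough range
#'   (dimensionless, `0 <= A < m_C` so the multiplier stays positive).
#' @param TST_h Total sleep time per day, hours, in `[0, 24)`.
#' @param r_Ww,r_Bw Wake-phase energy rates toward waking effort and
#'   biological investment (energy/day, >= 0).
#' @param r_Ws,r_Bs Sleep-phase energy rates (energy/day, >= 0).
#'
#' @return An object of class `ea_params`: a validated named list with the
#'   nine fields above.
#' @examples
#' p <- ea_params()
#' p
#' ea_params(TST_h = 0, r_Ws = 0.5, r_Bs = 0.5) # continuous-wake scenario
#' @export
ea_params <- function(p_W = 1.3, p_B1 = 0.7, m_C = 5, A = 2.5, TST_h = 8,
                      r_Ww = 0.5, r_Bw = 0.5, r_Ws = 0.5, r_Bs = 0.5) {
  p <- list(
    p_W = p_W, p_B1 = p_B1, m_C = m_C, A = A, TST_h = TST_h,
    r_Ww = r_Ww, r_Bw = r_Bw, r_Ws = r_Ws, r_Bs = r_Bs
  )
  validate_ea_params(p)
  structure(p, class = "ea_params")
}

validate_ea_params <- function(p) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (nm in names(p)) {
    if (!num1(p[[nm]])) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (p$p_W < 0) abort("`p_W` must be non-negative.")
  if (p$p_B1 < 0) abort("`p_B1` must be non-negative.")
  if (p$m_C <= 0) abort("`m_C` must be positive.")
  if (p$A < 0) abort("`A` must be non-negative.")
  if (p$A >= p$m_C) {
    abort("`A` must be smaller than `m_C` so the circadian multiplier stays positive.")
  }
  if (p$TST_h < 0 || p$TST_h >= 24) abort("`TST_h` must lie in [0, 24).")
  for (nm in c("r_Ww", "r_Bw", "r_Ws", "r_Bs")) {
    if (p[[nm]] < 0) abort(sprintf("`%s` must be non-negative.", nm))
  }
  invisible(p)
}

#' @export
print.ea_params <- function(x, ...) {
  cat("<ea_params>\n")
  cat(sprintf("  prices:    p_W = %g, p_B1 = %g\n", x$p_W, x$p_B1))
  cat(sprintf("  circadian: m_C = %g, A = %g\n", x$m_C, x$A))
  cat(sprintf("  schedule:  TST = %g h (wake [0, %.4g), sleep [%.4g, 1])\n",
              x$TST_h, 1 - x$TST_h / 24, 1 - x$TST_h / 24))
  cat(sprintf("  rates:     wake r_W = %g, r_B = %g; sleep r_W = %g, r_B = %g\n",
              x$r_Ww, x$r_Bw, x$r_Ws, x$r_Bs))
  invisible(x)
}

#' Test for ea_params objects
#' @param x An object.
#' @return `TRUE` if `x` is an `ea_params` object.
#' @export
is_ea_params <- function(x) inherits(x, "ea_params")

# fraction of the day asleep / switch time
tst_frac <- function(params) params$TST_h / 24
switch_time <- function(params) 1 - params$TST_h / 24

# parameter vector in the order the compiled derivatives expect
parms_vec <- function(params) {
  c(params$p_W, params$p_B1, params$m_C, params$A, tst_frac(params),
    params$r_Ww, params$r_Bw, params$r_Ws, params$r_Bs)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced, re-validated.
#'
#' @param params An [ea_params()] object.
#' @param ... Named fields to replace (any of the [ea_params()] arguments).
#' @return A new `ea_params` object.
#' @examples
#' ea_update(ea_params(), A = 0, TST_h = 12)
#' @export
ea_update <- function(params, ...) {
  stopifnot(is_ea_params(params))
  new <- modifyList(unclass(params), list(...))
  do.call(ea_params, new)
}

#' Wake/sleep phase schedule of a parameter set
#'
#' @param params An [ea_params()] object.
#' @return A tibble with one row per phase: `phase`, `from`, `to` (times in
#'   days). With `TST_h = 0` the sleep row is absent.
#' @examples
#' phase_schedule(ea_params(TST_h = 8))
#' @export
phase_schedule <- function(params) {
  stopifnot(is_ea_params(params))
  ts <- switch_time(params)
  out <- tibble(phase = "wake", from = 0, to = ts)
  if (params$TST_h > 0) {
    out <- dplyr::bind_rows(out, tibble(phase = "sleep", from = ts, to = 1))
  }
  out
}
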