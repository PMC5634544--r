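#' Circadian efficiency multiplier C(t)
#'
#' The circadian process enters the model as an efficiency multiplier in
#' the conversion of energy to biological investment,
#' `C(t) = m_C - A * sin(2*pi*(t - 0.25 + 0.5 * TST/24))`.
#' It has period one day, mean `m_C`, range `[m_C - A, m_C + A]`, and its
#' peak falls in the middle of the sleep phase (`t = 1 - TST/48`).
#'
#' @param t Time within the day, in days (vectorized).
#' @param params An [ea_params()] object.
#' @return Numeric vector of multiplier values.
#' @examples
#' p <- ea_params(m_C = 5, A = 2.5, TST_h = 8)
#' circadian_efficiency(1 - 8 / 48, p) # peak, m_C + A = 7.5
#' @export
circadian_efficiency <- function(t, params) {
  stopifnot(is_ea_params(params))
  params$m_C - params$A * sin(2 * pi * (t - 0.25 + 0.5 * tst_frac(params)))
}

#' Price of biological investment p_B(BD)
#'
#' The price of investing grows linearly with the outstanding biological
#' debt: `p_B = p_B1 * BD`.
#'
#' @param bd Biological debt (must be positive; vectorized).
#' @param params An [ea_params()] object.
#' @return Numeric vector of prices.
#' @examples
#' investment_price(0.336, ea_params())
#' @export
investment_price <- function(bd, params) {
  stopifnot(is_ea_params(params))
  if (any(bd <= 0)) abort("`bd` must be positive: biological debt BD > 0.")
  params$p_B1 * bd
}

#' Conversion efficiency x_B(t, BD)
#'
#' Fraction-like factor converting the investment energy stream into
#' completed biological investment, `x_B = C(t) * BD / (1 + BD^2)`. It
#' combines the circadian multiplier with a reactive homeostatic component
#' that is low at low debt, peaks at `BD = 1` (value `C(t)/2`), and decays
#' to zero as debt grows.
#'
#' @param t Time within the day, in days.
#' @param bd Biological debt (non-negative; the limit value 0 is returned
#'   at `bd = 0`).
#' @param params An [ea_params()] object.
#' @return Numeric vector of conversion factors.
#' @examples
#' conversion_efficiency(0.5, 1, ea_params(A = 0)) # maximum m_C/2
#' @export
conversion_efficiency <- function(t, bd, params) {
  stopifnot(is_ea_params(params))
  if (any(bd < 0)) abort("`bd` must be non-negative.")
  circadian_efficiency(t, params) * bd / (1 + bd^2)
}

#' Energy rates in force at a time of day
#'
#' Rates are constant within a behavioral state but differ between states:
#' `(r_Ww, r_Bw)` during wake, `(r_Ws, r_Bs)` during sleep. The switch
#' time `1 - TST/24` belongs to the sleep phase; with `TST_h = 0` the day
#' is all wake.
#'
#' @param t Time within the day, in days (vectorized).
#' @param params An [ea_params()] object.
#' @return A tibble with columns `t`, `phase`, `r_W`, `r_B`.
#' @examples
#' phase_rates(c(0.5, 0.9), ea_params(TST_h = 8))
#' @export
phase_rates <- function(t, params) {
  stopifnot(is_ea_params(params))
  asleep <- params$TST_h > 0 & t >= switch_time(params)
  tibble(
    t = t,
    phase = ifelse(asleep, "sleep", "wake"),
    r_W = ifelse(asleep, params$r_Ws, params$r_Ww),
    r_B = ifelse(asleep, params$r_Bs, params$r_Bw)
  )
}

#' Model right-hand side
#'
#' Instantaneous growth rates of biological requirements and investment:
#' `dBR/dt = p_W * r_W(t) + p_B1 * BD * r_B(t)` and
#' `dBI/dt = x_B(t, BD) * r_B(t)`, with `BD = BR - BI`. The implied scalar
#' debt equation is
#' `dBD/dt = p_W * r_W + r_B * (p_B1 * BD - C(t) * BD / (1 + BD^2))`,
#' which depends on the state only through `BD` — the basis for the
#' scalar-reduction integration route.
#'
#' @param t Time within the day, in days.
#' @param state Named numeric vector or list with `BR` and `BI` (and the
#'   implied `BD = BR - BI > 0`).
#' @param params An [ea_params()] object.
#' @return Named list with `dBR`, `dBI`, `dBD`.
#' @examples
#' ea_rhs(0.1, c(BR = 0.4, BI = 0.064), ea_params(TST_h = 0))
#' @export
ea_rhs <- function(t, state, params) {
  stopifnot(is_ea_params(params))
  state <- as.list(state)
  bd <- state$BR - state$BI
  if (!is.finite(bd) || bd <= 0) {
    abort("Invalid state: biological debt BD = BR - BI must be positive.")
  }
  r <- phase_rates(t, params)
  dBR <- params$p_W * r$r_W + investment_price(bd, params) * r$r_B
  dBI <- conversion_efficiency(t, bd, params) * r$r_B
  list(dBR = dBR, dBI = dBI, dBD = dBR - dBI)
}

#' Daily reset rule
#'
#' At the start of each day the bookkeeping is rebased: completed
#' investment is zeroed and requirements are set to the outstanding debt,
#' so `BD` itself is continuous across the day boundary.
#'
#' @param state Named numeric vector or list with `BR` and `BI`.
#' @return Named numeric vector `c(t = 0, BR = BD_end, BI = 0, BD = BD_end)`.
#' @examples
#' daily_reset(c(BR = 5, BI = 4.664))
#' @export
daily_reset <- function(state) {
  state <- as.list(state)
  bd <- state$BR - state$BI
  c(t = 0, BR = bd, BI = 0, BD = bd)
}
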