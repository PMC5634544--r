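# Day integration. All integration goes through deSolve::ode (lsoda) with
# the compiled right-hand sides in src/ea_ode.c, in two segments with a
# breakpoint at the wake->sleep switch so the discontinuous rates are never
# stepped across. Relative tolerance 1e-10, absolute 1e-12.

BD_FLOOR <- 1e-12
RTOL <- 1e-10
ATOL <- 1e-12

invalid_trajectory <- function(bd) {
  abort(
    sprintf("Invalid trajectory: BD reached the positivity floor (min BD = %.3g).", bd),
    class = "easleep_invalid_trajectory"
  )
}

# integrate one of the compiled systems over [0, 1], honoring the phase
# breakpoint; `times` are the requested output times (must include 0 and 1)
ode_day <- function(y0, times, params, func) {
  ts <- switch_time(params)
  pv <- parms_vec(params)
  run <- function(y, tt) {
    deSolve::ode(
      y = y, times = tt, func = func, parms = pv,
      dllname = "easleep", initfunc = "ea_init",
      method = "lsoda", rtol = RTOL, atol = ATOL
    )
  }
  if (ts > 0 && ts < 1) {
    t1 <- sort(unique(c(times[times <= ts], ts)))
    t2 <- sort(unique(c(ts, times[times >= ts])))
    if (length(t1) == 1L) t1 <- c(0, t1)
    o1 <- run(y0, t1)
    o2 <- run(o1[nrow(o1), -1], t2)
    out <- rbind(o1, o2[-1, , drop = FALSE])
  } else {
    out <- run(y0, sort(unique(times)))
  }
  out
}

# fast scalar route: end-of-day BD only
day_end_bd <- function(params, bd0) {
  out <- ode_day(c(BD = bd0), c(0, 1), params, "ea_deriv_bd")
  bd <- out[, 2]
  if (any(!is.finite(bd)) || min(bd) <= BD_FLOOR) invalid_trajectory(min(bd))
  bd[length(bd)]
}

# dense scalar route for cycle averages
day_dense_bd <- function(params, bd0, n = 401) {
  tt <- seq(0, 1, length.out = n)
  out <- ode_day(c(BD = bd0), tt, params, "ea_deriv_bd")
  bd <- out[, 2]
  if (any(!is.finite(bd)) || min(bd) <= BD_FLOOR) invalid_trajectory(min(bd))
  list(t = out[, 1], BD = bd)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Integrate the model over one day
#'
#' Solves the (BR, BI) system from the start-of-day state
#' `(BR = bd0, BI = 0)` over `[0, 1]` days, with a breakpoint at the
#' wake-to-sleep switch and adaptive error control (relative tolerance
#' 1e-10). The trajectory is flagged invalid (an error of class
#' `easleep_invalid_trajectory`) if the debt ever reaches the positivity
#' floor of 1e-12.
#'
#' @param params An [ea_params()] object.
#' @param bd0 Start-of-day biological debt (> 0).
#' @param n Number of output points on `[0, 1]` (the switch time is added).
#' @return A tibble of class `ea_trajectory` with columns `t`, `BR`, `BI`,
#'   `BD` and attributes `params` and `bd_end`.
#' @examples
#' tr <- integrate_day(ea_params(TST_h = 0), bd0 = 0.336)
#' tail(tr, 1)
#' @export
integrate_day <- function(params, bd0, n = 401) {
  stopifnot(is_ea_params(params))
  if (!is.numeric(bd0) || length(bd0) != 1L || !is.finite(bd0) || bd0 <= 0) {
    abort("`bd0` must be a single positive number.")
  }
  tt <- seq(0, 1, length.out = n)
  out <- ode_day(c(BR = bd0, BI = 0), tt, params, "ea_deriv_pair")
  bd <- out[, 2] - out[, 3]
  if (any(!is.finite(bd)) || min(bd) <= BD_FLOOR) invalid_trajectory(min(bd))
  traj <- tibble(t = out[, 1], BR = out[, 2], BI = out[, 3], BD = bd)
  structure(traj,
    class = c("ea_trajectory", class(traj)),
    params = params, bd_end = bd[length(bd)]
  )
}

#' Poincare map of start-of-day debt
#'
#' Maps the biological debt at the start of a day to the debt at its end,
#' `P(BD0) = BD(1)`, by integrating the scalar debt equation. Fixed points
#' of `P` are the model's daily limit cycles. The map is strictly
#' increasing in `BD0` (one-dimensional flow).
#'
#' @param params An [ea_params()] object.
#' @param bd0 Start-of-day debt (vectorized over values > 0).
#' @return Numeric vector `P(bd0)`.
#' @examples
#' p <- ea_params(TST_h = 0)
#' poincare_map(p, c(0.1, 0.336, 1))
#' @export
poincare_map <- function(params, bd0) {
  stopifnot(is_ea_params(params))
  if (any(bd0 <= 0)) abort("`bd0` must be positive.")
  vapply(bd0, function(b) day_end_bd(params, b), numeric(1))
}

#' Time-averaged biological debt of a trajectory or cycle
#'
#' Trapezoidal quadrature of `BD(t)` over the stored time grid. For a
#' periodic (limit-cycle) trajectory this is the model's "average BD",
#' the quantity equalized across strategies before comparing metabolic
#' rates.
#'
#' @param x An `ea_trajectory` from [integrate_day()], or a data frame
#'   with columns `t` and `BD`.
#' @return A single number, the time average of `BD`.
#' @examples
#' mean_bd(integrate_day(ea_params(TST_h = 0), 0.336))
#' @export
mean_bd <- function(x) {
  if (!all(c("t", "BD") %in% names(x))) {
    abort("`x` must have columns `t` and `BD`.")
  }
  trapz(x$t, x$BD) / (max(x$t) - min(x$t))
}
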