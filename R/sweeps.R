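# Parameter sweeps and multi-day runs: the model's computational
# experiments over MAI, TST, rho, circadian amplitude, the price/circadian
# constants, and chronic sleep restriction.

new_sweep <- function(tbl, swept, params, baseline) {
  structure(tbl, class = c("ea_sweep", class(tbl)),
            swept = swept, params = params, baseline = baseline)
}

# one resolved strategy as a sweep row; NA row when no periodic solution
strategy_row <- function(params, rho, mai_target, baseline, step = 0.02) {
  res <- tryCatch(
    match_mean_bd(params, rho, mai_target, baseline = baseline, step = step),
    easleep_no_cycle = function(e) NULL
  )
  if (is.null(res)) {
    return(tibble(
      exists = FALSE, r_Ww = params$r_Ww, r_Bw = NA_real_, r_Ws = NA_real_,
      r_Bs = NA_real_, mai_achieved = NA_real_, bd0 = NA_real_,
      m_bd = NA_real_, m_mr = NA_real_, matched = NA
    ))
  }
  tibble(
    exists = TRUE, r_Ww = res$params$r_Ww, r_Bw = res$params$r_Bw,
    r_Ws = res$params$r_Ws, r_Bs = res$params$r_Bs,
    mai_achieved = res$mai_achieved, bd0 = res$bd0,
    m_bd = res$m_bd, m_mr = res$m_mr, matched = res$matched
  )
}

add_savings <- function(tbl, m_mr1, m_mr2) {
  es <- energy_savings(m_mr1, m_mr2, m_mr2) # es_rho component
  dplyr::mutate(
    tbl,
    es_rho = ifelse(.data$exists, es$es_rho, NA_real_),
    es_total = ifelse(.data$exists, 100 * (m_mr1 - .data$m_mr) / m_mr1, NA_real_),
    es_mai = .data$es_total - .data$es_rho
  )
}

#' Sweep the target metabolic allocation index
#'
#' Varies the target MAI while holding `rho` and the sleep quota constant,
#' resolving each grid point with the mean-debt matching protocol.
#' Records the achieved MAI (the non-negativity clamp on `r_Ws` caps it)
#' and the energy-savings split. With the standard parameters, an 8 h
#' quota and `rho = 0.3`, the achievable MAI is capped near 0.7.
#'
#' @param params An [ea_params()] object (prices, circadian constants,
#'   `r_Ww`).
#' @param mai_grid Target MAI grid.
#' @param rho Metabolic rate reduction during sleep.
#' @param tst_h Sleep quota, hours.
#' @param step Coarse scan step passed to [match_mean_bd()].
#' @return A tibble of class `ea_sweep`: one row per grid point with the
#'   resolved rates, `mai_achieved`, cycle summaries, and `es_rho`,
#'   `es_mai`, `es_total` (percent). Rows where no periodic solution
#'   exists are present with `exists = FALSE`.
#' @examples
#' \donttest{
#' sweep_mai(ea_params(), mai_grid = c(0, 0.4, 1))
#' }
#' @export
sweep_mai <- function(params = ea_params(), mai_grid = seq(0, 1, by = 0.05),
                      rho = 0.3, tst_h = 8, step = 0.02) {
  stopifnot(is_ea_params(params))
  pars <- ea_update(params, TST_h = tst_h)
  wake <- strategy_wake(pars)
  mr <- match_mean_bd(pars, rho, 0, baseline = wake$m_bd, step = step,
                      label = "MRReduction")
  rows <- purrr::map(mai_grid, function(m) {
    strategy_row(pars, rho, m, baseline = wake$m_bd, step = step)
  })
  tbl <- dplyr::bind_cols(
    tibble(mai_target = mai_grid, rho = rho, tst_h = tst_h),
    dplyr::bind_rows(rows)
  )
  tbl <- add_savings(tbl, wake$m_mr, mr$m_mr)
  new_sweep(tbl, "mai_target", pars, wake$m_bd)
}

#' Sweep the sleep quota
#'
#' Varies total sleep time at fixed target MAI and `rho`. The savings
#' split exhibits the crossover the model predicts: partitioning (MAI)
#' dominates for short quotas, metabolic rate reduction for long ones.
#' `es_rho` is recomputed per quota (it depends on TST).
#'
#' @inheritParams sweep_mai
#' @param tst_grid Sleep-quota grid, hours.
#' @param mai_target Target MAI held constant.
#' @return An `ea_sweep` tibble (see [sweep_mai()]).
#' @examples
#' \donttest{
#' sweep_tst(ea_params(), tst_grid = c(4, 16))
#' }
#' @export
sweep_tst <- function(params = ea_params(), tst_grid = seq(1, 23, by = 1),
                      mai_target = 0.4, rho = 0.3, step = 0.02) {
  stopifnot(is_ea_params(params))
  wake <- strategy_wake(params)
  rows <- purrr::map(tst_grid, function(tst) {
    pars <- ea_update(params, TST_h = tst)
    mr <- tryCatch(
      match_mean_bd(pars, rho, 0, baseline = wake$m_bd, step = step,
                    label = "MRReduction"),
      easleep_no_cycle = function(e) NULL
    )
    row <- strategy_row(pars, rho, mai_target, baseline = wake$m_bd, step = step)
    m_mr2 <- if (is.null(mr)) NA_real_ else mr$m_mr
    dplyr::mutate(
      row,
      es_rho = ifelse(.data$exists & !is.na(m_mr2),
                      100 * (wake$m_mr - m_mr2) / wake$m_mr, NA_real_),
      es_total = ifelse(.data$exists, 100 * (wake$m_mr - .data$m_mr) / wake$m_mr,
                        NA_real_),
      es_mai = .data$es_total - .data$es_rho
    )
  })
  tbl <- dplyr::bind_cols(
    tibble(tst_h = tst_grid, mai_target = mai_target, rho = rho),
    dplyr::bind_rows(rows)
  )
  new_sweep(tbl, "tst_h", params, wake$m_bd)
}

#' Sweep the metabolic rate reduction
#'
#' Varies `rho` at fixed target MAI and sleep quota. Reducing metabolic
#' rate during the rest phase constrains the achievable MAI (the clamp
#' binds earlier), so `mai_achieved` falls at high `rho` and the MAI
#' contribution to savings shrinks.
#'
#' @inheritParams sweep_mai
#' @param rho_grid Grid of metabolic rate reductions in `[0, 1)`.
#' @param mai_target Target MAI held constant.
#' @return An `ea_sweep` tibble (see [sweep_mai()]).
#' @examples
#' \donttest{
#' sweep_rho(ea_params(), rho_grid = c(0, 0.3))
#' }
#' @export
sweep_rho <- function(params = ea_params(), rho_grid = seq(0, 0.95, by = 0.05),
                      mai_target = 0.7, tst_h = 8, step = 0.02) {
  stopifnot(is_ea_params(params))
  pars <- ea_update(params, TST_h = tst_h)
  wake <- strategy_wake(pars)
  rows <- purrr::map(rho_grid, function(r) {
    mr <- tryCatch(
      match_mean_bd(pars, r, 0, baseline = wake$m_bd, step = step,
                    label = "MRReduction"),
      easleep_no_cycle = function(e) NULL
    )
    row <- strategy_row(pars, r, mai_target, baseline = wake$m_bd, step = step)
    m_mr2 <- if (is.null(mr)) NA_real_ else mr$m_mr
    dplyr::mutate(
      row,
      es_rho = ifelse(.data$exists & !is.na(m_mr2),
                      100 * (wake$m_mr - m_mr2) / wake$m_mr, NA_real_),
      es_total = ifelse(.data$exists, 100 * (wake$m_mr - .data$m_mr) / wake$m_mr,
                        NA_real_),
      es_mai = .data$es_total - .data$es_rho
    )
  })
  tbl <- dplyr::bind_cols(
    tibble(rho = rho_grid, mai_target = mai_target, tst_h = tst_h),
    dplyr::bind_rows(rows)
  )
  new_sweep(tbl, "rho", pars, wake$m_bd)
}

#' Sweep target MAI against circadian amplitude
#'
#' Two-dimensional grid over target MAI and circadian amplitude `A` at
#' fixed `rho` and sleep quota. The Strategy Wake baseline is recomputed
#' for each amplitude (it depends on `A`). The model predicts amplitude
#' helps savings when partitioning is at least moderate (MAI >= 0.4) and
#' hurts when there is none (MAI = 0).
#'
#' @inheritParams sweep_mai
#' @param a_grid Circadian amplitude grid; every value must satisfy
#'   `A < m_C`.
#' @return An `ea_sweep` tibble with grid columns `A` and `mai_target`.
#' @examples
#' \donttest{
#' sweep_circadian(ea_params(), mai_grid = c(0, 0.7), a_grid = c(0, 2.5))
#' }
#' @export
sweep_circadian <- function(params = ea_params(),
                            mai_grid = seq(0, 1, by = 0.05),
                            a_grid = seq(0, 4.5, by = 0.25),
                            rho = 0.3, tst_h = 8, step = 0.02) {
  stopifnot(is_ea_params(params))
  if (any(a_grid >= params$m_C)) {
    abort("All amplitudes in `a_grid` must be smaller than `m_C`.")
  }
  out <- purrr::map(a_grid, function(a) {
    pars <- ea_update(params, TST_h = tst_h, A = a)
    wake <- strategy_wake(pars)
    mr <- match_mean_bd(pars, rho, 0, baseline = wake$m_bd, step = step,
                        label = "MRReduction")
    rows <- purrr::map(mai_grid, function(m) {
      strategy_row(pars, rho, m, baseline = wake$m_bd, step = step)
    })
    tbl <- dplyr::bind_cols(
      tibble(A = a, mai_target = mai_grid, rho = rho, tst_h = tst_h),
      dplyr::bind_rows(rows)
    )
    add_savings(tbl, wake$m_mr, mr$m_mr)
  })
  new_sweep(dplyr::bind_rows(out), c("A", "mai_target"), params, NA_real_)
}

#' Sensitivity grid over the price and circadian-level constants
#'
#' Varies `p_W` and `p_B1` (and optionally the circadian mean `m_C`, with
#' the amplitude tied to it as `A = 0.5 * m_C`) at fixed sleep quota,
#' `rho`, and target MAI, recording total energy savings wherever a stable
#' limit cycle exists. Points without one are kept, flagged
#' `exists = FALSE`.
#'
#' @inheritParams sweep_mai
#' @param pw_grid,pb1_grid Grids for the two price constants.
#' @param mc_values Circadian mean levels; for each, `A = 0.5 * m_C`.
#' @param mai_target Target MAI held constant.
#' @return An `ea_sweep` tibble with grid columns `p_W`, `p_B1`, `m_C`.
#'   Use [sensitivity_ranges()] for the per-`m_C` and overall spread of
#'   `es_total`.
#' @examples
#' \donttest{
#' sensitivity_grid(ea_params(), pw_grid = c(1, 1.3), pb1_grid = 0.7,
#'                  mc_values = 5)
#' }
#' @export
sensitivity_grid <- function(params = ea_params(),
                             pw_grid = seq(0, 2, by = 0.1),
                             pb1_grid = seq(0, 2, by = 0.1),
                             mc_values = c(2, 3.5, 5, 6.5),
                             rho = 0.3, mai_target = 0.4, tst_h = 8,
                             step = 0.02) {
  stopifnot(is_ea_params(params))
  grid <- tidyr::expand_grid(m_C = mc_values, p_W = pw_grid, p_B1 = pb1_grid)
  rows <- purrr::pmap(grid, function(m_C, p_W, p_B1) {
    pars <- ea_update(params, p_W = p_W, p_B1 = p_B1, m_C = m_C,
                      A = 0.5 * m_C, TST_h = tst_h)
    res <- tryCatch({
      wake <- strategy_wake(pars)
      row <- strategy_row(pars, rho, mai_target, baseline = wake$m_bd,
                          step = step)
      dplyr::mutate(row, es_total = ifelse(
        .data$exists, 100 * (wake$m_mr - .data$m_mr) / wake$m_mr, NA_real_
      ))
    }, easleep_no_cycle = function(e) NULL)
    if (is.null(res)) {
      res <- tibble(
        exists = FALSE, r_Ww = pars$r_Ww, r_Bw = NA_real_, r_Ws = NA_real_,
        r_Bs = NA_real_, mai_achieved = NA_real_, bd0 = NA_real_,
        m_bd = NA_real_, m_mr = NA_real_, matched = NA, es_total = NA_real_
      )
    }
    res
  })
  tbl <- dplyr::bind_cols(grid, dplyr::bind_rows(rows))
  tbl$rho <- rho
  tbl$mai_target <- mai_target
  tbl$tst_h <- tst_h
  new_sweep(tbl, c("p_W", "p_B1", "m_C"), params, NA_real_)
}

#' Spread of energy savings across a sensitivity grid
#'
#' @param tbl The output of [sensitivity_grid()].
#' @return A list with `per_mc` (tibble: `m_C`, `n`, `es_min`, `es_max`,
#'   `es_range` over points with a limit cycle) and `overall_range` (max
#'   minus min `es_total` across the whole grid, percentage points).
#' @export
sensitivity_ranges <- function(tbl) {
  ok <- tbl[tbl$exists %in% TRUE & is.finite(tbl$es_total), ]
  per_mc <- ok |>
    dplyr::group_by(.data$m_C) |>
    dplyr::summarise(
      n = dplyr::n(),
      es_min = min(.data$es_total),
      es_max = max(.data$es_total),
      es_range = max(.data$es_total) - min(.data$es_total),
      .groups = "drop"
    )
  list(per_mc = per_mc,
       overall_range = max(ok$es_total) - min(ok$es_total))
}

#' Multi-day run under fixed rates
#'
#' Chains [integrate_day()] and the daily reset over `n_days` days with
#' the rates held fixed (no per-day re-matching), recording end-of-day
#' debt and the daily mean debt. Diagnoses whether the run has settled
#' into a daily steady state (successive daily means changing by less
#' than `steady_tol`, relative) or is escalating (daily mean debt rising
#' by a growing increment over the final three days — the regime where
#' investment cannot service requirements and homeostasis is escaped).
#'
#' @param params An [ea_params()] object with the rates and quota to hold.
#' @param n_days Number of days (>= 2).
#' @param bd_init Start-of-run biological debt (> 0).
#' @param steady_tol Relative tolerance on successive daily means.
#' @param n_per_day Output points per day for the stored debt series.
#' @return A tibble of class `ea_multiday`, one row per day: `day`,
#'   `bd_start`, `bd_end`, `mean_bd`. Attributes: `series` (tibble `t`,
#'   `BD` over the whole run, `t` in days from the start), `steady_state`,
#'   `escalation`, `params`. `glance()` returns the flags.
#' @examples
#' \donttest{
#' run <- multiday_run(ea_params(r_Bw = 0.314, r_Ws = 0.126, r_Bs = 0.434),
#'                     n_days = 12, bd_init = 0.35)
#' glance(run)
#' }
#' @export
multiday_run <- function(params, n_days = 12, bd_init, steady_tol = 1e-4,
                         n_per_day = 201) {
  stopifnot(is_ea_params(params), n_days >= 2, bd_init > 0)
  bd <- bd_init
  days <- vector("list", n_days)
  series <- vector("list", n_days)
  for (d in seq_len(n_days)) {
    dd <- day_dense_bd(params, bd, n = n_per_day)
    m <- trapz(dd$t, dd$BD)
    days[[d]] <- tibble(day = d, bd_start = bd,
                        bd_end = dd$BD[length(dd$BD)], mean_bd = m)
    series[[d]] <- tibble(t = dd$t + (d - 1), BD = dd$BD)
    bd <- dd$BD[length(dd$BD)]
  }
  tbl <- dplyr::bind_rows(days)
  m <- tbl$mean_bd
  rel_last <- abs(m[n_days] - m[n_days - 1]) / m[n_days]
  steady <- rel_last < steady_tol
  escal <- FALSE
  if (n_days >= 3) {
    d1 <- m[n_days - 1] - m[n_days - 2]
    d2 <- m[n_days] - m[n_days - 1]
    escal <- d2 > d1 && d1 > 0 && rel_last >= steady_tol
  }
  structure(tbl, class = c("ea_multiday", class(tbl)),
            series = dplyr::bind_rows(series),
            steady_state = steady, escalation = escal, params = params)
}

#' @rdname tidiers
#' @export
glance.ea_multiday <- function(x, ...) {
  tibble(
    n_days = nrow(x),
    final_mean_bd = x$mean_bd[nrow(x)],
    steady_state = attr(x, "steady_state"),
    escalation = attr(x, "escalation")
  )
}

#' Shape metrics of a daily debt trajectory
#'
#' Summaries sufficient to characterize the temporal pattern of biological
#' debt over a steady-state day: its range, the number of local maxima and
#' minima per period (counted on the periodic closure, with a noise
#' tolerance), the fraction of each phase spent rising/falling, and the
#' sign of the mean curvature per phase. With no circadian amplitude and
#' no partitioning the steady-state debt is a flat line; with amplitude
#' but no partitioning it is a one-max/one-min sinusoid-like wave; with
#' partitioning it rises through wake and falls through sleep like the
#' homeostatic Process S.
#'
#' @param trajectory An `ea_trajectory` from [integrate_day()] (or any
#'   data frame with `t` and `BD`), ideally a limit-cycle day.
#' @param params The parameter set (for the phase switch time); defaults
#'   to the trajectory's `params` attribute.
#' @return A one-row tibble: `bd_range`, `n_max`, `n_min`,
#'   `frac_rising_wake`, `frac_falling_sleep`, `curvature_wake`,
#'   `curvature_sleep` (signs: -1 concave, 0 flat, 1 convex).
#' @examples
#' \donttest{
#' p <- ea_params(A = 0)
#' tr <- integrate_day(ea_update(p, TST_h = 0), 0.336)
#' bd_shape_metrics(tr)
#' }
#' @export
bd_shape_metrics <- function(trajectory, params = attr(trajectory, "params")) {
  stopifnot(all(c("t", "BD") %in% names(trajectory)))
  if (is.null(params)) abort("`params` is needed for the phase schedule.")
  t <- trajectory$t
  bd <- trajectory$BD
  ts <- switch_time(params)
  rng <- max(bd) - min(bd)
  eps <- max(1e-9, 1e-6 * max(abs(bd)))

  d <- diff(bd)
  s <- sign(d)
  s[abs(d) < eps] <- 0
  s2 <- s[s != 0]
  if (length(s2) == 0) {
    n_max <- 0L; n_min <- 0L
  } else {
    sc <- c(s2, s2[1]) # periodic closure
    n_max <- sum(head(sc, -1) == 1 & tail(sc, -1) == -1)
    n_min <- sum(head(sc, -1) == -1 & tail(sc, -1) == 1)
  }

  mid <- (head(t, -1) + tail(t, -1)) / 2
  wake_steps <- mid < ts
  sleep_steps <- mid >= ts
  frac_rising_wake <- if (any(wake_steps)) mean(d[wake_steps] > 0) else NA_real_
  frac_falling_sleep <- if (any(sleep_steps)) mean(d[sleep_steps] < 0) else NA_real_

  curv_sign <- function(idx) {
    if (sum(idx) < 3) return(NA_real_)
    dd <- diff(bd[idx], differences = 2)
    mdd <- mean(dd)
    if (abs(mdd) < eps^2) 0 else sign(mdd)
  }
  tibble(
    bd_range = rng, n_max = n_max, n_min = n_min,
    frac_rising_wake = frac_rising_wake,
    frac_falling_sleep = frac_falling_sleep,
    curvature_wake = curv_sign(t < ts),
    curvature_sleep = curv_sign(t >= ts)
  )
}
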