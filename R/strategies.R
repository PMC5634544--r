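# The three-strategy energy-savings protocol: derived indices (rho, MAI),
# explicit rate resolution, Strategy Wake baseline, and mean-debt matching.

#' Metabolic rate reduction rho implied by four energy rates
#'
#' `rho = 1 - (r_Ws + r_Bs) / (r_Ww + r_Bw)`: the proportional drop in
#' total metabolic rate from wake to sleep (0 = none, 1 = zero sleep
#' metabolism).
#'
#' @param r_Ww,r_Bw,r_Ws,r_Bs Phase-specific energy rates (>= 0).
#' @return A single number.
#' @examples
#' rho_of_rates(0.5, 0.3, 0.126, 0.434) # 0.3
#' @export
rho_of_rates <- function(r_Ww, r_Bw, r_Ws, r_Bs) {
  if (r_Ww + r_Bw <= 0) abort("Wake metabolic rate `r_Ww + r_Bw` must be positive.")
  1 - (r_Ws + r_Bs) / (r_Ww + r_Bw)
}

#' Metabolic allocation index implied by four energy rates
#'
#' `MAI = ((r_Ww - r_Bw)/(r_Ww + r_Bw) + (r_Bs - r_Ws)/(r_Ws + r_Bs)) / 2`:
#' the degree of state-dependent metabolic partitioning. 0 means identical
#' allocation ratios in both states; 1 means fully partitioned
#' (`r_Bw = r_Ws = 0`).
#'
#' @inheritParams rho_of_rates
#' @return A single number in `[-1, 1]`.
#' @examples
#' mai_of_rates(0.5, 0.3, 0.126, 0.434) # 0.4
#' @export
mai_of_rates <- function(r_Ww, r_Bw, r_Ws, r_Bs) {
  if (r_Ww + r_Bw <= 0 || r_Ws + r_Bs <= 0) {
    abort("Both phase totals `r_Ww + r_Bw` and `r_Ws + r_Bs` must be positive.")
  }
  0.5 * ((r_Ww - r_Bw) / (r_Ww + r_Bw) + (r_Bs - r_Ws) / (r_Ws + r_Bs))
}

#' Sleep-phase rates from rho and a target MAI
#'
#' Solves the rho and MAI definitions for the sleep rates given the wake
#' rates: `r_Ws = max(0, (1 - rho) * ((1 - MAI) * r_Ww - MAI * r_Bw))` and
#' `r_Bs = (1 - rho) * (r_Ww + r_Bw) - r_Ws`. The clamp keeps all rates
#' non-negative; when it binds, the achieved MAI falls short of the target
#' (evaluate with [mai_of_rates()]). The sleep total always satisfies
#' `r_Ws + r_Bs = (1 - rho) * (r_Ww + r_Bw)` exactly, so the requested rho
#' is met by construction.
#'
#' @param r_Bw Wake investment rate.
#' @param rho Metabolic rate reduction, in `[0, 1]`.
#' @param mai_target Target metabolic allocation index, in `[0, 1]`.
#' @param r_Ww Wake effort rate.
#' @return Named numeric vector `c(r_Ws = , r_Bs = )`.
#' @examples
#' sleep_rates(0.3, rho = 0.3, mai_target = 0.4, r_Ww = 0.5)
#' sleep_rates(0.48, 0.3, 0.6, 0.5) # clamp binds: r_Ws = 0
#' @export
sleep_rates <- function(r_Bw, rho, mai_target, r_Ww) {
  stopifnot(rho >= 0, rho <= 1, mai_target >= 0, mai_target <= 1,
            r_Bw >= 0, r_Ww >= 0)
  r_Ws <- max(0, (1 - rho) * ((1 - mai_target) * r_Ww - mai_target * r_Bw))
  r_Bs <- (1 - rho) * (r_Ww + r_Bw) - r_Ws
  c(r_Ws = r_Ws, r_Bs = r_Bs)
}

#' Daily mean metabolic rate
#'
#' `m_MR = (1 - TST/24) * (r_Ww + r_Bw) + (TST/24) * (r_Ws + r_Bs)`:
#' exact arithmetic on the resolved rates, no integration involved.
#'
#' @param x An [ea_params()] object (rates and sleep quota) or an
#'   `ea_strategy` from [strategy_wake()] / [match_mean_bd()].
#' @return A single number (energy/day).
#' @examples
#' mean_mr(ea_params(r_Bw = 0.3, r_Ws = 0.126, r_Bs = 0.434, TST_h = 8))
#' @export
mean_mr <- function(x) UseMethod("mean_mr")

#' @export
mean_mr.ea_params <- function(x) {
  f <- tst_frac(x)
  (1 - f) * (x$r_Ww + x$r_Bw) + f * (x$r_Ws + x$r_Bs)
}

#' @export
mean_mr.ea_strategy <- function(x) mean_mr(x$params)

#' Energy savings from the three-strategy comparison
#'
#' Given the mean metabolic rates of Strategy Wake (`m_mr1`), Strategy MR
#' Reduction (`m_mr2`), and Strategy MP + MR Reduction (`m_mr3`), computes
#' `ES_rho = (m_mr1 - m_mr2)/m_mr1`, `ES_total = (m_mr1 - m_mr3)/m_mr1`,
#' and `ES_MAI = ES_total - ES_rho`, reported in percent.
#'
#' @param m_mr1,m_mr2,m_mr3 Mean metabolic rates of the three strategies.
#' @return A one-row tibble with `es_rho`, `es_mai`, `es_total` (percent).
#' @examples
#' energy_savings(1, 0.925, 0.72)
#' @export
energy_savings <- function(m_mr1, m_mr2, m_mr3) {
  if (m_mr1 <= 0) abort("Baseline mean metabolic rate `m_mr1` must be positive.")
  es_rho <- 100 * (m_mr1 - m_mr2) / m_mr1
  es_total <- 100 * (m_mr1 - m_mr3) / m_mr1
  tibble(es_rho = es_rho, es_mai = es_total - es_rho, es_total = es_total)
}

new_strategy <- function(strategy, params, rho, mai_target, cycle,
                         matched, stability = "stable") {
  structure(
    list(
      strategy = strategy,
      params = params,
      rho_achieved = rho_of_rates(params$r_Ww, params$r_Bw, params$r_Ws, params$r_Bs),
      rho = rho,
      mai_target = mai_target,
      mai_achieved = if (params$TST_h > 0 || strategy == "Wake") {
        if (params$r_Ws + params$r_Bs > 0) {
          mai_of_rates(params$r_Ww, params$r_Bw, params$r_Ws, params$r_Bs)
        } else NA_real_
      } else NA_real_,
      bd0 = cycle$bd0,
      m_bd = cycle$m_bd,
      m_mr = mean_mr(params),
      matched = matched,
      stability = stability
    ),
    class = "ea_strategy"
  )
}

#' @export
print.ea_strategy <- function(x, ...) {
  cat(sprintf("<ea_strategy> %s\n", x$strategy))
  cat(sprintf("  rates: r_Ww = %.5g, r_Bw = %.5g, r_Ws = %.5g, r_Bs = %.5g (TST = %g h)\n",
              x$params$r_Ww, x$params$r_Bw, x$params$r_Ws, x$params$r_Bs,
              x$params$TST_h))
  cat(sprintf("  rho = %.3g, MAI target = %.3g, achieved = %.4g\n",
              x$rho_achieved, x$mai_target,
              ifelse(is.na(x$mai_achieved), NA, x$mai_achieved)))
  cat(sprintf("  cycle: BD0 = %.5g (%s), mean BD = %.5g, mean MR = %.5g, matched = %s\n",
              x$bd0, x$stability, x$m_bd, x$m_mr, x$matched))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ea_strategy <- function(x, ...) {
  tibble(
    strategy = x$strategy,
    r_Ww = x$params$r_Ww, r_Bw = x$params$r_Bw,
    r_Ws = x$params$r_Ws, r_Bs = x$params$r_Bs,
    tst_h = x$params$TST_h,
    rho_achieved = x$rho_achieved,
    mai_target = x$mai_target, mai_achieved = x$mai_achieved,
    bd0 = x$bd0, stability = x$stability,
    m_bd = x$m_bd, m_mr = x$m_mr, matched = x$matched
  )
}

#' @rdname tidiers
#' @export
glance.ea_strategy <- function(x, ...) {
  tibble(bd0 = x$bd0, stability = x$stability, m_bd = x$m_bd,
         m_mr = x$m_mr, matched = x$matched)
}

#' Strategy Wake: the continuous-wakefulness baseline
#'
#' The comparator condition: no sleep (`TST = 0`), no metabolic rate
#' reduction, no partitioning, with `r_Bw` set equal to `r_Ww`. Finds the
#' stable daily limit cycle and records the baseline mean debt `m_bd` and
#' mean metabolic rate `m_mr = r_Ww + r_Bw`.
#'
#' @param params An [ea_params()] object; only its prices, circadian
#'   constants, and `r_Ww` are used.
#' @return An `ea_strategy` object (see [tidy()] for the tabular form).
#' @examples
#' \donttest{
#' strategy_wake(ea_params()) # stable fixed point near BD = 0.336
#' }
#' @export
strategy_wake <- function(params) {
  stopifnot(is_ea_params(params))
  r <- params$r_Ww
  wp <- ea_update(params, TST_h = 0, r_Bw = r, r_Ws = r, r_Bs = r)
  cyc <- find_limit_cycles(wp)
  cyc <- cyc[cyc$stability %in% c("stable", "half-stable"), ]
  if (!nrow(cyc)) {
    abort("Strategy Wake has no stable limit cycle under these parameters.",
          class = "easleep_no_cycle")
  }
  new_strategy("Wake", wp, rho = 0, mai_target = 0,
               cycle = list(bd0 = cyc$bd0[1], m_bd = cyc$m_bd[1]),
               matched = TRUE, stability = cyc$stability[1])
}

#' Resolve a sleep strategy by matching the baseline mean debt
#'
#' Implements the matching protocol: hold `r_Ww` at its Strategy Wake
#' value, start from `r_Bw = 0` and increase it (coarse scan, then
#' bisection) until the stable limit cycle's time-averaged debt equals the
#' Strategy Wake baseline to a relative tolerance of 1e-4. Below the
#' saddle-node onset no cycle exists; if at onset the cycle's mean debt is
#' already below the baseline, the match is impossible and the strategy is
#' evaluated at the bifurcation point instead (`matched = FALSE`).
#'
#' @param params An [ea_params()] object; `r_Ww`, the prices, circadian
#'   constants, and `TST_h` define the scenario.
#' @param rho Metabolic rate reduction during sleep, in `[0, 1]`.
#' @param mai_target Target metabolic allocation index, in `[0, 1]`.
#' @param baseline Baseline mean debt to match. Default: computed from
#'   [strategy_wake()] on `params`.
#' @param step Coarse upward scan step in `r_Bw` (default 0.02).
#' @param r_bw_max Upper bound of the `r_Bw` search (default 10); an error
#'   of class `easleep_no_cycle` is raised if no periodic solution exists
#'   anywhere below it.
#' @param tol_rel Relative matching tolerance on the mean debt.
#' @param label Strategy label stored on the result.
#' @return An `ea_strategy` object.
#' @examples
#' \donttest{
#' base <- strategy_wake(ea_params())
#' match_mean_bd(ea_params(), rho = 0.3, mai_target = 0.4,
#'               baseline = base$m_bd)
#' }
#' @export
match_mean_bd <- function(params, rho, mai_target, baseline = NULL,
                          step = 0.02, r_bw_max = 10, tol_rel = 1e-4,
                          label = "MP+MRReduction") {
  stopifnot(is_ea_params(params))
  if (is.null(baseline)) baseline <- strategy_wake(params)$m_bd

  at <- function(r_bw) {
    s <- sleep_rates(r_bw, rho, mai_target, params$r_Ww)
    ea_update(params, r_Bw = r_bw, r_Ws = s[["r_Ws"]], r_Bs = s[["r_Bs"]])
  }
  guess <- NULL
  # mean debt of the stable cycle at r_Bw, NA when no cycle exists
  m_at <- function(r_bw) {
    sc <- stable_cycle(at(r_bw), guess = guess)
    if (is.null(sc)) return(NA_real_)
    guess <<- sc$bd0
    sc
  }

  # coarse upward scan until the stable cycle exists with m_bd <= baseline
  rb <- 0
  repeat {
    sc <- m_at(rb)
    if (is.list(sc) && sc$m_bd <= baseline) break
    rb <- rb + step
    if (rb > r_bw_max) {
      abort("No periodic solution with mean debt at or below the baseline was found below `r_bw_max`.",
            class = "easleep_no_cycle")
    }
  }

  if (rb == 0) {
    lo <- 0; hi <- 0
  } else {
    lo <- rb - step; hi <- rb
  }
  sc_hi <- sc
  # bisect on: cycle exists and its mean debt is at or below the baseline
  while (hi - lo > 1e-7) {
    if (abs(sc_hi$m_bd - baseline) / baseline <= tol_rel) break
    mid <- (lo + hi) / 2
    sc_mid <- m_at(mid)
    if (is.list(sc_mid) && sc_mid$m_bd <= baseline) {
      hi <- mid; sc_hi <- sc_mid
    } else {
      lo <- mid
    }
  }

  matched <- abs(sc_hi$m_bd - baseline) / baseline <= tol_rel
  pars <- at(hi)
  slope <- map_slope(pars, sc_hi$bd0)
  new_strategy(label, pars, rho = rho, mai_target = mai_target,
               cycle = sc_hi, matched = matched,
               stability = classify_slope(slope))
}

#' Run the full three-strategy comparison
#'
#' Convenience wrapper: Strategy Wake baseline, Strategy MR Reduction
#' (same `rho`, `MAI = 0`), and Strategy MP + MR Reduction (`rho` plus the
#' target MAI), all at the same sleep quota, with energy savings split
#' into the rho and MAI components.
#'
#' @inheritParams match_mean_bd
#' @return An object of class `ea_protocol`: list with `strategies` (the
#'   three `ea_strategy` objects), `table` (their [tidy()] rows), and
#'   `savings` (one-row tibble of `es_rho`, `es_mai`, `es_total` in
#'   percent). `tidy()` returns the table, `glance()` the savings.
#' @examples
#' \donttest{
#' pr <- ea_protocol(ea_params(), rho = 0.3, mai_target = 0.4)
#' glance(pr)
#' }
#' @export
ea_protocol <- function(params, rho, mai_target, step = 0.02) {
  wake <- strategy_wake(params)
  mr <- match_mean_bd(params, rho, 0, baseline = wake$m_bd, step = step,
                      label = "MRReduction")
  mp <- match_mean_bd(params, rho, mai_target, baseline = wake$m_bd,
                      step = step, label = "MP+MRReduction")
  sav <- energy_savings(wake$m_mr, mr$m_mr, mp$m_mr)
  structure(
    list(
      strategies = list(wake = wake, mr_reduction = mr, mp_mr_reduction = mp),
      table = dplyr::bind_rows(tidy(wake), tidy(mr), tidy(mp)),
      savings = sav
    ),
    class = "ea_protocol"
  )
}

#' @export
print.ea_protocol <- function(x, ...) {
  cat("<ea_protocol> three-strategy energy savings comparison\n")
  print(x$table[, c("strategy", "r_Bw", "r_Ws", "r_Bs", "mai_achieved",
                    "m_bd", "m_mr", "matched")])
  cat(sprintf("  ES_rho = %.1f%%, ES_MAI = %.1f%%, ES_total = %.1f%%\n",
              x$savings$es_rho, x$savings$es_mai, x$savings$es_total))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.ea_protocol <- function(x, ...) x$table

#' @rdname tidiers
#' @export
glance.ea_protocol <- function(x, ...) x$savings

#' Tidiers for easleep result objects
#'
#' [tidy()] returns the tabular form of a result (one row per strategy or
#' component); [glance()] returns a one-row summary.
#'
#' @param x An `ea_strategy` or `ea_protocol` object.
#' @param ... Unused.
#' @name tidiers
NULL
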