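# Limit-cycle machinery: fixed points of the daily Poincare map, their
# stability, cycle averages, and the saddle-node bifurcation in r_Bw.

FP_TOL <- 1e-8        # fixed-point refinement tolerance on BD
SLOPE_STEP <- 1e-5    # centered-difference step for the map slope
HALF_STABLE_BAND <- 1e-3

# P(b) - b, returning NA where the trajectory is invalid
gap_fun <- function(params) {
  function(b) {
    tryCatch(day_end_bd(params, b) - b,
      easleep_invalid_trajectory = function(e) NA_real_
    )
  }
}

search_grid <- function(interval, n_grid) {
  lo <- max(interval[1], 1e-9)
  g <- exp(seq(log(max(lo, 1e-3)), log(interval[2]), length.out = n_grid))
  sort(unique(c(lo, g)))
}

map_slope <- function(params, bd0) {
  h <- SLOPE_STEP
  (day_end_bd(params, bd0 + h) - day_end_bd(params, max(bd0 - h, h))) /
    (bd0 + h - max(bd0 - h, h))
}

classify_slope <- function(slope) {
  if (abs(slope - 1) < HALF_STABLE_BAND) "half-stable"
  else if (slope < 1) "stable"
  else "unstable"
}

# all fixed points in `interval`: grid sign changes plus a tangency probe
# at interior local minima of the gap (a narrow dip below the diagonal near
# a saddle-node can fall between grid points)
find_roots <- function(params, interval, n_grid = 25) {
  gap <- gap_fun(params)
  g <- search_grid(interval, n_grid)
  v <- vapply(g, gap, numeric(1))
  ok <- which(is.finite(v))
  roots <- numeric(0)
  if (length(ok) >= 2) {
    for (k in seq_len(length(ok) - 1)) {
      i <- ok[k]; j <- ok[k + 1]
      if (sign(v[i]) != sign(v[j]) && v[i] != 0) {
        r <- uniroot(gap, c(g[i], g[j]), f.lower = v[i], f.upper = v[j],
                     tol = FP_TOL / 10)
        roots <- c(roots, r$root)
      } else if (v[i] == 0) {
        roots <- c(roots, g[i])
      }
    }
  }
  # tangency probe: local minima of the sampled gap that stay positive
  if (length(ok) >= 3) {
    vv <- v[ok]
    for (k in 2:(length(ok) - 1)) {
      if (vv[k] > 0 && vv[k] <= vv[k - 1] && vv[k] <= vv[k + 1]) {
        lo <- g[ok[k - 1]]; hi <- g[ok[k + 1]]
        op <- optimize(gap, c(lo, hi), tol = 1e-9)
        if (is.finite(op$objective) && op$objective < 0) {
          glo <- gap(lo); ghi <- gap(hi)
          if (is.finite(glo) && glo > 0) {
            roots <- c(roots, uniroot(gap, c(lo, op$minimum), tol = FP_TOL / 10)$root)
          }
          if (is.finite(ghi) && ghi > 0) {
            roots <- c(roots, uniroot(gap, c(op$minimum, hi), tol = FP_TOL / 10)$root)
          }
        } else if (is.finite(op$objective) && abs(op$objective) <= FP_TOL) {
          roots <- c(roots, op$minimum)  # tangent (half-stable) point
        }
      }
    }
  }
  roots <- sort(roots)
  if (length(roots) > 1) {
    keep <- c(TRUE, diff(roots) > 1e-6)
    roots <- roots[keep]
  }
  roots
}

#' Find the limit cycles of the daily map
#'
#' Locates all fixed points of the Poincare map in the search interval by
#' bracketed root-finding on `P(BD) - BD` (with a tangency probe for
#' near-saddle-node dips that fall between grid points), classifies each by
#' the finite-difference slope of the map, and computes the time-averaged
#' debt of each cycle. Zero, one, or two fixed points are the regimes the
#' model exhibits; an empty result is a valid outcome (no periodic
#' solution). When two exist, the smaller-debt one is the stable cycle.
#'
#' @param params An [ea_params()] object.
#' @param interval Search interval for the start-of-day debt, default
#'   `c(1e-6, 50)`.
#' @param n_grid Number of (log-spaced) grid points used for bracketing.
#' @param trajectories If `TRUE`, attach a `trajectory` list-column of
#'   [integrate_day()] tibbles.
#' @return A tibble of class `ea_cycles`, one row per cycle: `bd0`,
#'   `slope`, `stability` (stable/unstable/half-stable), `m_bd`.
#' @examples
#' find_limit_cycles(ea_params(TST_h = 0)) # Strategy Wake: stable + unstable
#' @export
find_limit_cycles <- function(params, interval = c(1e-6, 50), n_grid = 25,
                              trajectories = FALSE) {
  stopifnot(is_ea_params(params))
  roots <- find_roots(params, interval, n_grid)
  if (!length(roots)) {
    out <- tibble(bd0 = numeric(0), slope = numeric(0),
                  stability = character(0), m_bd = numeric(0))
  } else {
    slope <- vapply(roots, function(b) map_slope(params, b), numeric(1))
    m_bd <- vapply(roots, function(b) {
      d <- day_dense_bd(params, b)
      trapz(d$t, d$BD)
    }, numeric(1))
    out <- tibble(
      bd0 = roots, slope = slope,
      stability = vapply(slope, classify_slope, character(1)),
      m_bd = m_bd
    )
  }
  if (trajectories && nrow(out)) {
    out$trajectory <- lapply(out$bd0, function(b) integrate_day(params, b))
  }
  structure(out, class = c("ea_cycles", class(out)), params = params)
}

# stable (or half-stable) cycle only, with an optional warm start from a
# previous solution; returns list(bd0, m_bd) or NULL when no cycle exists
stable_cycle <- function(params, guess = NULL, interval = c(1e-6, 50)) {
  gap <- gap_fun(params)
  bd0 <- NULL
  if (!is.null(guess) && is.finite(guess)) {
    lo <- guess * 0.5; hi <- guess * 1.6
    glo <- gap(lo); ghi <- gap(hi)
    if (is.finite(glo) && is.finite(ghi) && glo > 0 && ghi < 0) {
      bd0 <- uniroot(gap, c(lo, hi), f.lower = glo, f.upper = ghi,
                     tol = FP_TOL / 10)$root
    }
  }
  if (is.null(bd0)) {
    cyc <- find_limit_cycles(params, interval)
    cyc <- cyc[cyc$stability %in% c("stable", "half-stable"), ]
    if (!nrow(cyc)) return(NULL)
    return(list(bd0 = cyc$bd0[1], m_bd = cyc$m_bd[1]))
  }
  d <- day_dense_bd(params, bd0)
  list(bd0 = bd0, m_bd = trapz(d$t, d$BD))
}

# does any fixed point exist? robust to tangency (minimum of the gap)
cycle_exists <- function(params, interval = c(1e-6, 50), n_grid = 17) {
  gap <- gap_fun(params)
  g <- search_grid(interval, n_grid)
  v <- vapply(g, gap, numeric(1))
  ok <- is.finite(v)
  if (any(v[ok] <= 0)) return(TRUE)
  gg <- g[ok]; vv <- v[ok]
  if (length(vv) >= 3) {
    for (k in 2:(length(vv) - 1)) {
      if (vv[k] <= vv[k - 1] && vv[k] <= vv[k + 1]) {
        op <- optimize(gap, c(gg[k - 1], gg[k + 1]), tol = 1e-9)
        if (is.finite(op$objective) && op$objective <= 0) return(TRUE)
      }
    }
  }
  FALSE
}

#' Locate the saddle-node bifurcation in the wake investment rate
#'
#' For a strategy family parameterized by the wake investment rate `r_Bw`
#' (with `r_Ws`, `r_Bs` resolved from `rho` and the target MAI via
#' [sleep_rates()]), limit cycles are absent at low `r_Bw` and appear at a
#' saddle-node bifurcation as `r_Bw` grows. This bisects `r_Bw` on cycle
#' existence (detected through the minimum of `P(BD) - BD`, so tangent
#' cycles are caught) to locate the onset.
#'
#' @param params An [ea_params()] object supplying everything but the
#'   resolved rates; `r_Ww` is taken from it and held fixed.
#' @param rho Proportional metabolic rate reduction during sleep, in
#'   `[0, 1]`.
#' @param mai_target Target metabolic allocation index, in `[0, 1]`.
#' @param r_bw_range Search range for `r_Bw`.
#' @param tol Bisection tolerance on `r_Bw`, default 1e-5.
#' @return A list with `r_Bw` (the onset rate), `params` (the resolved
#'   parameter set at onset), and `cycles` (the [find_limit_cycles()] table
#'   there; the cycle is tangent or newly split).
#' @examples
#' \donttest{
#' find_bifurcation(ea_params(), rho = 0.3, mai_target = 0.4)
#' }
#' @export
find_bifurcation <- function(params, rho, mai_target,
                             r_bw_range = c(0, 2), tol = 1e-5) {
  stopifnot(is_ea_params(params))
  at <- function(r_bw) {
    s <- sleep_rates(r_bw, rho, mai_target, params$r_Ww)
    ea_update(params, r_Bw = r_bw, r_Ws = s[["r_Ws"]], r_Bs = s[["r_Bs"]])
  }
  lo <- r_bw_range[1]; hi <- r_bw_range[2]
  if (cycle_exists(at(lo))) {
    abort("A limit cycle already exists at the lower end of `r_bw_range`.")
  }
  if (!cycle_exists(at(hi))) {
    abort("No limit cycle exists anywhere in `r_bw_range`; no bifurcation to bracket.")
  }
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (cycle_exists(at(mid))) hi <- mid else lo <- mid
  }
  pars <- at(hi)
  list(r_Bw = hi, params = pars, cycles = find_limit_cycles(pars))
}
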