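# Model symbols: circadian multiplier, prices, conversion efficiency,
# phase schedule, right-hand side, daily reset.

test_that("parameter validation enforces the model's constraints", {
  expect_s3_class(ea_params(), "ea_params")
  expect_error(ea_params(A = 6, m_C = 5), "smaller than `m_C`")
  expect_error(ea_params(A = 5, m_C = 5), "smaller than `m_C`")
  expect_error(ea_params(TST_h = 24), "TST_h")
  expect_error(ea_params(r_Bw = -0.1), "non-negative")
  expect_error(ea_params(m_C = 0), "positive")
  # r_Ws = 0 is a legal rate (fully partitioned sleep)
  expect_silent(ea_params(r_Ws = 0))
})

test_that("circadian multiplier has the stated closed form, peak, and range", {
  p <- ea_params(m_C = 5, A = 2.5, TST_h = 8)
  # amplitude zero: constant at the mean level
  p0 <- ea_params(A = 0)
  expect_equal(circadian_efficiency(seq(0, 1, 0.1), p0), rep(5, 11))
  # analytic peak m_C + A in the middle of the sleep phase
  expect_equal(circadian_efficiency(1 - 8 / 48, p), 7.5)
  # closed-form value at the start of the day
  expect_equal(circadian_efficiency(0, p),
               5 - 2.5 * sin(2 * pi * (-0.25 + (8 / 24) / 2)), tolerance = 1e-12)
  expect_equal(circadian_efficiency(0, p), 6.25)
  # bounded by m_C +/- A
  tt <- seq(0, 1, length.out = 501)
  expect_true(all(circadian_efficiency(tt, p) <= 7.5 + 1e-12))
  expect_true(all(circadian_efficiency(tt, p) >= 2.5 - 1e-12))
})

test_that("circadian multiplier has period one day and mean m_C", {
  set.seed(11)
  for (i in 1:5) {
    p <- random_params()
    tt <- seq(0, 1, length.out = 33)
    expect_equal(circadian_efficiency(tt, p), circadian_efficiency(tt + 1, p),
                 tolerance = 1e-12)
    m <- stats::integrate(function(t) circadian_efficiency(t, p), 0, 1,
                          rel.tol = 1e-10)$value
    expect_equal(m, p$m_C, tolerance = 1e-8)
  }
})

test_that("investment price is linear in debt with zero intercept", {
  p <- ea_params(p_B1 = 0.7)
  expect_equal(investment_price(1, p), 0.7)
  expect_equal(investment_price(0.336, p), 0.2352)
  expect_equal(investment_price(2, ea_params(p_B1 = 0)), 0)
  expect_error(investment_price(0, p), "positive")
  expect_error(investment_price(-1, p), "positive")
})

test_that("conversion efficiency is unimodal in debt with maximum C/2 at BD = 1", {
  p0 <- ea_params(A = 0, m_C = 5)
  expect_equal(conversion_efficiency(0.3, 1, p0), 2.5)
  expect_equal(conversion_efficiency(0.3, 0, p0), 0) # limit at zero debt
  # closed form at the circadian peak
  p <- ea_params(m_C = 5, A = 2.5, TST_h = 8)
  expect_equal(conversion_efficiency(5 / 6, 2, p), 7.5 * 2 / 5)
  # unimodal with argmax 1 on a grid, for any time of day
  bd <- seq(0.05, 6, by = 0.05)
  for (t in c(0, 0.4, 0.9)) {
    v <- conversion_efficiency(t, bd, p)
    expect_equal(bd[which.max(v)], 1)
    expect_true(all(diff(v[bd < 1]) > 0))
    expect_true(all(diff(v[bd > 1]) < 0))
  }
})

test_that("phase rates honor the wake-first schedule and boundary ownership", {
  p <- ea_params(TST_h = 8, r_Ww = 0.5, r_Bw = 0.3, r_Ws = 0.126, r_Bs = 0.434)
  r <- phase_rates(c(0.5, 1 - 8 / 24, 0.9), p)
  expect_equal(r$phase, c("wake", "sleep", "sleep")) # switch belongs to sleep
  expect_equal(r$r_W, c(0.5, 0.126, 0.126))
  expect_equal(r$r_B, c(0.3, 0.434, 0.434))
  # no sleep phase at all when TST = 0
  p0 <- ea_params(TST_h = 0)
  r0 <- phase_rates(c(0, 0.5, 1), p0)
  expect_true(all(r0$phase == "wake"))
  expect_equal(nrow(phase_schedule(p0)), 1L)
  # near-all-sleep quota
  p23 <- ea_params(TST_h = 23.9)
  expect_equal(phase_rates(0.5, p23)$phase, "sleep")
})

test_that("right-hand side matches the closed-form debt equation", {
  # no energy deployment: nothing moves
  p_zero <- ea_params(r_Ww = 0, r_Bw = 0, r_Ws = 0, r_Bs = 0)
  d <- ea_rhs(0.3, c(BR = 1, BI = 0.5), p_zero)
  expect_equal(d$dBR, 0)
  expect_equal(d$dBI, 0)
  # hand arithmetic at the wake steady-state debt (A = 0 so C = 5)
  p <- ea_params(A = 0, m_C = 5, p_W = 1.3, p_B1 = 0.7, TST_h = 0,
                 r_Ww = 0.5, r_Bw = 0.5)
  bd <- 0.336
  d <- ea_rhs(0.1, c(BR = bd, BI = 0), p)
  expect_equal(d$dBD,
               1.3 * 0.5 + 0.5 * (0.7 * bd - 5 * bd / (1 + bd^2)),
               tolerance = 1e-12)
  expect_equal(d$dBD, d$dBR - d$dBI)
  # algebraic zero: C chosen to balance the debt equation exactly
  bd <- 0.8; r_W <- 0.4; r_B <- 0.6; p_W <- 1.1; p_B1 <- 0.5
  C_star <- p_W * r_W / (r_B * bd / (1 + bd^2)) + p_B1 * (1 + bd^2)
  p_bal <- ea_params(p_W = p_W, p_B1 = p_B1, m_C = C_star, A = 0, TST_h = 0,
                     r_Ww = r_W, r_Bw = r_B)
  expect_equal(ea_rhs(0.2, c(BR = bd, BI = 0), p_bal)$dBD, 0,
               tolerance = 1e-12)
  # invalid state signals
  expect_error(ea_rhs(0.1, c(BR = 1, BI = 1), p), "positive")
})

test_that("daily reset preserves debt and is idempotent", {
  s <- daily_reset(c(BR = 5, BI = 4.664))
  expect_equal(unname(s["BR"]), 0.336)
  expect_equal(unname(s["BI"]), 0)
  expect_equal(unname(s["BD"]), 0.336)
  expect_equal(daily_reset(s)[c("BR", "BI", "BD")], s[c("BR", "BI", "BD")])
  set.seed(21)
  for (i in 1:10) {
    br <- runif(1, 0.5, 10); bi <- runif(1, 0, br - 0.01)
    s <- daily_reset(c(BR = br, BI = bi))
    expect_equal(unname(s["BR"] - s["BI"]), br - bi)
  }
})

test_that("scalar debt reduction agrees with the full (BR, BI) system", {
  set.seed(31)
  for (i in 1:6) {
    p <- random_params()
    bd0 <- runif(1, 0.1, 2)
    pair_end <- attr(integrate_day(p, bd0), "bd_end")
    scalar_end <- poincare_map(p, bd0)
    expect_equal(pair_end, scalar_end, tolerance = 1e-6)
  }
})

test_that("trajectory invariants hold: BD = BR - BI pointwise, BD(0) = bd0", {
  p <- std_params()
  tr <- integrate_day(p, 0.4)
  expect_equal(tr$BD, tr$BR - tr$BI, tolerance = 1e-12)
  expect_equal(tr$BD[1], 0.4)
  expect_equal(tr$t[1], 0)
  expect_equal(tr$t[nrow(tr)], 1)
  # zero dynamics: debt constant
  p0 <- ea_params(r_Ww = 0, r_Bw = 0, r_Ws = 0, r_Bs = 0)
  tr0 <- integrate_day(p0, 0.7)
  expect_true(max(abs(tr0$BD - 0.7)) < 1e-9)
})
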