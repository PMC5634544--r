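# Sweeps, sensitivity grid, multi-day runs, and debt-shape diagnostics.
# Grids here are kept deliberately small; the full study-condition grids
# are exercised by the acceptance suite.

test_that("MAI sweep: zero target reduces to pure MR reduction, clamp caps the rest", {
  sw <- sweep_mai(ea_params(), mai_grid = c(0, 0.4, 1), rho = 0.3, tst_h = 8)
  expect_s3_class(sw, "ea_sweep")
  expect_equal(nrow(sw), 3L)
  expect_true(all(sw$exists))
  # target 0 is Strategy MR Reduction itself: no MAI contribution
  expect_equal(sw$es_mai[1], 0, tolerance = 1e-9)
  # target 0.4 achieved exactly; target 1 clamped below 1
  expect_equal(sw$mai_achieved[2], 0.4, tolerance = 1e-9)
  expect_lt(sw$mai_achieved[3], 1)
  expect_gt(sw$mai_achieved[3], sw$mai_achieved[2])
  # savings grow with achieved partitioning
  expect_true(all(diff(sw$es_total) > 0))
  # every row's savings re-derive from its stored rates (exact arithmetic)
  m_mr1 <- 2 * sw$r_Ww[1]
  re_mr <- (1 - sw$tst_h / 24) * (sw$r_Ww + sw$r_Bw) +
    (sw$tst_h / 24) * (sw$r_Ws + sw$r_Bs)
  expect_equal(re_mr, sw$m_mr, tolerance = 1e-12)
  expect_equal(100 * (m_mr1 - re_mr) / m_mr1, sw$es_total, tolerance = 1e-9)
})

test_that("TST sweep shows the short/long-quota crossover in marginal savings", {
  sw <- sweep_tst(ea_params(), tst_grid = c(4, 6, 14, 16), mai_target = 0.4,
                  rho = 0.3)
  expect_true(all(sw$exists))
  # modest partitioning saves at least as much as rate reduction at every quota
  expect_true(all(sw$es_mai >= sw$es_rho))
  # but the marginal gains cross over: extra sleep pays through partitioning
  # at short quotas and through rate reduction beyond about 14 h, where the
  # MAI contribution flattens
  expect_gt(diff(sw$es_mai[sw$tst_h %in% c(4, 6)]),
            diff(sw$es_rho[sw$tst_h %in% c(4, 6)]))
  expect_gt(diff(sw$es_rho[sw$tst_h %in% c(14, 16)]),
            diff(sw$es_mai[sw$tst_h %in% c(14, 16)]))
  # longer sleep saves more in total
  expect_true(all(diff(sw$es_total) > 0))
})

test_that("a zero sleep quota reproduces the baseline (all savings zero)", {
  sw <- sweep_tst(ea_params(), tst_grid = 0, mai_target = 0, rho = 0)
  expect_true(sw$exists[1])
  expect_equal(sw$es_total[1], 0, tolerance = 0.05)
})

test_that("rho sweep: no rate reduction means no rho savings; high rho constrains MAI", {
  sw <- sweep_rho(ea_params(), rho_grid = c(0, 0.3, 0.9), mai_target = 0.7,
                  tst_h = 8)
  expect_true(all(sw$exists))
  expect_lt(abs(sw$es_rho[1]), 0.05) # within the mean-debt matching tolerance
  # reductions in sleep metabolic rate constrain the achievable MAI
  expect_lt(sw$mai_achieved[3], sw$mai_achieved[2])
  # and shrink the MAI share of the savings
  expect_lt(sw$es_mai[3], sw$es_mai[2])
})

test_that("circadian sweep: amplitude helps with partitioning, hurts without", {
  sw <- sweep_circadian(ea_params(), mai_grid = c(0, 0.7), a_grid = c(0, 2.5),
                        rho = 0.3, tst_h = 8)
  expect_equal(nrow(sw), 4L)
  e <- function(a, m) sw$es_total[sw$A == a & sw$mai_target == m]
  expect_lt(e(2.5, 0), e(0, 0))     # no partitioning: amplitude costs energy
  expect_gt(e(2.5, 0.7), e(0, 0.7)) # moderate partitioning: amplitude pays
  # the A = 0 column agrees with a no-amplitude MAI sweep
  sw0 <- sweep_mai(ea_params(A = 0), mai_grid = c(0, 0.7), rho = 0.3, tst_h = 8)
  expect_equal(e(0, 0), sw0$es_total[1], tolerance = 1e-9)
  expect_equal(e(0, 0.7), sw0$es_total[2], tolerance = 1e-9)
})

test_that("the MAI/rho sweeps agree at their shared grid point", {
  a <- sweep_mai(ea_params(), mai_grid = 0.7, rho = 0.3, tst_h = 8)
  b <- sweep_rho(ea_params(), rho_grid = 0.3, mai_target = 0.7, tst_h = 8)
  expect_equal(a$es_total, b$es_total, tolerance = 1e-9)
})

test_that("sensitivity grid is deterministic and flags missing cycles", {
  run <- function() {
    sensitivity_grid(ea_params(), pw_grid = c(0, 1.3), pb1_grid = 0.7,
                     mc_values = 5)
  }
  g1 <- run(); g2 <- run()
  expect_identical(as.data.frame(g1), as.data.frame(g2))
  # p_W = 0 leaves continuous wakefulness without a stable cycle
  expect_false(g1$exists[g1$p_W == 0])
  expect_true(g1$exists[g1$p_W == 1.3])
  rng <- sensitivity_ranges(g1)
  expect_equal(rng$per_mc$n, 1L)
  expect_equal(rng$overall_range, 0)
})

test_that("multi-day runs converge at a full quota and fail to at severe restriction", {
  mp <- match_mean_bd(ea_params(), rho = 0.3, mai_target = 0.4)
  # full 8 h quota: daily means flat at steady state
  run8 <- multiday_run(mp$params, n_days = 12, bd_init = mp$bd0)
  expect_true(attr(run8, "steady_state"))
  expect_false(attr(run8, "escalation"))
  expect_lt(diff(range(run8$mean_bd)) / run8$mean_bd[1], 1e-4)
  # debt is continuous across day boundaries
  expect_equal(run8$bd_start[-1], run8$bd_end[-nrow(run8)], tolerance = 1e-12)
  # severe restriction with the same rates: no steady state within 12 days
  run3 <- multiday_run(ea_update(mp$params, TST_h = 3), n_days = 12,
                       bd_init = mp$bd0)
  expect_false(attr(run3, "steady_state"))
  expect_true(all(diff(run3$mean_bd) > 0))
  # glance reports the flags
  g <- glance(run3)
  expect_false(g$steady_state)
  # zero rates: constant debt, trivially steady
  p0 <- ea_params(r_Ww = 0, r_Bw = 0, r_Ws = 0, r_Bs = 0)
  run0 <- multiday_run(p0, n_days = 3, bd_init = 0.5)
  expect_true(attr(run0, "steady_state"))
  expect_equal(run0$mean_bd, rep(0.5, 3), tolerance = 1e-8)
})

test_that("debt-shape metrics distinguish flat, sinusoid-like, and homeostat-like days", {
  # no amplitude, no partitioning: flat line at steady state
  p_flat <- ea_params(A = 0, TST_h = 8)
  cyc <- find_limit_cycles(p_flat)
  tr <- integrate_day(p_flat, cyc$bd0[cyc$stability == "stable"][1])
  m <- bd_shape_metrics(tr)
  expect_lt(m$bd_range, 1e-6)
  expect_equal(m$n_max, 0L)
  # amplitude without partitioning: one maximum and one minimum per period
  p_sin <- ea_params(A = 2.5, TST_h = 8)
  cyc <- find_limit_cycles(p_sin)
  tr <- integrate_day(p_sin, cyc$bd0[cyc$stability == "stable"][1])
  m <- bd_shape_metrics(tr)
  expect_gt(m$bd_range, 0.01)
  expect_equal(m$n_max, 1L)
  expect_equal(m$n_min, 1L)
  # partitioning: debt rises through wake and falls through sleep
  mp <- match_mean_bd(ea_params(), rho = 0.3, mai_target = 0.4)
  tr <- integrate_day(mp$params, mp$bd0)
  m <- bd_shape_metrics(tr)
  expect_gt(m$frac_rising_wake, 0.9)
  expect_gt(m$frac_falling_sleep, 0.9)
})
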