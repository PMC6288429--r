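test_that("decay fit recovers known time constants to < 0.1%", {
  for (tau in c(5, 18.7, 60, 320)) {
    d <- synthetic_decay(tau)
    fit <- fit_decay(d$time, d$current)
    expect_true(fit$ok)
    expect_lt(abs(fit$tau - tau) / tau, 1e-3)
  }
  # offset is recovered too
  d <- synthetic_decay(40, offset = -0.8)
  fit <- fit_decay(d$time, d$current)
  expect_lt(abs(fit$offset - -0.8), 0.01)
})

test_that("decay-phase windowing isolates the decay from late rebounds", {
  d <- synthetic_decay(20)
  # a late secondary bump (release-driven rebound) ends the fit window but
  # does not corrupt the early time constant
  d$current <- d$current - 1.5 * exp(-((d$time - 300) / 40)^2)
  fit <- fit_decay(d$time, d$current)
  expect_lt(fit$window[2], 300)
  expect_lt(abs(fit$tau - 20) / 20, 0.15)
})

test_that("decay fit flags non-exponential traces instead of failing silently", {
  d <- synthetic_decay(20)
  # persistent large oscillation: no clean decay phase exists
  d$current <- d$current + 0.8 * sin(d$time / 3)
  fit <- fit_decay(d$time, d$current)
  expect_false(fit$ok)
  expect_true(is.finite(fit$tau))
})

test_that("APD90 of an analytic triangular AP matches the closed form", {
  # peak +40 at t = 1, linear fall to -85 at t = 251:
  # 90% repolarization level = 40 - 0.9 * 125 = -72.5 mV,
  # crossed at t = 1 + 112.5 / 0.5 = 226 ms; upstroke at t ~ 0
  tr <- triangle_ap()
  apd <- compute_apd90(tr$time, tr$v)
  expect_true(apd$repolarized)
  expect_lt(abs(apd$apd90 - 226), 0.3)
  expect_equal(apd$v_peak, 40)
})

test_that("a beat that never repolarizes carries no finite APD90", {
  t <- seq(0, 999, by = 0.5)
  v <- -85 + 120 * pmin(1, t / 2) - 20 * pmin(1, t / 500)  # stays high
  apd <- compute_apd90(t, v)
  expect_false(apd$repolarized)
  expect_true(is.na(apd$apd90))
})

test_that("APD90 is stable under sampling-interval halving", {
  st <- baseline_paced_state()
  cfg <- baseline_config()
  tr1 <- run_beat(st, cfg, record = TRUE, dt_record = 0.1)$trace
  tr2 <- run_beat(st, cfg, record = TRUE, dt_record = 0.05)$trace
  a1 <- compute_apd90(tr1$time, tr1$v)$apd90
  a2 <- compute_apd90(tr2$time, tr2$v)$apd90
  expect_lt(abs(a1 - a2), 0.5)
})

test_that("EAD detection counts plateau deflections, not the spike-dome", {
  apd_of <- function(tr) compute_apd90(tr$time, tr$v)
  # monotone repolarization: no EADs
  tr <- bumpy_ap()
  expect_identical(count_eads(tr$time, tr$v, apd_of(tr)), 0L)
  # one 10 mV bump during the plateau: one EAD
  tr1 <- bumpy_ap(bumps = list(c(150, 15, 10)))
  expect_identical(count_eads(tr1$time, tr1$v, apd_of(tr1)), 1L)
  # two separated bumps above the floor: two EADs
  tr2 <- bumpy_ap(bumps = list(c(130, 12, 12), c(200, 12, 12)), tau = 160)
  expect_identical(count_eads(tr2$time, tr2$v, apd_of(tr2)), 2L)
  # sub-threshold ripple (< 1 mV prominence) is ignored
  tr3 <- bumpy_ap(bumps = list(c(150, 15, 0.5)))
  expect_identical(count_eads(tr3$time, tr3$v, apd_of(tr3)), 0L)
  # a deflection taking off above +20 mV is the spike-notch-dome complex
  tr4 <- bumpy_ap(bumps = list(c(8, 3, 30)))
  expect_identical(count_eads(tr4$time, tr4$v, apd_of(tr4)), 0L)
})

test_that("beat classification separates normal, EAD, and oscillatory", {
  cl <- 1000
  t <- seq(0, 2 * cl, by = 0.5)
  tb <- t %% cl
  normal <- -85 + 125 * pmin(1, tb / 2) * exp(-pmax(0, tb - 2) / 120)
  m <- classify_beats(data.frame(time = t, v = normal), cl = cl)
  expect_equal(m$class, c("normal", "normal"))
  expect_true(all(is.finite(m$apd90)))
  # voltage never reaching 90% repolarization: oscillatory, no finite APD90
  t1 <- seq(0, cl, by = 0.5)
  osc <- -85 + 110 * pmin(1, t1 / 2) - 15 * pmin(1, t1 / 600) +
    5 * sin(t1 / 30)
  mo <- classify_beats(data.frame(time = t1, v = osc), cl = cl)
  expect_equal(mo$class, "oscillatory")
  expect_true(is.na(mo$apd90))
})
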