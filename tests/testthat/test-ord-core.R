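test_that("right-hand side rejects non-finite states, naming the field", {
  y <- ord_initial_state()
  y[["cai"]] <- NaN
  expect_error(ord_rhs(y), "cai")
  y <- ord_initial_state()
  y[["xs1"]] <- Inf
  expect_error(ord_rhs(y), "xs1")
})

test_that("gate variables cannot leave [0, 1]", {
  gates <- setdiff(ord_state_names(),
                   c("v", "nai", "nass", "ki", "kss", "cai", "cass",
                     "cansr", "cajsr", "casl", "jrelnp", "jrelp",
                     "jrelorph"))
  cfg <- model_config(remodeling = remodeling_params(0.5, 0.5, 0.5))
  for (vtest in c(-87.5, -20, 10)) {
    y <- ord_initial_state()
    y[["v"]] <- vtest
    for (g in gates) {
      y0 <- y; y0[[g]] <- 0
      expect_gte(ord_rhs(y0, config = cfg)$derivatives[[g]], 0)
      y1 <- y; y1[[g]] <- 1
      expect_lte(ord_rhs(y1, config = cfg)$derivatives[[g]], 0)
    }
  }
})

test_that("the unstimulated cell has a stable resting state near -88 mV", {
  cfg <- baseline_config()
  rest <- cached("baseline_rest", find_rest(cfg, max_time = 100000))
  # published baseline resting potential is about -88 mV
  expect_lt(abs(rest[["v"]] - -88), 1.5)
  r <- ord_rhs(rest, config = cfg)
  expect_lt(max(abs(r$derivatives)), 1e-4)
  # rest is a fixed point: 10 s free-running stays within 1 mV
  out <- integrate_segment(rest, cfg, c(0, 10000))
  expect_lt(abs(out[nrow(out), "v"] - rest[["v"]]), 1)
  # concentrations positive, gates in bounds
  expect_true(all(rest[c("nai", "ki", "cai", "cass", "casl", "cansr",
                         "cajsr")] > 0))
})

test_that("paced baseline beat matches the published endocardial phenotype", {
  cfg <- baseline_config()
  st <- baseline_paced_state()
  tr <- run_beat(st, cfg, record = TRUE)$trace
  apd <- compute_apd90(tr$time, tr$v)
  # published endo APD90 at CL 1000 ms is ~270 ms
  expect_gt(apd$apd90, 240)
  expect_lt(apd$apd90, 300)
  expect_gt(apd$v_peak, 25)
  expect_lt(apd$v_peak, 55)
  expect_gt(max(tr$cai), 2e-4)  # a real Ca transient
})

test_that("remodeling machinery is inert at the intact corner", {
  # with f_TT = 1 and all channels in subgroup A, the sub-sarcolemmal pool,
  # orphaned release, and surface NCX carry nothing: perturbing their
  # parameters must not change the AP
  st <- baseline_paced_state()
  cfg1 <- baseline_config()
  cfg2 <- baseline_config(geometry = list(sl_cdi_scale = 0.01),
                          orphan = list(amp = 50, km = 1e-4))
  cfg2$phospho$camk_fraction <- 0.9  # surface CaMKII pool: no channels there
  tr1 <- run_beat(st, cfg1, record = TRUE)$trace
  tr2 <- run_beat(st, cfg2, record = TRUE)$trace
  expect_lt(max(abs(tr1$v - tr2$v)), 1e-6)
  expect_equal(max(abs(tr1$ical_sl)), 0)
  expect_lt(max(tr1$jrelorph_flux), 1e-12)
  expect_equal(max(abs(tr1$inaca_sl)), 0)
})

test_that("total calcium is conserved when sarcolemmal Ca fluxes are removed", {
  # zero every sarcolemmal Ca pathway through the conductance block, then
  # total Ca (free + buffered, volume weighted) must stay constant
  cfg <- model_config(remodeling = remodeling_params(0.5, 0.5, 0.5),
                      conductances = list(pca = 0, gncx = 0, pcab = 0,
                                          gpca = 0))
  y <- ord_initial_state()
  tot0 <- total_calcium(y, cfg)
  out <- integrate_segment(y, cfg, seq(0, 10000, by = 1000))
  for (k in seq_len(nrow(out))) {
    yk <- out[k, 2:45]; names(yk) <- ord_state_names()
    expect_lt(abs(total_calcium(yk, cfg) - tot0) / tot0, 1e-6)
  }
})

test_that("APD90 is insensitive to solver tolerance", {
  st <- baseline_paced_state()
  apd <- function(rtol, atol) {
    cfg <- baseline_config(solver = list(rtol = rtol, atol = atol))
    tr <- run_beat(st, cfg, record = TRUE)$trace
    compute_apd90(tr$time, tr$v)$apd90
  }
  expect_lt(abs(apd(1e-6, 1e-8) - apd(5e-7, 5e-9)), 0.5)
})

test_that("extending conditioning beyond the criterion leaves APD90 put", {
  cfg <- baseline_config()
  st1 <- pace_to_steady(ord_initial_state(), cfg, max_beats = 150)
  expect_true(st1$converged)
  st2 <- pace_to_steady(st1$state, cfg, max_beats = 2 * st1$beats)
  tr1 <- run_beat(st1$state, cfg, record = TRUE)$trace
  tr2 <- run_beat(st2$state, cfg, record = TRUE)$trace
  expect_lt(abs(compute_apd90(tr1$time, tr1$v)$apd90 -
                compute_apd90(tr2$time, tr2$v)$apd90), 1)
})
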