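test_that("subgroup fractions are products of the remodeling probabilities", {
  # intact myocyte: every channel is in subgroup A
  expect_equal(unname(subgroup_fractions(remodeling_params(1, 1, 1))),
               c(1, 0, 0, 0, 0, 0))
  # complete de-tubulation moves everything to the surface (subgroup D)
  expect_equal(unname(subgroup_fractions(remodeling_params(0, 1, 1))),
               c(0, 0, 0, 1, 0, 0))
  # product arithmetic; C and F absorb both PDE states of B2AR-free channels
  expect_equal(unname(subgroup_fractions(remodeling_params(0.5, 0.5, 0.5))),
               c(0.125, 0.125, 0.25, 0.125, 0.125, 0.25))
  expect_error(remodeling_params(1.3, 1, 1), "f_tt")
})

test_that("subgroup weights normalize exactly over the full sweep grid", {
  for (fb in seq(0, 1, by = 0.25))
    for (ft in seq(0, 1, by = 0.1))
      for (fp in seq(0, 1, by = 0.1)) {
        w <- subgroup_fractions(remodeling_params(ft, fb, fp))
        expect_lt(abs(sum(w) - 1), 1e-15)
        expect_true(all(w >= 0))
      }
})

test_that("preset cases put 80% in the dominant subgroup at the right corner", {
  for (id in 1:6) {
    cd <- case_definition(id)
    expect_equal(unname(cd$weights[id]), 0.8)
    expect_equal(sum(cd$weights), 1)
    expect_equal(sum(cd$weights[-id]), 0.2)
  }
  expect_equal(case_definition(1)$remodeling$f_tt, 1)
  expect_equal(case_definition(4)$remodeling$f_tt, 0)  # de-tubulated
  expect_equal(case_definition(3)$remodeling$f_b2ar, 0)
  expect_equal(case_definition(2)$remodeling$f_pde, 0)
  expect_error(case_definition(7), "1..6")
})

test_that("NCX redistributes to the surface in proportion to T-tubule loss", {
  expect_equal(ncx_distribution(1), c(t_tubular = 0.8, surface = 0.2))
  expect_equal(ncx_distribution(0), c(t_tubular = 0, surface = 1))
  expect_equal(ncx_distribution(0.5), c(t_tubular = 0.4, surface = 0.6))
  expect_error(ncx_distribution(-0.1), "\\[0, 1\\]")
})

test_that("RyR coupling follows T-tubule integrity", {
  expect_equal(ryr_coupling(1), c(coupled = 1, orphaned = 0))
  expect_equal(ryr_coupling(0), c(coupled = 0, orphaned = 1))
  expect_equal(ryr_coupling(0.3), c(coupled = 0.3, orphaned = 0.7))
})

test_that("surface and T-tubular LTCC components split by subgroup weights", {
  # fixed state; all-surface configuration carries no T-tubular current
  y <- ord_initial_state()
  y[["v"]] <- -6.7; y[["d"]] <- 0.3  # open channels at a plateau potential
  cur_tt_only <- ord_rhs(y, config = model_config(
    remodeling = remodeling_params(1, 1, 1)))$currents
  cur_sl_only <- ord_rhs(y, config = model_config(
    remodeling = remodeling_params(0, 1, 1)))$currents
  expect_equal(unname(cur_tt_only["ical_sl"]), 0)
  expect_equal(unname(cur_sl_only["ical_tt"]), 0)
  expect_lt(cur_tt_only[["ical_tt"]], 0)
  expect_lt(cur_sl_only[["ical_sl"]], 0)
})

test_that("peak LTCC current under stimulation is non-decreasing in f_B2AR", {
  # fixed state, growing B2AR association: more channels phosphorylated
  y <- ord_initial_state()
  y[["v"]] <- -6.7; y[["d"]] <- 0.3
  peaks <- vapply(seq(0, 1, by = 0.25), function(fb) {
    cfg <- model_config(remodeling = remodeling_params(1, fb, 0.5,
                                                       stimulated = TRUE))
    -ord_rhs(y, config = cfg)$currents[["ical"]]
  }, numeric(1))
  expect_true(all(diff(peaks) >= -1e-12))
})
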