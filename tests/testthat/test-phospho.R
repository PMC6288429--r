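test_that("PKA-phosphorylated fractions follow the subgroup signaling class", {
  ph <- phospho_config()
  # PDE-associated channels: 25% at rest, 75% under stimulation
  expect_equal(pka_fraction(ph, "with_PDE", stimulated = FALSE), 0.25)
  expect_equal(pka_fraction(ph, "with_PDE", stimulated = TRUE), 0.75)
  # no beta-2 AR, no phosphorylation, ever
  expect_equal(pka_fraction(ph, "without_B2AR", stimulated = FALSE), 0)
  expect_equal(pka_fraction(ph, "without_B2AR", stimulated = TRUE), 0)
  # PDE-free channels are fully phosphorylated under stimulation; at rest
  # PDE (itself PKA-activated) is inactive, so its absence changes nothing
  expect_equal(pka_fraction(ph, "without_PDE", stimulated = TRUE), 1.0)
  expect_equal(pka_fraction(ph, "without_PDE", stimulated = FALSE),
               pka_fraction(ph, "with_PDE", stimulated = FALSE))
  expect_error(pka_fraction(ph, "nonsense"), "unknown subgroup class")
})

test_that("per-subgroup fractions pair T-tubular and surface columns", {
  p <- subgroup_pka_fractions(phospho_config(), stimulated = TRUE)
  expect_equal(unname(p[c("pA", "pD")]), c(0.75, 0.75))
  expect_equal(unname(p[c("pB", "pE")]), c(1, 1))
  expect_equal(unname(p[c("pC", "pF")]), c(0, 0))
})

test_that("population current composes weighted binary populations", {
  # identity: nothing phosphorylated
  expect_equal(population_current(-2.4), -2.4)
  # fully PKA-phosphorylated LTCC: amplitude x 2.5
  expect_equal(population_current(-1, pka_weight = 1, pka_effect = 2.5), -2.5)
  # 50/50 split: 0.5 * 1 + 0.5 * 2.5
  expect_equal(population_current(-1, pka_weight = 0.5, pka_effect = 2.5),
               -1.75)
  # PKA and CaMKII act independently (product of multipliers)
  expect_equal(population_current(-1, pka_weight = 1, camk_weight = 1,
                                  pka_effect = 2.5, camk_effect = 1.1),
               -2.75)
  expect_error(population_current(-1, pka_weight = -0.1), "\\[0, 1\\]")
})

test_that("total current is linear in the population weights", {
  # convex combinations of valid splits give convex combinations of currents
  set.seed(11)
  for (k in 1:20) {
    w1 <- runif(1); w2 <- runif(1); a <- runif(1)
    base <- -runif(1, 0.5, 5)
    mix <- population_current(base, pka_weight = a * w1 + (1 - a) * w2,
                              pka_effect = 2.5)
    parts <- a * population_current(base, pka_weight = w1, pka_effect = 2.5) +
      (1 - a) * population_current(base, pka_weight = w2, pka_effect = 2.5)
    expect_equal(mix, parts, tolerance = 1e-12)
  }
})

test_that("target effect table is identity when unphosphorylated", {
  for (target in c("RyR", "PLB", "IKs", "INa", "INaK", "IKur", "TnI",
                   "LTCC", "INaL")) {
    mod <- target_effects(target, phosphorylated = FALSE)
    expect_equal(mod$amp, 1)
    expect_equal(mod$km_up_factor, 1)
    expect_equal(mod$km_trpn_factor, 1)
  }
  expect_equal(target_effects("LTCC", TRUE)$amp, 2.5)
  expect_lt(target_effects("PLB", TRUE)$km_up_factor, 1)
  expect_gt(target_effects("TnI", TRUE)$km_trpn_factor, 1)
  expect_error(target_effects("IKr", TRUE), "unsupported")
})

test_that("parameter packing carries phospho state into the solver vector", {
  cfg <- model_config(remodeling = remodeling_params(stimulated = TRUE))
  p <- build_parms(cfg)
  expect_length(p, length(ord_parameter_names()))
  expect_equal(unname(p["pB"]), 1)     # PDE-free, stimulated
  expect_equal(unname(p["pk_ryr"]), 0.75)
  expect_equal(unname(p["eff_ltcc"]), 2.5)
  cfg0 <- model_config()
  expect_equal(unname(build_parms(cfg0)["pk_ryr"]), 0.25)
})
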