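test_that("voltage clamp reaches a holding steady state and fits both components", {
  vc <- case_clamp(1, FALSE)
  expect_true(vc$holding$converged)
  expect_true(all(c("time", "v", "ical_tt", "ical_sl", "ical") %in%
                  names(vc$trace)))
  expect_equal(unique(vc$trace$v), -6.7)
  expect_true(vc$tau1$ok)
  expect_gt(vc$tau1$tau, 0)
  expect_gt(vc$tau2$tau, vc$tau1$tau)  # surface decay slower than dyadic
  # components add up to the total
  expect_equal(vc$trace$ical, vc$trace$ical_tt + vc$trace$ical_sl,
               tolerance = 1e-10)
})

test_that("steady-state pacing records identical consecutive beats", {
  pe <- case_pacing(1, FALSE)
  expect_true(pe$conditioning$converged)
  expect_equal(nrow(pe$metrics), 3)
  expect_lt(diff(range(pe$metrics$apd90)), 1)
  expect_equal(pe$metrics$class, rep("normal", 3))
})

test_that("sweeps cover the grid, tolerate failures, and are bit-identical", {
  run <- function() sweep_heatmap(f_b2ar_levels = c(0.25, 1),
                                  stimulated = TRUE,
                                  f_tt_grid = c(0.2, 1),
                                  f_pde_grid = c(0, 1),
                                  recorded_beats = 2,
                                  max_conditioning_beats = 10,
                                  dt_record = 1)
  s1 <- run()
  expect_equal(nrow(s1), 8)
  expect_true(all(!is.na(s1$mean_apd90) | s1$class == "oscillatory" |
                  !is.na(s1$error)))
  # whole-sweep determinism
  s2 <- run()
  expect_identical(s1, s2)
  # a failing grid point is recorded, the sweep continues
  s3 <- sweep_heatmap(f_b2ar_levels = 1, stimulated = FALSE,
                      f_tt_grid = c(0.5, 1), f_pde_grid = 1,
                      recorded_beats = 1, max_conditioning_beats = 2,
                      dt_record = 1,
                      config_fn = function(rem) {
                        if (rem$f_tt < 1) stop("deliberate grid failure")
                        model_config(remodeling = rem)
                      })
  expect_equal(sum(!is.na(s3$error)), 1)
  expect_equal(sum(is.na(s3$error)), 1)
})

test_that("the command-line interface runs a short pacing case end to end", {
  out_dir <- tempfile("cli")
  status <- suppressMessages(
    cardiomd_cli(c("case", "1", "--beats", "1", "--max-beats", "2",
                   "--out", out_dir)))
  expect_identical(status, 0L)
  expect_true(file.exists(file.path(out_dir, "pace_trace.csv")))
  expect_true(file.exists(file.path(out_dir, "beat_metrics.csv")))
  # configuration errors exit with status 1
  expect_identical(suppressMessages(
    cardiomd_cli(c("pace", "--f_tt", "1.4"))), 1L)
  expect_identical(suppressMessages(cardiomd_cli(character())), 1L)
})
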