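#' Voltage-clamp protocol for the LTCC current
#'
#' Holds the membrane at the holding potential until the clamped cell
#' reaches steady state, steps to the test potential, and records the
#' T-tubular and surface-membrane components of the LTCC current. Each
#' component's post-peak decay is fitted with a single exponential plus
#' offset; the T-tubular time constant is reported as `tau1` and the
#' surface-membrane one as `tau2`.
#'
#' @param config a [model_config()].
#' @param v_hold holding potential (mV).
#' @param v_step step potential (mV).
#' @param step_duration recorded step length (ms).
#' @param dt sampling interval (ms).
#' @return list with `trace` (data.frame: time, v, ical_tt, ical_sl,
#'   ical), `tau1`, `tau2` (full [fit_decay()] results), and the
#'   holding-state convergence report.
#' @export
run_voltage_clamp <- function(config, v_hold = -96.7, v_step = -6.7,
                              step_duration = 500, dt = NULL) {
  stopifnot(v_hold < v_step)
  dt <- dt %||% config$solver$dt_record
  hold <- clamp_to_steady(ord_initial_state(config), config, v_hold)
  state <- hold$state
  state[["v"]] <- v_step
  out <- integrate_segment(state, config, seq(0, step_duration, by = dt),
                           clamp = TRUE)
  trace <- data.frame(time = out[, "time"], v = out[, "v"],
                      ical_tt = out[, "ical_tt"],
                      ical_sl = out[, "ical_sl"],
                      ical = out[, "ical"])
  tau1 <- fit_decay(trace$time, trace$ical_tt)
  tau2 <- fit_decay(trace$time, trace$ical_sl)
  list(trace = trace, tau1 = tau1, tau2 = tau2, holding = hold)
}

#' Steady-state pacing experiment
#'
#' Paces the configured myocyte at the protocol cycle length until the
#' steady-state criterion is met, then records the requested number of
#' beats, returning the sampled trace, per-beat metrics, and the mean
#' APD90 over the recorded beats (oscillatory beats carry no finite APD90
#' and are excluded from the mean).
#'
#' @param config a [model_config()].
#' @param recorded_beats number of beats to record (3 for APD analysis,
#'   15 for EAD evaluation).
#' @param max_conditioning_beats optional cap overriding the protocol
#'   block.
#' @param dt_record sampling interval for the recorded beats (ms).
#' @return list with `trace`, `metrics` (from [classify_beats()]),
#'   `mean_apd90`, `conditioning` report, and `config`.
#' @export
run_pacing_experiment <- function(config, recorded_beats = 3,
                                  max_conditioning_beats = NULL,
                                  dt_record = NULL) {
  cond <- pace_to_steady(ord_initial_state(config), config,
                         max_beats = max_conditioning_beats)
  state <- cond$state
  traces <- vector("list", recorded_beats)
  for (b in seq_len(recorded_beats)) {
    res <- run_beat(state, config, record = TRUE, dt_record = dt_record)
    tr <- res$trace
    tr$time <- tr$time + (b - 1) * config$protocol$cl
    traces[[b]] <- tr
    state <- res$state
  }
  trace <- do.call(rbind, traces)
  metrics <- classify_beats(trace, cl = config$protocol$cl,
                            prominence = config$protocol$ead_prominence,
                            floor = config$protocol$ead_floor,
                            takeoff_max = config$protocol$ead_takeoff)
  list(trace = trace, metrics = metrics,
       mean_apd90 = mean(metrics$apd90[metrics$class != "oscillatory"],
                         na.rm = TRUE),
       conditioning = cond, config = config)
}

#' Parameter-sweep heatmap of APD90 and beat classification
#'
#' Runs the steady-state pacing protocol over the grid of T-tubule
#' integrity and PDE association for each beta-2 AR level, storing the
#' mean APD90 over the recorded beats, the EAD count, and the dominant
#' classification of each cell. Deterministic and order-independent;
#' individual grid-point failures are recorded and the sweep continues.
#'
#' @param f_b2ar_levels beta-2 AR association levels.
#' @param stimulated sympathetic stimulation applied?
#' @param f_tt_grid,f_pde_grid grid values.
#' @param recorded_beats beats recorded per cell (default 15).
#' @param max_conditioning_beats conditioning cap per cell.
#' @param dt_record sampling interval for recorded beats (ms).
#' @param config_fn optional function `(remodeling) -> model_config` for
#'   customized sweeps.
#' @return data.frame with one row per grid cell: `f_b2ar`, `f_tt`,
#'   `f_pde`, `mean_apd90`, `n_ead`, `n_osc_beats`, `class`, `error`.
#' @export
sweep_heatmap <- function(f_b2ar_levels = seq(0, 1, by = 0.25),
                          stimulated = TRUE,
                          f_tt_grid = seq(0, 1, by = 0.1),
                          f_pde_grid = seq(0, 1, by = 0.1),
                          recorded_beats = 15,
                          max_conditioning_beats = NULL,
                          dt_record = 0.5,
                          config_fn = NULL) {
  grid <- expand.grid(f_pde = f_pde_grid, f_tt = f_tt_grid,
                      f_b2ar = f_b2ar_levels)
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    g <- grid[k, ]
    base <- data.frame(f_b2ar = g$f_b2ar, f_tt = g$f_tt, f_pde = g$f_pde)
    res <- tryCatch({
      rem <- remodeling_params(g$f_tt, g$f_b2ar, g$f_pde,
                               stimulated = stimulated)
      cfg <- if (is.null(config_fn)) model_config(remodeling = rem)
             else config_fn(rem)
      run_pacing_experiment(cfg, recorded_beats = recorded_beats,
                            max_conditioning_beats = max_conditioning_beats,
                            dt_record = dt_record)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      return(cbind(base, data.frame(mean_apd90 = NA_real_,
                                    n_ead = NA_integer_,
                                    n_osc_beats = NA_integer_,
                                    class = NA_character_,
                                    error = conditionMessage(res),
                                    stringsAsFactors = FALSE)))
    }
    m <- res$metrics
    n_osc <- sum(m$class == "oscillatory")
    cls <- if (n_osc > 0) "oscillatory"
           else if (any(m$class == "EAD")) "EAD" else "normal"
    cbind(base, data.frame(mean_apd90 = res$mean_apd90,
                           n_ead = sum(m$n_ead),
                           n_osc_beats = n_osc,
                           class = cls, error = NA_character_,
                           stringsAsFactors = FALSE))
  })
  do.call(rbind, rows)
}
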