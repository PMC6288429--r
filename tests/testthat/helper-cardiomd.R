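# Shared fixtures: expensive simulations are cached across test files so a
# case is conditioned at most once per test run.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

case_pacing <- function(case_id, stimulated, beats = 3, cap = 200) {
  key <- sprintf("pace_%d_%d_%d_%d", case_id, stimulated, beats, cap)
  cached(key, {
    cfg <- model_config(case_id = case_id,
                        remodeling = remodeling_params(stimulated = stimulated))
    suppressWarnings(
      run_pacing_experiment(cfg, recorded_beats = beats,
                            max_conditioning_beats = cap))
  })
}

case_clamp <- function(case_id, stimulated) {
  key <- sprintf("clamp_%d_%d", case_id, stimulated)
  cached(key, {
    cfg <- model_config(case_id = case_id,
                        remodeling = remodeling_params(stimulated = stimulated))
    suppressWarnings(run_voltage_clamp(cfg))
  })
}

# baseline cell: phosphorylation populations off, dynamic CaMKII everywhere
baseline_config <- function(...) {
  model_config(phospho = phospho_config(basal_pka_fraction = 0,
                                        stim_pka_fraction = 0,
                                        camk_fraction = 0),
               ttub_camk = "dynamic", ...)
}

baseline_paced_state <- function() {
  cached("baseline_paced", {
    cfg <- baseline_config()
    pace_to_steady(ord_initial_state(), cfg, max_beats = 150)$state
  })
}

# synthetic mono-exponential decay trace sampled like a clamp recording
synthetic_decay <- function(tau, amp = -5, offset = -0.1, t_end = 500,
                            dt = 0.1, t_peak = 5) {
  t <- seq(0, t_end, by = dt)
  rise <- pmin(1, t / t_peak)
  i <- offset + amp * rise * exp(-pmax(0, t - t_peak) / tau)
  data.frame(time = t, current = i)
}

# triangular AP with analytic APD90
triangle_ap <- function(dt = 0.1, v_rest = -85, v_peak = 40,
                        t_peak = 1, t_end_fall = 251, t_total = 600) {
  t <- seq(0, t_total, by = dt)
  v <- ifelse(t <= t_peak, v_rest + (v_peak - v_rest) * t / t_peak,
         ifelse(t <= t_end_fall,
                v_peak - (v_peak - v_rest) * (t - t_peak) /
                  (t_end_fall - t_peak),
                v_rest))
  data.frame(time = t, v = v)
}

# smooth AP-like pulse with optional plateau bumps (for EAD detection)
bumpy_ap <- function(bumps = list(), dt = 0.1, t_total = 1000, tau = 120) {
  t <- seq(0, t_total, by = dt)
  v <- -85 + 125 * (pmin(1, t / 2)) * exp(-pmax(0, t - 2) / tau)
  for (b in bumps)  # b = c(center, width, height)
    v <- v + b[3] * exp(-((t - b[1]) / b[2])^2)
  data.frame(time = t, v = v)
}
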