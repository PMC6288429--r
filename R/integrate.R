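#' Integrate the model over one contiguous segment
#'
#' Thin wrapper over the stiff adaptive solver (lsoda) driving the compiled
#' right-hand side. The stimulus and clamp settings are constant within a
#' segment; protocols stitch segments together so the solver never steps
#' across a current discontinuity.
#'
#' @param state named initial state.
#' @param config a [model_config()].
#' @param times output times (ms), starting at the segment origin.
#' @param istim applied stimulus current (uA/uF) during the segment.
#' @param clamp hold the membrane potential fixed?
#' @return matrix from [deSolve::ode()] with state and auxiliary columns.
#' @export
integrate_segment <- function(state, config, times, istim = 0,
                              clamp = FALSE) {
  p <- build_parms(config, istim = istim, clamp = clamp)
  out <- deSolve::ode(y = state, times = times, func = "ord_derivs",
                      parms = p, dllname = "cardiomd",
                      initfunc = "ord_initmod",
                      nout = 26L, outnames = ord_aux_names(),
                      rtol = config$solver$rtol, atol = config$solver$atol,
                      maxsteps = config$solver$max_steps, method = "lsoda")
  last <- out[nrow(out), 2:45]
  if (any(!is.finite(last)))
    stop(sprintf("solver failure: non-finite state at t = %.3f ms",
                 out[nrow(out), 1]), call. = FALSE)
  out
}

final_state <- function(out) {
  y <- out[nrow(out), 2:45]
  names(y) <- ord_state_names()
  y
}

#' Run one paced beat
#'
#' Applies the stimulus pulse then integrates to the end of the cycle.
#' With `record = TRUE` the full beat is sampled at the analysis interval;
#' otherwise only the segment ends are computed (fast conditioning).
#'
#' @param state initial state (beat start).
#' @param config a [model_config()].
#' @param record sample the beat for analysis?
#' @param dt_record sampling interval (ms); defaults to the solver block's.
#' @return list with `state` (end of beat) and, when recording, `trace`
#'   (data.frame of time, states, currents).
#' @export
run_beat <- function(state, config, record = FALSE, dt_record = NULL) {
  pr <- config$protocol
  dt <- dt_record %||% config$solver$dt_record
  t1 <- if (record) seq(0, pr$stim_dur, by = min(dt, pr$stim_dur)) else
    c(0, pr$stim_dur)
  o1 <- integrate_segment(state, config, t1, istim = pr$stim_amp)
  s1 <- final_state(o1)
  t2 <- if (record)
    unique(c(seq(pr$stim_dur, pr$cl, by = dt), pr$cl))
  else c(pr$stim_dur, pr$cl)
  o2 <- integrate_segment(s1, config, t2, istim = 0)
  res <- list(state = final_state(o2))
  if (record) {
    m <- rbind(o1[-nrow(o1), , drop = FALSE], o2)
    res$trace <- as.data.frame(m)
    names(res$trace)[1] <- "time"
  }
  res
}

#' Pace to steady state
#'
#' Paces at the protocol cycle length until the maximum relative change of
#' the state vector between successive beat starts drops below the
#' conditioning tolerance, capped at the configured maximum beat count.
#'
#' @param state starting state.
#' @param config a [model_config()].
#' @param max_beats optional cap overriding the protocol block.
#' @return list with `state`, `beats` used, and `converged`.
#' @export
pace_to_steady <- function(state, config, max_beats = NULL) {
  cap <- max_beats %||% config$protocol$max_conditioning_beats
  tol <- config$protocol$conditioning_tol
  prev <- state
  converged <- FALSE
  beats <- 0L
  while (beats < cap) {
    state <- run_beat(state, config)$state
    beats <- beats + 1L
    rel <- max(abs(state - prev) / (abs(prev) + 1e-4))
    prev <- state
    if (rel < tol) { converged <- TRUE; break }
  }
  list(state = state, beats = beats, converged = converged)
}

#' Relax to the clamped steady state
#'
#' Holds the membrane potential at `v_hold` and integrates in chunks until
#' the gating and Ca-handling states stop changing (relative tolerance per
#' chunk), capped at `max_time`. Monovalent ion concentrations drift
#' quasi-statically under a sustained clamp (a dialyzed cell never reaches
#' true flux balance) and are excluded from the criterion.
#'
#' @param state starting state.
#' @param config a [model_config()].
#' @param v_hold holding potential (mV).
#' @param chunk chunk length (ms).
#' @param max_time total cap (ms).
#' @param tol relative-change convergence tolerance per chunk.
#' @return list with `state`, `time` spent, and `converged`.
#' @export
clamp_to_steady <- function(state, config, v_hold, chunk = 10000,
                            max_time = 600000, tol = 1e-3) {
  state[["v"]] <- v_hold
  track <- setdiff(ord_state_names(), c("nai", "nass", "ki", "kss"))
  t <- 0
  converged <- FALSE
  while (t < max_time) {
    out <- integrate_segment(state, config, c(0, chunk), clamp = TRUE)
    new <- final_state(out)
    rel <- max(abs(new[track] - state[track]) / (abs(state[track]) + 1e-4))
    state <- new
    t <- t + chunk
    if (rel < tol) { converged <- TRUE; break }
  }
  list(state = state, time = t, converged = converged)
}

#' Find the unstimulated resting state
#'
#' Integrates without stimulus until the free-running state settles.
#'
#' @param config a [model_config()].
#' @param state optional starting state.
#' @param max_time cap (ms).
#' @return resting state vector.
#' @export
find_rest <- function(config, state = NULL, max_time = 200000) {
  state <- state %||% ord_initial_state(config)
  t <- 0
  while (t < max_time) {
    out <- integrate_segment(state, config, c(0, 10000))
    new <- final_state(out)
    rel <- max(abs(new - state) / (abs(state) + 1e-4))
    state <- new
    t <- t + 10000
    if (rel < 1e-7) break
  }
  state
}
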