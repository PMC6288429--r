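#' Fit a mono-exponential decay time constant
#'
#' Fits `I(t) = offset + amplitude * exp(-(t - t0) / tau)` to the decay
#' phase of an inward current, by nonlinear least squares. The fit window
#' opens where the current has relaxed to `window_start` of its post-peak
#' magnitude and closes at the end of the decay phase: the point where the
#' current magnitude rebounds above its running minimum by more than
#' `rebound_tol` of the peak magnitude (secondary release-driven bumps are
#' not part of the inactivation decay), or the end of the trace for
#' monotone decays. Very slow decays therefore keep the whole window and
#' the time constant is extrapolated from the observed curvature. The
#' solver is started from a log-linear estimate plus fallback guesses and
#' the best-residual fit is kept.
#'
#' @param time time (ms).
#' @param current current trace, inward negative.
#' @param window_start fraction of the post-peak magnitude at which the fit
#'   window opens (default 0.95).
#' @param rebound_tol rebound tolerance, as a fraction of the post-peak
#'   magnitude, that ends the decay phase (default 0.02).
#' @return list with `tau` (ms), `amplitude`, `offset`, `rms` residual,
#'   `window` (fit window in ms), and `ok` (fit quality flag: `FALSE` when
#'   the decay is non-monotone or non-exponential enough to defeat the
#'   fit, in which case the values are still reported).
#' @export
fit_decay <- function(time, current, window_start = 0.95,
                      rebound_tol = 0.02) {
  stopifnot(length(time) == length(current), length(time) > 10)
  ipk <- which.min(current)  # inward peak
  if (ipk >= length(current) - 5)
    return(list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                rms = NA_real_, window = c(NA_real_, NA_real_), ok = FALSE))
  tail_level <- mean(current[max(1L, length(current) - 20L):length(current)])
  peak_mag <- tail_level - current[ipk]
  if (peak_mag <= 0)
    return(list(tau = NA_real_, amplitude = NA_real_, offset = NA_real_,
                rms = NA_real_, window = c(NA_real_, NA_real_), ok = FALSE))
  # window opens once the magnitude has relaxed to the requested fraction
  rel <- (tail_level - current) / peak_mag
  i0 <- which(seq_along(current) > ipk & rel <= window_start)[1]
  if (is.na(i0)) i0 <- ipk + 1L
  # window closes where the decay phase ends (magnitude rebounds)
  seg <- current[i0:length(current)]
  run_max <- cummax(seg)  # inward current relaxing toward zero
  turn <- which(seg < run_max - rebound_tol * peak_mag)[1]
  i1 <- if (is.na(turn)) length(current) else i0 + turn - 2L
  i1 <- min(max(i1, i0 + 20L), length(current))
  tt <- time[i0:i1] - time[i0]
  yy <- current[i0:i1]

  off0 <- yy[length(yy)]
  amp0 <- yy[1] - off0
  dec <- off0 - yy
  pos <- dec > 0.02 * max(dec)
  tau_lin <- if (sum(pos) > 5) {
    fitl <- stats::lm(log(dec[pos]) ~ tt[pos])
    max(1, -1 / coef(fitl)[2])
  } else max(1, diff(range(tt)) / 3)
  span <- diff(range(tt))
  best <- NULL
  for (tau0 in unique(c(tau_lin, span / 4, span / 10))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ off + amp * exp(-tt / tau),
                        start = list(off = off0, amp = amp0, tau = tau0),
                        lower = c(-Inf, -Inf, 1e-3),
                        control = minpack.lm::nls.lm.control(maxiter = 300)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rms <- sqrt(mean((yy - predict(fit))^2))
      if (is.null(best) || rms < best$rms)
        best <- list(fit = fit, rms = rms)
    }
  }
  if (is.null(best)) {
    return(list(tau = tau_lin, amplitude = amp0, offset = off0,
                rms = sqrt(mean((yy - off0 - amp0 * exp(-tt / tau_lin))^2)),
                window = c(time[i0], time[i1]), ok = FALSE))
  }
  cf <- coef(best$fit)
  mono <- all(diff(yy) > -rebound_tol * peak_mag)
  # a fit is unreliable when a rebound cut the window before most of the
  # decay had happened (no clean decay phase to fit)
  completion <- (current[i1] - current[i0]) / (tail_level - current[i0])
  enough <- is.na(turn) || completion >= 0.5
  list(tau = unname(cf["tau"]), amplitude = unname(cf["amp"]),
       offset = unname(cf["off"]), rms = best$rms,
       window = c(time[i0], time[i1]),
       ok = mono && enough && best$rms < 0.1 * peak_mag)
}

#' Action potential duration at 90% repolarization
#'
#' APD90 is the time of 90% repolarization minus the time of maximal
#' upstroke velocity. The diastolic reference is the potential just before
#' the stimulus; the repolarization level is
#' `v_peak - 0.9 * (v_peak - v_diastolic)`, located by linear interpolation
#' at the first downward crossing after the peak.
#'
#' @param time time within the beat (ms), stimulus at `stim_time`.
#' @param v membrane potential (mV).
#' @param stim_time stimulus onset (ms).
#' @return list with `apd90` (ms; `NA` when the beat never repolarizes),
#'   `t_upstroke`, `v_peak`, `v_diastolic`, and `repolarized`.
#' @export
compute_apd90 <- function(time, v, stim_time = 0) {
  stopifnot(length(time) == length(v), length(v) > 3)
  pre <- which(time <= stim_time)
  v_dia <- if (length(pre)) v[max(pre)] else v[1]
  dvdt <- diff(v) / diff(time)
  iup <- which.max(dvdt)
  t_up <- time[iup]
  after <- which(time >= t_up)
  ipk <- after[which.max(v[after])]
  v_peak <- v[ipk]
  level <- v_peak - 0.9 * (v_peak - v_dia)
  idx <- which(seq_along(v) > ipk & v <= level)[1]
  if (is.na(idx))
    return(list(apd90 = NA_real_, t_upstroke = t_up, v_peak = v_peak,
                v_diastolic = v_dia, repolarized = FALSE))
  # linear interpolation between the bracketing samples
  t_cross <- time[idx - 1] + (level - v[idx - 1]) *
    (time[idx] - time[idx - 1]) / (v[idx] - v[idx - 1])
  list(apd90 = t_cross - t_up, t_upstroke = t_up, v_peak = v_peak,
       v_diastolic = v_dia, repolarized = TRUE)
}

moving_average <- function(x, n) {
  if (n <= 1) return(x)
  k <- rep(1 / n, n)
  y <- stats::filter(x, k, sides = 2)
  y[is.na(y)] <- x[is.na(y)]
  as.numeric(y)
}

#' Count early afterdepolarizations in one beat
#'
#' An EAD is a local minimum followed by a local maximum of the membrane
#' potential during the repolarization phase (after the AP peak, above the
#' EAD floor, before 90% repolarization), with prominence above the
#' configured threshold. Detection runs on a 1-ms smoothed trace to be
#' robust against solver ripple.
#'
#' @param time,v beat trace.
#' @param apd list from [compute_apd90()].
#' @param prominence minimum deflection (mV).
#' @param floor lowest potential (mV) at which a deflection counts.
#' @param takeoff_max highest takeoff potential (mV): deflections starting
#'   above this are part of the spike-notch-dome complex, not EADs.
#' @param smooth_ms smoothing window (ms).
#' @return integer EAD count.
#' @export
count_eads <- function(time, v, apd, prominence = 1, floor = -50,
                       takeoff_max = 20, smooth_ms = 1) {
  dt <- stats::median(diff(time))
  vs <- moving_average(v, max(1L, round(smooth_ms / dt)))
  ipk <- which.max(vs)
  iend <- if (isTRUE(apd$repolarized))
    max(which(time <= apd$t_upstroke + apd$apd90)) else length(vs)
  if (iend - ipk < 5) return(0L)
  seg <- vs[ipk:iend]
  d <- diff(seg)
  sign_d <- sign(d)
  sign_d[sign_d == 0] <- 1
  turns <- which(diff(sign_d) != 0) + 1L
  n <- 0L
  i <- 1L
  while (i < length(turns)) {
    a <- turns[i]; b <- turns[i + 1L]
    rise <- seg[b] - seg[a]
    if (d[a] > 0 && rise >= prominence && seg[b] >= floor &&
        seg[a] <= takeoff_max) {
      n <- n + 1L
      i <- i + 2L
    } else i <- i + 1L
  }
  n
}

#' Classify recorded beats
#'
#' Computes per-beat APD90 and EAD counts and assigns each beat one of the
#' classes `normal`, `EAD`, or `oscillatory` (the membrane never reaches
#' 90% repolarization before the next stimulus; such beats carry no finite
#' APD90).
#'
#' @param trace data.frame with `time` and `v` columns spanning whole
#'   cycles, stimuli at multiples of `cl` from `t0`.
#' @param cl cycle length (ms).
#' @param t0 time of the first stimulus.
#' @param prominence,floor,takeoff_max EAD detection settings (see
#'   [count_eads()]).
#' @return data.frame with one row per beat: `beat`, `apd90`,
#'   `t_upstroke`, `n_ead`, `class`.
#' @export
classify_beats <- function(trace, cl = 1000, t0 = 0, prominence = 1,
                           floor = -50, takeoff_max = 20) {
  stopifnot(all(c("time", "v") %in% names(trace)))
  t_end <- max(trace$time)
  n_beats <- as.integer((t_end - t0) / cl + 1e-9)
  if (n_beats < 1) stop("trace must span at least one full cycle",
                        call. = FALSE)
  rows <- lapply(seq_len(n_beats), function(b) {
    sel <- trace$time >= t0 + (b - 1) * cl & trace$time <= t0 + b * cl
    tt <- trace$time[sel] - (t0 + (b - 1) * cl)
    vv <- trace$v[sel]
    apd <- compute_apd90(tt, vv, stim_time = 0)
    ne <- count_eads(tt, vv, apd, prominence = prominence,
                     floor = floor, takeoff_max = takeoff_max)
    cls <- if (!apd$repolarized) "oscillatory"
           else if (ne > 0) "EAD" else "normal"
    data.frame(beat = b, apd90 = apd$apd90, t_upstroke = apd$t_upstroke,
               n_ead = ne, class = cls, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
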