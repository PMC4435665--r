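#' Detect action potentials in a current-clamp sweep
#'
#' One spike is counted per upward crossing of `ap_threshold_mV` that is
#' followed by a downward crossing; the spike time is the local maximum of
#' the potential between the crossings. Peaks closer together than
#' `merge_ms` are merged (refractory merging).
#'
#' @param sweep A current-clamp [new_sweep()].
#' @param ap_threshold_mV Detection threshold (mV); default -20.
#' @param merge_ms Minimum separation between spikes (ms).
#' @return A `spike_train` tibble with column `time_ms` (AP peak times
#'   relative to sweep start, strictly increasing).
#' @export
detect_action_potentials <- function(sweep, ap_threshold_mV = -20,
                                     merge_ms = 1) {
  if (sweep$mode != "current_clamp")
    abort("spike detection requires a current-clamp sweep.")
  v <- sweep$response
  above <- v > ap_threshold_mV
  up <- which(diff(above) == 1L) + 1L
  down <- which(diff(above) == -1L)
  times <- numeric(0)
  for (i in up) {
    j <- down[down >= i][1]
    if (is.na(j)) next # no downward crossing: spike not completed
    k <- i + which.max(v[i:j]) - 1L
    times <- c(times, sweep$t0 + (k - 1L) * sweep$dt)
  }
  if (length(times) > 1) {
    keep <- c(TRUE, diff(times) >= merge_ms)
    times <- times[keep]
  }
  structure(tibble(time_ms = times), class = c("spike_train", "tbl_df",
                                               "tbl", "data.frame"))
}

spike_times <- function(train) {
  if (is.data.frame(train)) train$time_ms else as.numeric(train)
}

#' Classify a spike train as a burst
#'
#' Implements the operational burst criterion: a burst is at least
#' `min_aps` action potentials within a sliding window of `span_ms`
#' (default: 3 APs within 100 ms) inside the search window. Candidate
#' windows are anchored at each spike; `n_aps` is the spike count of the
#' maximal qualifying window (earliest such window on ties).
#'
#' @param train A `spike_train` from [detect_action_potentials()] or a
#'   numeric vector of spike times (ms).
#' @param search_window Length-2 numeric `(t_start, t_end)` in ms; only
#'   spikes inside it are considered.
#' @param min_aps Minimum spikes per window (>= 2).
#' @param span_ms Window length (ms).
#' @return A one-row `burst_event` tibble: `is_burst`, `n_aps`,
#'   `window_start`, `window_end`, plus `NA` placeholders for the burst
#'   morphology fields filled by [rebound_burst_threshold()].
#' @examples
#' classify_burst(c(5, 40, 90), search_window = c(0, 300))$is_burst
#' @export
classify_burst <- function(train, search_window, min_aps = 3, span_ms = 100) {
  if (min_aps < 2) abort("`min_aps` must be >= 2.")
  if (span_ms <= 0) abort("`span_ms` must be > 0.")
  tt <- spike_times(train)
  tt <- sort(tt[tt >= search_window[1] & tt <= search_window[2]])
  counts <- vapply(tt, function(t0) sum(tt >= t0 & tt <= t0 + span_ms), 0L)
  qualifying <- counts >= min_aps
  if (length(tt) == 0 || !any(qualifying)) {
    return(burst_event(is_burst = FALSE, n_aps = length(tt)))
  }
  best <- which(counts == max(counts[qualifying]) & qualifying)[1]
  burst_event(is_burst = TRUE, n_aps = counts[best],
              window_start = tt[best], window_end = tt[best] + span_ms)
}

burst_event <- function(is_burst = FALSE, n_aps = 0L, window_start = NA_real_,
                        window_end = NA_real_) {
  tibble(is_burst = is_burst, n_aps = as.integer(n_aps),
         window_start = window_start, window_end = window_end,
         inflection_mV = NA_real_, deflection_mV = NA_real_,
         latency_to_inflection_ms = NA_real_, latency_to_ap_ms = NA_real_,
         latency_inflection_to_ap_ms = NA_real_,
         latency_to_deflection_ms = NA_real_,
         inflect_to_deflect_ms = NA_real_, ahp_mV = NA_real_)
}

#' Passive membrane properties from a hyperpolarizing step sweep
#'
#' Measured with the study's conventions: the resting membrane potential is
#' the mean over the last 50 ms before the step; the maximum
#' hyperpolarization is the minimum potential during the step; the pre-burst
#' membrane potential is the mean over the last 10 ms of the step; the sag
#' is `pre_burst - max_hyperpolarization`, positive for the depolarizing
#' relaxation produced by Ih (the sign is normalized to
#' depolarizing-positive regardless of age-group printing conventions).
#'
#' @param sweep A current-clamp sweep containing one step.
#' @return A one-row tibble: `rmp_mV`, `rin_MOhm` (`NA` here; see
#'   [input_resistance()]), `sag_mV`, `max_hyperpolarization_mV`,
#'   `pre_burst_potential_mV`.
#' @export
passive_properties <- function(sweep) {
  seg <- parse_step_command(sweep)
  t <- sweep_times(sweep)
  v <- sweep$response
  pre <- v[t >= seg$step_on - 50 & t < seg$step_on]
  rmp <- mean(pre)
  instep <- t >= seg$step_on & t < seg$step_off
  vmin <- min(v[instep])
  vpre <- mean(v[t >= seg$step_off - 10 & t < seg$step_off])
  tibble(rmp_mV = rmp, rin_MOhm = NA_real_, sag_mV = vpre - vmin,
         max_hyperpolarization_mV = vmin, pre_burst_potential_mV = vpre)
}

#' Input resistance from a hyperpolarizing step
#'
#' `R_in = |V_maxhyp - RMP| / |I| * 1000` (MOhm), using the maximum change
#' in membrane potential upon hyperpolarization during the step.
#'
#' @param sweep A current-clamp sweep with a hyperpolarizing step.
#' @param amplitude_pA Step amplitude; taken from the command if missing.
#' @return Input resistance in MOhm.
#' @examples
#' # a -10 mV deflection at -100 pA is 100 MOhm
#' @export
input_resistance <- function(sweep, amplitude_pA = NULL) {
  seg <- parse_step_command(sweep)
  if (is.null(amplitude_pA)) amplitude_pA <- seg$amplitude - seg$holding
  if (amplitude_pA == 0) abort("input resistance is undefined for a zero step.")
  pp <- passive_properties(sweep)
  abs(pp$max_hyperpolarization_mV - pp$rmp_mV) / abs(amplitude_pA) * 1000
}

#' Burst inflection and deflection points
#'
#' Surrogate for the chart-based measurement of where the membrane begins
#' to exponentially depolarize (inflection, before the first AP) and
#' repolarize (deflection, after the last AP). Spikes are clipped by linear
#' interpolation across +/- `clip_ms` of each AP peak and the trace smoothed
#' with a 1-ms boxcar. On the clipped trace the rebound dV/dt first decays
#' (passive charge redistribution), passes through a shallow valley, and
#' rises regeneratively into the low-threshold spike; the inflection point
#' is taken as the end of that valley (the last time dV/dt remains within
#' 10 percent of its minimum before the regenerative rise), validated by
#' requiring dV/dt to subsequently exceed the valley level by
#' `max(k_on * SD, min_slope)` for >= 2 ms, where SD is the dV/dt noise of
#' the quiet reference segment before the search window. The deflection
#' time is the first time after the last AP at which dV/dt falls below
#' `-max(k_off * SD, min_slope)` sustained for >= 2 ms.
#'
#' @param sweep The burst-carrying current-clamp sweep.
#' @param spikes Spike train from [detect_action_potentials()].
#' @param search_start Time (ms) from which to search (typically the step
#'   offset for rebound bursts); defaults to step offset.
#' @param k_on,k_off Threshold multipliers on the baseline dV/dt SD.
#' @param min_slope Floor on the dV/dt threshold (mV/ms), for noiseless
#'   traces.
#' @param clip_ms Half-width of the spike-clipping window (ms).
#' @return One-row tibble `inflection_mV`, `deflection_mV`,
#'   `inflection_time_ms`, `deflection_time_ms`, `found` (both points
#'   located). Missing points are flagged, not errors.
#' @export
burst_inflection_deflection <- function(sweep, spikes, search_start = NULL,
                                        k_on = 3, k_off = 3,
                                        min_slope = 0.05, clip_ms = 2) {
  t <- sweep_times(sweep)
  v <- sweep$response
  tt <- spike_times(spikes)
  if (is.null(search_start)) search_start <- parse_step_command(sweep)$step_off
  miss <- tibble(inflection_mV = NA_real_, deflection_mV = NA_real_,
                 inflection_time_ms = NA_real_, deflection_time_ms = NA_real_,
                 found = FALSE)
  tt <- tt[tt >= search_start]

  # clip spikes by linear interpolation
  vc <- v
  for (s in tt) {
    idx <- which(t >= s - clip_ms & t <= s + clip_ms)
    if (length(idx) >= 2) {
      i0 <- max(min(idx) - 1L, 1L); i1 <- min(max(idx) + 1L, length(v))
      vc[idx] <- approx(c(t[i0], t[i1]), c(v[i0], v[i1]), xout = t[idx])$y
    }
  }
  # 1-ms boxcar smoothing
  w <- max(1L, round(1 / sweep$dt))
  if (w > 1) {
    vc_s <- stats::filter(vc, rep(1 / w, w), sides = 2)
    vc_s[is.na(vc_s)] <- vc[is.na(vc_s)]
    vc <- as.numeric(vc_s)
  }
  # central difference over +/- 0.5 ms: per-sample differences of a noisy
  # trace are noise-dominated at these sampling rates
  k <- max(1L, round(0.5 / sweep$dt))
  n_v <- length(vc)
  dv <- rep(NA_real_, n_v)
  idx <- (k + 1L):(n_v - k)
  dv[idx] <- (vc[idx + k] - vc[idx - k]) / (2 * k * sweep$dt)

  ref <- which(t >= search_start - 50 & t < search_start)
  sd_ref <- sd(dv[ref], na.rm = TRUE)
  if (!is.finite(sd_ref)) sd_ref <- 0
  thr_on <- max(k_on * sd_ref, min_slope)
  need <- max(1L, round(2 / sweep$dt)) # sustained >= 2 ms

  sustained_from <- function(cond, from_idx) {
    cond[is.na(cond)] <- FALSE
    idx <- which(cond & seq_along(cond) >= from_idx)
    for (i in idx) {
      if (i + need - 1L <= length(cond) && all(cond[i:(i + need - 1L)]))
        return(i)
    }
    NA_integer_
  }

  search_i <- which(t >= search_start)[1]
  right_i <- if (length(tt)) {
    max(search_i + 1L, which(t >= tt[1] - clip_ms - 2)[1] - 1L)
  } else {
    # spikeless low-threshold event: bound the search by the peak
    rng <- search_i:length(v)
    rng[which.max(vc[rng])]
  }
  if (is.na(right_i) || right_i <= search_i + need) return(miss)
  valley <- search_i:right_i
  # the valley ends at the steepest point of the regenerative rise
  rise_peak <- valley[which.max(dv[valley])]
  if (rise_peak > search_i + 1L) valley <- search_i:rise_peak
  dv_min <- min(dv[valley], na.rm = TRUE)
  lev <- dv_min + 0.1 * abs(dv_min) + 0.01
  in_valley <- which(dv[valley] <= lev)
  if (length(in_valley) == 0) return(miss)
  i_on <- valley[max(in_valley)]
  # validation: a regenerative rise must follow
  rise <- sustained_from(dv > dv_min + thr_on, i_on)
  if (is.na(rise)) return(miss)

  i_off <- NA_integer_
  if (length(tt)) {
    last_ap_i <- which(t >= tt[length(tt)])[1]
    cond_off <- dv < -max(k_off * sd_ref, min_slope)
    i_off <- sustained_from(cond_off, last_ap_i + round((clip_ms + 2) / sweep$dt))
  } else {
    cond_off <- dv < -max(k_off * sd_ref, min_slope)
    i_off <- sustained_from(cond_off, right_i)
  }
  if (is.na(i_off)) return(miss)
  tibble(inflection_mV = vc[i_on], deflection_mV = vc[i_off],
         inflection_time_ms = t[i_on], deflection_time_ms = t[i_off],
         found = TRUE)
}

scan_threshold <- function(ladder, direction, min_aps, span_ms, search_ms,
                           ap_threshold_mV) {
  p <- ladder$protocol
  seg <- protocol_segments(p)
  amps <- p$amplitudes
  idx <- if (direction < 0) which(amps < 0) else which(amps > 0)
  if (length(idx) == 0)
    abort(sprintf("ladder contains no %s steps.",
                  if (direction < 0) "hyperpolarizing" else "depolarizing"))
  idx <- idx[order(abs(amps[idx]))]
  window <- if (direction < 0) c(seg$step_off, seg$step_off + search_ms)
            else c(seg$step_on, seg$step_off)
  for (i in idx) {
    spikes <- detect_action_potentials(ladder$sweeps[[i]], ap_threshold_mV)
    ev <- classify_burst(spikes, window, min_aps, span_ms)
    if (ev$is_burst)
      return(list(index = i, event = ev, spikes = spikes, window = window))
  }
  list(index = NA_integer_, event = NULL, spikes = NULL, window = window)
}

threshold_result <- function(ladder, hit, search_start) {
  p <- ladder$protocol
  if (is.na(hit$index)) {
    return(structure(list(threshold_pA = NA_real_,
                          threshold_sweep_index = NA_integer_,
                          burst = burst_event(FALSE, 0L),
                          passive = NULL, aps_per_burst = NA_integer_,
                          no_burst = TRUE),
                     class = "burst_threshold"))
  }
  sw <- ladder$sweeps[[hit$index]]
  ev <- hit$event
  tt <- spike_times(hit$spikes)
  tt_in <- tt[tt >= hit$window[1] & tt <= hit$window[2]]
  seg <- protocol_segments(p)
  morph <- burst_inflection_deflection(sw, hit$spikes,
                                       search_start = search_start)
  pass <- passive_properties(sw)
  pass$rin_MOhm <- if (p$amplitudes[hit$index] != 0)
    input_resistance(sw) else NA_real_
  # afterhyperpolarization: minimum V within 200 ms after the last burst AP
  t <- sweep_times(sw)
  last_ap <- max(tt_in)
  post <- t > last_ap + 2 & t <= last_ap + 200
  ev$ahp_mV <- if (any(post)) min(sw$response[post]) else NA_real_
  ev$inflection_mV <- morph$inflection_mV
  ev$deflection_mV <- morph$deflection_mV
  ev$latency_to_inflection_ms <- morph$inflection_time_ms - search_start
  ev$latency_to_ap_ms <- min(tt_in) - search_start
  ev$latency_inflection_to_ap_ms <- min(tt_in) - morph$inflection_time_ms
  ev$latency_to_deflection_ms <- morph$deflection_time_ms - search_start
  ev$inflect_to_deflect_ms <- morph$deflection_time_ms -
    morph$inflection_time_ms
  structure(list(threshold_pA = p$amplitudes[hit$index],
                 threshold_sweep_index = hit$index,
                 burst = ev, passive = pass,
                 # the complete burst event: all spikes in the search window
                 # (the criterion window of `burst` is 100 ms, but bursts
                 # routinely outlast it)
                 aps_per_burst = length(tt_in), no_burst = FALSE),
            class = "burst_threshold")
}

#' Rebound burst threshold over a step-protocol ladder
#'
#' Scans the hyperpolarizing amplitudes from smallest to largest magnitude
#' and returns the first whose post-release window (`[step offset,
#' step offset + search_ms]`) satisfies the burst criterion, together with
#' the passive properties and burst morphology of that threshold sweep. If
#' no sweep qualifies an explicit no-burst result is returned (a value, not
#' an error: saturating T-type block legitimately produces it).
#'
#' @param ladder An analyzed (response-filled) current-clamp ladder.
#' @param min_aps,span_ms Burst criterion (default 3 APs in 100 ms).
#' @param search_ms Rebound search window after step offset (default
#'   300 ms, enclosing the longest observed latencies to AP).
#' @param ap_threshold_mV Spike detection threshold.
#' @return A `burst_threshold` object: `threshold_pA`,
#'   `threshold_sweep_index`, `burst` (a `burst_event` row), `passive`,
#'   `aps_per_burst`, `no_burst`.
#' @export
rebound_burst_threshold <- function(ladder, min_aps = 3, span_ms = 100,
                                    search_ms = 300, ap_threshold_mV = -20) {
  hit <- scan_threshold(ladder, -1, min_aps, span_ms, search_ms,
                        ap_threshold_mV)
  threshold_result(ladder, hit, protocol_segments(ladder$protocol)$step_off)
}

#' Depolarizing burst threshold
#'
#' Mirror of [rebound_burst_threshold()] for depolarizing steps: the burst
#' window lies inside the step (`[step onset, step offset]`). Used for the
#' Ih-blocked condition in which neurons require depolarizing rather than
#' hyperpolarizing current to burst.
#'
#' @inheritParams rebound_burst_threshold
#' @return A `burst_threshold` object.
#' @export
depolarizing_burst_threshold <- function(ladder, min_aps = 3, span_ms = 100,
                                         search_ms = 300,
                                         ap_threshold_mV = -20) {
  hit <- scan_threshold(ladder, +1, min_aps, span_ms, search_ms,
                        ap_threshold_mV)
  threshold_result(ladder, hit, protocol_segments(ladder$protocol)$step_on)
}

#' @export
print.burst_threshold <- function(x, ...) {
  if (x$no_burst) {
    cat("<burst_threshold> no burst over the full ladder\n")
  } else {
    cat(sprintf("<burst_threshold> %g pA (sweep %d), %d APs/burst\n",
                x$threshold_pA, x$threshold_sweep_index, x$aps_per_burst))
  }
  invisible(x)
}

#' Collect a threshold result into a one-row tibble
#' @param x A `burst_threshold` object.
#' @param ... Unused.
#' @return One-row tibble of threshold, burst morphology and passive
#'   properties.
#' @export
tidy.burst_threshold <- function(x, ...) {
  base <- tibble(threshold_pA = x$threshold_pA,
                 sweep_index = x$threshold_sweep_index,
                 no_burst = x$no_burst, aps_per_burst = x$aps_per_burst)
  if (!is.null(x$passive)) base <- dplyr::bind_cols(base, x$passive)
  dplyr::bind_cols(base, x$burst[, c("inflection_mV", "deflection_mV",
                                     "latency_to_inflection_ms",
                                     "latency_to_ap_ms",
                                     "latency_inflection_to_ap_ms",
                                     "latency_to_deflection_ms",
                                     "inflect_to_deflect_ms", "ahp_mV")])
}

#' Tonic firing frequency of a depolarizing step sweep
#'
#' Spike count between 500 and 1,000 ms after step onset divided by 0.5 s,
#' the convention that excludes any burst contribution at step onset.
#'
#' @param sweep A current-clamp sweep with a depolarizing step of at least
#'   1,000 ms.
#' @param ap_threshold_mV Spike detection threshold.
#' @return Firing rate in Hz.
#' @export
tonic_firing_frequency <- function(sweep, ap_threshold_mV = -20) {
  seg <- parse_step_command(sweep)
  if (is.na(seg$step_on) || seg$step_off - seg$step_on < 1000)
    abort("tonic frequency requires a step of at least 1,000 ms.")
  tt <- spike_times(detect_action_potentials(sweep, ap_threshold_mV))
  sum(tt >= seg$step_on + 500 & tt < seg$step_on + 1000) / 0.5
}

#' Input-output curve over a ladder
#'
#' Per-amplitude firing measure: for hyperpolarizing steps the rebound
#' spike count in the post-release window expressed as a frequency; for
#' depolarizing steps the in-step spike frequency. Optionally the
#' amplitude axis is re-expressed relative to the rebound threshold
#' (threshold maps to 0).
#'
#' @param ladder Analyzed current-clamp ladder.
#' @param normalize If `TRUE`, add `norm_amplitude_pA` relative to the
#'   rebound threshold.
#' @param search_ms Rebound window (ms).
#' @param ap_threshold_mV Spike detection threshold.
#' @return A tibble: `amplitude_pA`, `n_spikes`, `freq_hz`, `is_burst`,
#'   and optionally `norm_amplitude_pA`.
#' @export
input_output_curve <- function(ladder, normalize = FALSE, search_ms = 300,
                               ap_threshold_mV = -20) {
  p <- ladder$protocol
  seg <- protocol_segments(p)
  rows <- purrr::imap(ladder$sweeps, function(sw, i) {
    a <- p$amplitudes[i]
    spikes <- detect_action_potentials(sw, ap_threshold_mV)
    window <- if (a < 0) c(seg$step_off, seg$step_off + search_ms)
              else c(seg$step_on, seg$step_off)
    tt <- spike_times(spikes)
    n <- sum(tt >= window[1] & tt <= window[2])
    ev <- classify_burst(spikes, window)
    tibble(amplitude_pA = a, n_spikes = n,
           freq_hz = n / (diff(window) / 1000), is_burst = ev$is_burst)
  }) %>% list_rbind()
  if (normalize) {
    thr <- rebound_burst_threshold(ladder, search_ms = search_ms,
                                   ap_threshold_mV = ap_threshold_mV)
    rows$norm_amplitude_pA <- rows$amplitude_pA -
      (if (thr$no_burst) NA_real_ else thr$threshold_pA)
  }
  rows
}
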