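# Shared fixtures. Expensive simulations are computed once per test run and
# cached in this environment.
.fix <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fix)) assign(name, force(expr), envir = .fix)
  get(name, envir = .fix)
}

cc_quiet <- function() clamp_config("current_clamp", noise_sd = 0)
vc_quiet <- function() clamp_config("voltage_clamp", noise_sd = 0)

passive_cell <- function(g_leak = 5, Cm = 67, E_leak = -80) {
  neuron_params(Cm = Cm, g_leak = g_leak, E_leak = E_leak,
                g_T = 0, g_h = 0, g_HVA = 0, g_Na = 0, g_K = 0)
}

nec_lad1000 <- function() fixture("nec_lad1000", {
  simulate_ladder(preset("NEC"), protocol_template("cc1000", dt = 0.05),
                  cc_quiet())
})

nec_thr <- function() fixture("nec_thr", rebound_burst_threshold(nec_lad1000()))

# a synthetic current-clamp sweep with gaussian spikes at given times
synthetic_spike_sweep <- function(spike_times_ms, dur_ms = 400, dt = 0.05,
                                  base_mV = -78, peak_mV = 30,
                                  width_ms = 0.6) {
  t <- seq(0, dur_ms - dt, by = dt)
  v <- rep(base_mV, length(t))
  for (s in spike_times_ms)
    v <- v + (peak_mV - base_mV) * exp(-((t - s) / width_ms)^2)
  new_sweep(dt, command = rep(0, length(t)), response = v)
}

# exhaustive pairwise burst search: the independent oracle for classify_burst
oracle_burst <- function(times, window, min_aps = 3, span_ms = 100) {
  tt <- sort(times[times >= window[1] & times <= window[2]])
  n <- length(tt)
  best <- 0L
  if (n) {
    for (i in seq_len(n)) {
      j <- max(which(tt - tt[i] <= span_ms & tt >= tt[i]))
      best <- max(best, j - i + 1L)
    }
  }
  list(is_burst = best >= min_aps, n_aps = best)
}

# per-sweep brute-force rebound threshold: the oracle for the scan
oracle_rebound_threshold <- function(ladder, min_aps = 3, span_ms = 100,
                                     search_ms = 300) {
  seg <- protocol_segments(ladder$protocol)
  amps <- ladder$protocol$amplitudes
  burst <- vapply(seq_along(ladder$sweeps), function(i) {
    tt <- detect_action_potentials(ladder$sweeps[[i]])$time_ms
    oracle_burst(tt, c(seg$step_off, seg$step_off + search_ms),
                 min_aps, span_ms)$is_burst
  }, TRUE)
  hyp <- which(amps < 0 & burst)
  if (!length(hyp)) NA_real_ else amps[hyp[which.min(abs(amps[hyp]))]]
}
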