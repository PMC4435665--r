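test_that("spike detection finds inserted spikes and ignores quiet traces", {
  quiet <- new_sweep(0.05, rep(0, 4000), rep(-78, 4000))
  expect_identical(nrow(detect_action_potentials(quiet)), 0L)

  truth <- c(10, 30, 60, 300)
  sw <- synthetic_spike_sweep(truth)
  got <- detect_action_potentials(sw)$time_ms
  expect_length(got, 4)
  expect_lt(max(abs(got - truth)), 0.1)
})

test_that("spike detection matches brute-force peak enumeration on a model sweep", {
  thr <- nec_thr()
  sw <- nec_lad1000()$sweeps[[thr$threshold_sweep_index]]
  got <- detect_action_potentials(sw, -20)$time_ms
  # oracle: local maxima above threshold, separated by >= 1 ms
  v <- sw$response
  is_peak <- c(FALSE, diff(sign(diff(v))) == -2, FALSE) & v > -20
  pk <- sweep_times(sw)[is_peak]
  pk <- pk[c(TRUE, diff(pk) >= 1)]
  expect_identical(length(got), length(pk))
  expect_lt(max(abs(got - pk)), 0.2)
})

test_that("burst classification applies the 3-APs-in-100-ms criterion literally", {
  w <- c(0, 400)
  expect_true(classify_burst(c(5, 40, 90), w)$is_burst)
  expect_identical(classify_burst(c(5, 40, 90), w)$n_aps, 3L)
  expect_false(classify_burst(c(5, 150), w)$is_burst)
  ev <- classify_burst(c(5, 40, 90, 210, 230, 260), w)
  expect_true(ev$is_burst)
  expect_identical(ev$n_aps, 3L)
  expect_identical(ev$window_start, 5)
  expect_error(classify_burst(c(5, 40), w, min_aps = 1), ">= 2")
})

test_that("burst classification equals the exhaustive pairwise search on random trains", {
  set.seed(101)
  for (i in 1:100) {
    n <- sample(0:12, 1)
    tt <- sort(runif(n, 0, 500))
    got <- classify_burst(tt, c(0, 500))
    ora <- oracle_burst(tt, c(0, 500))
    expect_identical(got$is_burst, ora$is_burst)
    if (got$is_burst) expect_identical(as.integer(got$n_aps), ora$n_aps)
  }
})

test_that("rebound threshold scan returns the first bursting amplitude", {
  # constructed ladder: flat traces, spikes inserted post-offset only at -50
  proto <- make_step_protocol(0, 100, 200, 300, -110, -10, 10, dt = 0.1)
  sweeps <- lapply(seq_along(proto$protocol$amplitudes), function(i) {
    a <- proto$protocol$amplitudes[i]
    sw <- proto$sweeps[[i]]
    spikes <- if (a == -50) c(320, 340, 360) else numeric(0)
    out <- synthetic_spike_sweep(spikes, dur_ms = 600, dt = 0.1)
    out$command <- sw$command
    out
  })
  lad <- structure(list(protocol = proto$protocol, sweeps = sweeps),
                   class = "ladder")
  res <- rebound_burst_threshold(lad)
  expect_identical(res$threshold_pA, -50)
  expect_identical(res$aps_per_burst, 3L)
  # bisection property: every smaller-magnitude amplitude is non-burst
  seg <- protocol_segments(proto$protocol)
  smaller <- which(proto$protocol$amplitudes < 0 &
                     abs(proto$protocol$amplitudes) < 50)
  for (i in smaller) {
    sp <- detect_action_potentials(lad$sweeps[[i]])
    expect_false(classify_burst(sp, c(seg$step_off,
                                      seg$step_off + 300))$is_burst)
  }
})

test_that("threshold scan equals per-sweep brute force on the model and flags no-burst", {
  expect_identical(nec_thr()$threshold_pA,
                   oracle_rebound_threshold(nec_lad1000()))
  lad <- simulate_ladder(modify_params(preset("NEC"), block_T = 1),
                         make_step_protocol(0, 200, 1000, 400, -110, -10, 10,
                                            dt = 0.1),
                         cc_quiet())
  res <- rebound_burst_threshold(lad)
  expect_true(res$no_burst)
  expect_true(is.na(res$threshold_pA))
  expect_error(rebound_burst_threshold(
    make_step_protocol(0, 10, 20, 10, 10, 50, 10, dt = 0.5)),
    "hyperpolarizing")
})

test_that("depolarizing variant mirrors the scan inside the step", {
  # tonic-like regular spiking (60-ms intervals) never satisfies the criterion
  proto <- make_step_protocol(0, 100, 1000, 100, 10, 100, 10, dt = 0.1)
  sweeps <- lapply(seq_along(proto$protocol$amplitudes), function(i) {
    out <- synthetic_spike_sweep(seq(150, 1050, by = 60), dur_ms = 1200,
                                 dt = 0.1)
    out$command <- proto$sweeps[[i]]$command
    out
  })
  lad <- structure(list(protocol = proto$protocol, sweeps = sweeps),
                   class = "ladder")
  expect_true(depolarizing_burst_threshold(lad)$no_burst)

  # and a 20-ms-interval cluster qualifies at the first amplitude carrying it
  sweeps[[3]]$response <- synthetic_spike_sweep(c(200, 220, 240),
                                                dur_ms = 1200,
                                                dt = 0.1)$response
  lad2 <- structure(list(protocol = proto$protocol, sweeps = sweeps),
                    class = "ladder")
  expect_identical(depolarizing_burst_threshold(lad2)$threshold_pA, 30)
})

test_that("input resistance follows Ohm's law and the strain direction", {
  proto <- make_step_protocol(0, 100, 500, 100, -100, -100, 10, dt = 0.1)
  sw <- proto$sweeps[[1]]
  sw$response <- ifelse(sw$command == -100, -88, -78)
  expect_equal(input_resistance(sw), 100)
  expect_error(input_resistance(sw, amplitude_pA = 0), "zero step")

  i100 <- which(nec_lad1000()$protocol$amplitudes == -100)
  rin_nec <- input_resistance(nec_lad1000()$sweeps[[i100]])
  gaers <- fixture("gaers_lad1000", {
    simulate_ladder(preset("GAERS"), protocol_template("cc1000", dt = 0.05),
                    cc_quiet())
  })
  expect_lt(input_resistance(gaers$sweeps[[i100]]), rin_nec)
})

test_that("passive properties report rest, trough, pre-burst level and sag", {
  p <- passive_cell(g_leak = 5, Cm = 67, E_leak = -78)
  proto <- make_step_protocol(0, 200, 1000, 100, -100, -100, 10, dt = 0.05)
  lad <- simulate_ladder(p, proto, cc_quiet())
  pp <- passive_properties(lad$sweeps[[1]])
  expect_equal(pp$rmp_mV, -78, tolerance = 1e-6)
  expect_lt(abs(pp$sag_mV), 0.3) # no sag conductance
  expect_lt(pp$max_hyperpolarization_mV, pp$rmp_mV)

  sags <- vapply(c(0, 3.5, 7), function(gh) {
    pl <- simulate_ladder(modify_params(preset("NEC"), g_h = gh), proto,
                          cc_quiet())
    passive_properties(pl$sweeps[[1]])$sag_mV
  }, 0)
  expect_false(is.unsorted(sags))
  expect_gt(sags[3], 1)

  rest <- unname(resting_state(preset("NEC"))["V"])
  nl <- simulate_ladder(preset("NEC"), proto, cc_quiet())
  expect_equal(passive_properties(nl$sweeps[[1]])$rmp_mV, rest,
               tolerance = 0.5)
})

test_that("inflection detector locates a constructed low-threshold event onset", {
  tt <- seq(0, 500, 0.05)
  v <- rep(-78, length(tt))
  on <- tt >= 200 & tt < 260
  v[on] <- -78 + 15 * (1 - exp(-(tt[on] - 200) / 8))
  off <- tt >= 260
  v[off] <- -78 + (15 * (1 - exp(-60 / 8))) * exp(-(tt[off] - 260) / 15)
  sw <- new_sweep(0.05, command = rep(0, length(tt)), response = v)
  m <- burst_inflection_deflection(sw, tibble::tibble(time_ms = numeric(0)),
                                   search_start = 100)
  expect_true(m$found)
  expect_lt(abs(m$inflection_time_ms - 200), 2)

  flat <- new_sweep(0.05, rep(0, 4000), rep(-78, 4000))
  m2 <- burst_inflection_deflection(flat,
                                    tibble::tibble(time_ms = numeric(0)),
                                    search_start = 100)
  expect_false(m2$found) # flagged missing, not an error
})

test_that("threshold-sweep inflection potential falls in the expected band", {
  thr <- nec_thr()
  expect_gt(thr$burst$inflection_mV, -75)
  expect_lt(thr$burst$inflection_mV, -65)
  expect_gt(thr$burst$latency_inflection_to_ap_ms, 0)
})

test_that("tonic firing frequency counts the late half of the step", {
  sw <- synthetic_spike_sweep(seq(620, 1070, by = 50), dur_ms = 1400,
                              dt = 0.1)
  sw$command <- c(rep(0, 1000), rep(80, 11000), rep(0, 2000))
  expect_equal(tonic_firing_frequency(sw), 10 / 0.5)
  quiet <- sw; quiet$response <- rep(-78, length(sw$response))
  expect_equal(tonic_firing_frequency(quiet), 0)
  short <- synthetic_spike_sweep(numeric(0), dur_ms = 500, dt = 0.1)
  short$command[1000:2000] <- 80
  expect_error(tonic_firing_frequency(short), "1,000 ms")
})

test_that("simulated frequency-current curve is non-decreasing for tonic firing", {
  lad <- nec_lad1000()
  dep <- which(lad$protocol$amplitudes >= 10)
  fi <- vapply(dep, function(i) tonic_firing_frequency(lad$sweeps[[i]]), 0)
  expect_false(is.unsorted(fi))
})

test_that("input-output curve matches per-sweep recomputation and normalizes at threshold", {
  lad <- nec_lad1000()
  io <- input_output_curve(lad, normalize = TRUE)
  expect_identical(nrow(io), 32L)
  thr <- nec_thr()
  expect_equal(io$norm_amplitude_pA[io$amplitude_pA == thr$threshold_pA], 0)
  seg <- protocol_segments(lad$protocol)
  for (i in c(3, 7, 20, 30)) {
    tt <- detect_action_potentials(lad$sweeps[[i]])$time_ms
    a <- lad$protocol$amplitudes[i]
    w <- if (a < 0) c(seg$step_off, seg$step_off + 300)
         else c(seg$step_on, seg$step_off)
    expect_identical(io$n_spikes[i], sum(tt >= w[1] & tt <= w[2]))
  }
})

test_that("burst classification is invariant to sub-threshold recording noise", {
  thr <- nec_thr()
  sw <- nec_lad1000()$sweeps[[thr$threshold_sweep_index]]
  seg <- protocol_segments(nec_lad1000()$protocol)
  set.seed(7)
  for (r in 1:5) {
    noisy <- sw
    noisy$response <- sw$response + rnorm(length(sw$response), 0, 0.2)
    ev <- classify_burst(detect_action_potentials(noisy),
                         c(seg$step_off, seg$step_off + 300))
    expect_true(ev$is_burst)
    expect_identical(ev$n_aps, thr$burst$n_aps)
  }
})
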