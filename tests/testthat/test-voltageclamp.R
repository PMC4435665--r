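test_that("capacitance integral handles a rectangular surrogate transient", {
  proto <- make_step_protocol(-90, 20, 40, 20, -85, -85, 5, dt = 0.05,
                              mode = "voltage_clamp")
  sw <- proto$sweeps[[1]]
  resp <- rep(0, length(sw$command))
  t <- sweep_times(sw)
  resp[t >= 20 & t < 30] <- 25 # 25 pA for 10 ms = 250 pA*ms
  sw$response <- resp
  expect_equal(whole_cell_capacitance(sw), 250 / 5, tolerance = 0.005)
  flat <- sw; flat$command <- rep(-90, length(sw$command))
  expect_error(whole_cell_capacitance(flat), "no voltage step")
})

test_that("capacitance estimate is robust to series resistance and leak", {
  p <- passive_cell(g_leak = 5, Cm = 67)
  est <- function(clamp) {
    lad <- simulate_ladder(p, protocol_template("cmstep"), clamp)
    whole_cell_capacitance(lad$sweeps[[1]])
  }
  base <- est(vc_quiet())
  expect_equal(base, 67, tolerance = 0.02)
  # doubling the pipette resistance at the standard 70% compensation
  doubled <- est(clamp_config("voltage_clamp", R_series = 10, noise_sd = 0))
  expect_lt(abs(doubled - base) / base, 0.05)
  # leak independence, assessed at high compensation
  hi <- function(gl) {
    lad <- simulate_ladder(passive_cell(g_leak = gl, Cm = 67),
                           protocol_template("cmstep"),
                           clamp_config("voltage_clamp",
                                        rs_compensation = 0.9, noise_sd = 0))
    whole_cell_capacitance(lad$sweeps[[1]])
  }
  ests <- vapply(c(1, 3, 10), hi, 0)
  expect_lt((max(ests) - min(ests)) / mean(ests), 0.02)
})

test_that("leak correction cancels an ohmic cell and is idempotent", {
  p <- passive_cell(g_leak = 4, Cm = 30, E_leak = -70)
  iv <- simulate_ladder(p, protocol_template("cavIV", dt = 0.05), vc_quiet())
  cal <- simulate_ladder(p, protocol_template("leakcal", dt = 0.05),
                         vc_quiet())
  corr <- leak_correct(iv, calib = cal)
  seg <- protocol_segments(iv$protocol)
  # away from the capacitive edges the corrected current is ~0
  for (i in c(1, 9, 17)) {
    sw <- corr$sweeps[[i]]
    t <- sweep_times(sw)
    inner <- t >= seg$step_on + 5 & t < seg$step_off
    expect_lt(max(abs(sw$response[inner])), 1)
  }
  twice <- leak_correct(corr, calib = leak_correct(cal, calib = cal))
  expect_equal(twice$sweeps[[9]]$response, corr$sweeps[[9]]$response,
               tolerance = 1e-6)
  expect_error(leak_correct(iv, calib = iv), ">= 2 calibration steps")
})

test_that("leak-corrected T current matches the leak-free simulation", {
  p <- modify_params(preset("P7P9_NEC"), g_HVA = 0)
  iv <- simulate_ladder(p, protocol_template("cavIV", dt = 0.05), vc_quiet())
  cal <- simulate_ladder(p, protocol_template("leakcal", dt = 0.05),
                         vc_quiet())
  corr <- leak_correct(iv, calib = cal)
  pure <- simulate_ladder(modify_params(p, g_leak = 1e-9),
                          protocol_template("cavIV", dt = 0.05),
                          clamp_config("voltage_clamp", noise_sd = 0))
  cm <- p$Cm
  iv_corr <- build_iv(corr, cm)
  iv_pure <- build_iv(pure, cm)
  i <- which.min(iv_corr$peak_pA)
  expect_equal(iv_corr$peak_pA[i], iv_pure$peak_pA[i], tolerance = 0.03)
})

test_that("I-V construction spans the protocol and equals brute-force peak picking", {
  p <- preset("P7P9_NEC")
  iv <- fixture("p7p9_iv", {
    lad <- simulate_ladder(p, protocol_template("cavIV", dt = 0.05),
                           vc_quiet())
    cal <- simulate_ladder(p, protocol_template("leakcal", dt = 0.05),
                           vc_quiet())
    leak_correct(lad, calib = cal)
  })
  curve <- build_iv(iv, p$Cm)
  expect_identical(nrow(curve), 17L)
  expect_identical(curve$voltage_mV, seq(-70, 10, by = 5))
  expect_equal(curve$density_pA_per_pF, curve$peak_pA / p$Cm)
  seg <- protocol_segments(iv$protocol)
  for (i in c(1, 8, 17)) {
    sw <- iv$sweeps[[i]]
    t <- sweep_times(sw)
    w <- t >= seg$step_on + 1 & t < seg$step_off
    expect_identical(curve$peak_pA[i], min(sw$response[w]))
  }
  expect_error(build_iv(iv), "capacitance")

  zero <- passive_cell(g_leak = 3, Cm = 25)
  zl <- leak_correct(
    simulate_ladder(zero, protocol_template("cavIV", dt = 0.1), vc_quiet()),
    calib = simulate_ladder(zero, protocol_template("leakcal", dt = 0.1),
                            vc_quiet()))
  zc <- build_iv(zl, 25, blank_ms = 5)
  expect_lt(max(abs(zc$peak_pA)), 2)
})

test_that("pre-pulse subtraction separates T-type from HVA components", {
  p <- preset("P7P9_NEC")
  tot <- fixture("p7p9_iv", {
    lad <- simulate_ladder(p, protocol_template("cavIV", dt = 0.05),
                           vc_quiet())
    cal <- simulate_ladder(p, protocol_template("leakcal", dt = 0.05),
                           vc_quiet())
    leak_correct(lad, calib = cal)
  })
  pre <- fixture("p7p9_pre", {
    lad <- simulate_ladder(p, protocol_template("cavIV_prepulse", dt = 0.05),
                           vc_quiet())
    cal <- simulate_ladder(p, protocol_template("leakcal", dt = 0.05),
                           vc_quiet())
    leak_correct(lad, calib = cal)
  })
  sep <- isolate_t_type(tot, pre, p$Cm)
  # identical inputs give a null T component
  null <- isolate_t_type(pre, pre, p$Cm)
  expect_lt(max(abs(null$t_type$peak_pA)), 1e-9)
  # T peaks at a more negative potential than HVA
  vt <- sep$t_type$voltage_mV[which.min(sep$t_type$peak_pA)]
  vh <- sep$hva$voltage_mV[which.min(sep$hva$peak_pA)]
  expect_lt(vt, vh)
  # channel-off oracle: isolated T matches a direct HVA-free simulation
  pure_t <- fixture("p7p9_pure_t", {
    q <- modify_params(p, g_HVA = 0)
    lad <- simulate_ladder(q, protocol_template("cavIV", dt = 0.05),
                           vc_quiet())
    cal <- simulate_ladder(q, protocol_template("leakcal", dt = 0.05),
                           vc_quiet())
    build_iv(leak_correct(lad, calib = cal), p$Cm)
  })
  i <- which.min(pure_t$peak_pA)
  expect_equal(sep$t_type$density_pA_per_pF[i], pure_t$density_pA_per_pF[i],
               tolerance = 0.05)
  # subtraction commutes with scalar scaling of inputs
  sc <- function(lad, k) {
    lad$sweeps <- lapply(lad$sweeps, function(s) {
      s$response <- k * s$response; s
    })
    lad
  }
  sep2 <- isolate_t_type(sc(tot, 2), sc(pre, 2), p$Cm)
  expect_equal(sep2$t_type$peak_pA, 2 * sep$t_type$peak_pA, tolerance = 1e-9)
})

test_that("blocker subtraction isolates Ih and behaves like a difference of noises", {
  p <- preset("NEC")
  tpl <- make_step_protocol(-60, 100, 600, 50, -110, -80, 15, dt = 0.1,
                            mode = "voltage_clamp", tail_mV = -110,
                            tail_ms = 150)
  ctrl <- simulate_ladder(p, tpl, vc_quiet())
  expect_lt(max(abs(unlist(lapply(
    zd_sensitive_current(ctrl, ctrl)$sweeps, `[[`, "response")))), 1e-12)

  blocked <- simulate_ladder(modify_params(p, block_h = 1), tpl, vc_quiet())
  diff_lad <- zd_sensitive_current(ctrl, blocked)
  pure <- simulate_ladder(modify_params(p, g_leak = 1e-9, g_T = 0,
                                        g_HVA = 0, g_Na = 0, g_K = 0),
                          tpl, vc_quiet())
  i <- 1 # deepest pre-pulse
  seg <- protocol_segments(tpl$protocol)
  t <- sweep_times(diff_lad$sweeps[[i]])
  w <- t >= seg$step_on + 50 & t < seg$step_off
  pk_diff <- min(diff_lad$sweeps[[i]]$response[w])
  pk_pure <- min(pure$sweeps[[i]]$response[w])
  expect_equal(pk_diff, pk_pure, tolerance = 0.02)

  # variance of a subtraction of independent noisy sweeps adds
  noisy <- clamp_config("voltage_clamp", noise_sd = 2, seed = 1L)
  noisy2 <- clamp_config("voltage_clamp", noise_sd = 2, seed = 2L)
  a <- simulate_ladder(passive_cell(), tpl, noisy)
  b <- simulate_ladder(passive_cell(), tpl, noisy2)
  d <- zd_sensitive_current(a, b)
  base <- sweep_times(d$sweeps[[1]]) < 100
  expect_equal(var(d$sweeps[[1]]$response[base]), 8, tolerance = 0.3)
})

test_that("tail-current activation recovers the activation curve of a known gate", {
  # a gate with a voltage-independent time constant equilibrates in the
  # 1,000-ms pre-pulse yet barely relaxes in the measurement window
  p <- modify_params(preset("NEC"), g_T = 0, g_HVA = 0, g_Na = 0, g_K = 0,
                     h_act = gate_kinetics(-86, 4.2, "constant",
                                           tau_ms = 100))
  tpl <- protocol_template("ihtail", dt = 0.05)
  ctrl <- simulate_ladder(p, tpl, vc_quiet())
  blocked <- simulate_ladder(modify_params(p, block_h = 1), tpl, vc_quiet())
  act <- tail_current_activation(zd_sensitive_current(ctrl, blocked))
  expect_identical(act$normalized[which.min(act$prepulse_mV)], 1)
  rinf <- gate_inf(p$h_act, act$prepulse_mV)
  rinf <- rinf / rinf[which.min(act$prepulse_mV)]
  expect_lt(max(abs(act$normalized - rinf)), 0.05)
  expect_false(is.unsorted(rev(act$normalized))) # monotone non-increasing
  expect_error(tail_current_activation(
    protocol_template("cavIV", dt = 0.5)), "tail")
})

test_that("Ih tail density is larger for the epileptic-strain preset", {
  dens <- function(p) {
    tpl <- protocol_template("ihtail", dt = 0.1)
    ctrl <- simulate_ladder(p, tpl, vc_quiet())
    blocked <- simulate_ladder(modify_params(p, block_h = 1), tpl,
                               vc_quiet())
    act <- tail_current_activation(zd_sensitive_current(ctrl, blocked))
    abs(act$tail_peak_pA[which.min(act$prepulse_mV)]) / p$Cm
  }
  expect_gt(dens(preset("GAERS")), dens(preset("NEC")))
})

test_that("Boltzmann fitting recovers exact parameters and beats the grid oracle", {
  v <- seq(-110, -60, by = 5)
  curve <- tibble::tibble(prepulse_mV = v,
                          normalized = 1 / (1 + exp((v + 86.2) / 4.2)))
  fit <- fit_boltzmann(curve)
  expect_equal(fit$v50_mV, -86.2, tolerance = 1e-4)
  expect_equal(fit$slope_mV, 4.2, tolerance = 1e-4)

  set.seed(5)
  noisy <- curve
  noisy$normalized <- noisy$normalized + rnorm(length(v), 0, 0.03)
  fit2 <- fit_boltzmann(noisy)
  # no point of a coarse 2-D lattice does better than the converged fit
  lattice <- expand.grid(v50 = seq(-110, -60, by = 1),
                         k = seq(0.5, 12, by = 0.25))
  rss <- vapply(seq_len(nrow(lattice)), function(i) {
    sum((noisy$normalized -
           1 / (1 + exp((v - lattice$v50[i]) / lattice$k[i])))^2)
  }, 0)
  expect_lte(fit2$rss, min(rss) + 1e-9)
  expect_error(fit_boltzmann(curve[1:3, ]), ">= 4")
})

test_that("Hill fitting recovers the dose-response parameters", {
  conc <- c(0.5, 1, 2, 4, 8, 16, 64)
  dr <- tibble::tibble(concentration_nM = conc,
                       fraction_blocked = conc / (conc + 3.8))
  fit <- fit_hill_ec50(dr)
  expect_equal(fit$ec50_nM, 3.8, tolerance = 1e-3)
  expect_equal(fit$hill_n, 1, tolerance = 1e-3)

  set.seed(9)
  noisy <- dr
  noisy$fraction_blocked <- pmin(1, pmax(0,
    dr$fraction_blocked * (1 + rnorm(length(conc), 0, 0.03))))
  fit2 <- fit_hill_ec50(noisy)
  lattice <- expand.grid(ec = exp(seq(log(0.2), log(100), length.out = 150)),
                         n = seq(0.4, 3, by = 0.1))
  rss <- vapply(seq_len(nrow(lattice)), function(i) {
    sum((noisy$fraction_blocked - conc^lattice$n[i] /
           (conc^lattice$n[i] + lattice$ec[i]^lattice$n[i]))^2)
  }, 0)
  expect_lte(fit2$rss, min(rss) + 1e-9)

  expect_error(fit_hill_ec50(tibble::tibble(
    concentration_nM = conc, fraction_blocked = rep(1, 7))), "degenerate")
})
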