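#' Gating-variable kinetics
#'
#' Steady-state activation follows a Boltzmann,
#' `x_inf(V) = 1/(1 + exp((V - v_half)/slope))`; a negative `slope` gives a
#' depolarization-activated gate, a positive one a gate activated by
#' hyperpolarization (HCN) or an inactivation gate. The voltage-dependent
#' time constant is a named functional form:
#' `"biexp_recip"` (`tau = 1/(exp(-(V-vL)/kL) + exp((V-vR)/kR))`, the
#' standard thalamocortical T-activation and HCN forms), `"t_inact_tc"`
#' (the piecewise-exponential T-inactivation form with its hundreds-of-ms
#' recovery near -90 mV), or `"constant"`. `tau_scale` multiplies the form.
#'
#' @param v_half Half-activation voltage (mV).
#' @param slope Slope factor (mV), nonzero; sign encodes direction.
#' @param tau_form One of `"t_act_tc"`, `"t_inact_tc"`, `"hcn_tc"`,
#'   `"constant"`.
#' @param tau_scale Dimensionless multiplier on the time-constant form.
#' @param tau_ms Time constant for `tau_form = "constant"`.
#' @return A `gate_kinetics` object.
#' @export
gate_kinetics <- function(v_half, slope,
                          tau_form = c("t_act_tc", "t_inact_tc", "hcn_tc",
                                       "constant"),
                          tau_scale = 1, tau_ms = 1.5) {
  tau_form <- match.arg(tau_form)
  if (slope == 0) abort("`slope` must be nonzero.")
  gk <- structure(list(v_half = v_half, slope = slope, tau_form = tau_form,
                       tau_scale = tau_scale, tau_ms = tau_ms),
                  class = "gate_kinetics")
  v <- seq(-120, 40, by = 1)
  if (any(gate_tau(gk, v) <= 0))
    abort("time-constant form is not positive on [-120, 40] mV.")
  gk
}

#' Steady state and time constant of a gate
#' @param gk A [gate_kinetics()] object.
#' @param v Membrane potential(s), mV.
#' @return Numeric vector.
#' @export
gate_inf <- function(gk, v) 1 / (1 + exp((v - gk$v_half) / gk$slope))

#' @rdname gate_inf
#' @export
gate_tau <- function(gk, v) {
  base <- switch(gk$tau_form,
    t_act_tc = 0.612 + 1 / (exp(-(v + 132) / 16.7) + exp((v + 16.8) / 18.2)),
    t_inact_tc = ifelse(v < -80, exp((v + 467) / 66.6),
                        28 + exp(-(v + 22) / 10.5)),
    hcn_tc = pmax(1, 1 / (exp(-14.59 - 0.086 * v) + exp(8.6 + 0.2 * v))),
    constant = rep(gk$tau_ms, length(v)))
  base * gk$tau_scale
}

#' Parameters of the single-compartment VB neuron model
#'
#' The model integrates `Cm dV/dt = -(I_T + I_h + I_HVA + I_Na + I_K +
#' I_leak) + I_inj` with `I_T = g_T m^2 h (V - E_Ca)` (low-threshold calcium
#' current with slow de-inactivation), `I_h = g_h r (V - E_h)` (HCN),
#' `I_HVA = g_HVA q^2 (V - E_Ca)`, Traub-type spiking sodium/potassium
#' currents, and ohmic leak. Pharmacological block is modeled as fractional
#' conductance scaling: `block_t = 1` emulates a saturating pan-T-type
#' blocker (Z944), `block_h = 1` a saturating HCN blocker (ZD7288).
#'
#' @param Cm Whole-cell capacitance (pF).
#' @param g_leak,E_leak Leak conductance (nS) and reversal (mV).
#' @param g_T Maximal T-type conductance (nS); `T_act`, `T_inact` its gates.
#' @param E_Ca Calcium reversal (mV; linear driving force).
#' @param g_h Maximal HCN conductance (nS); `h_act` its gate; `E_h` reversal.
#' @param g_HVA High-voltage-activated calcium conductance (nS); `HVA_act`
#'   its gate.
#' @param g_Na,g_K,E_Na,E_K,v_spike Spiking conductances, reversals and the
#'   spike-threshold offset of the Traub kinetics.
#' @param T_act,T_inact,h_act,HVA_act [gate_kinetics()] objects.
#' @param block_T,block_h Fractional block in `[0, 1]`.
#' @return A `neuron_params` object.
#' @export
neuron_params <- function(Cm = 55, g_leak = 4.5, E_leak = -85,
                          g_T = 45, E_Ca = 120,
                          g_h = 7, E_h = -35,
                          g_HVA = 6,
                          g_Na = 1200, g_K = 1000, E_Na = 50, E_K = -100,
                          v_spike = -52,
                          T_act = gate_kinetics(-60, -5.5, "t_act_tc"),
                          T_inact = gate_kinetics(-81, 4, "t_inact_tc",
                                                  tau_scale = 0.5),
                          h_act = gate_kinetics(-86, 4.2, "hcn_tc",
                                                tau_scale = 0.7),
                          HVA_act = gate_kinetics(-20, -6.5, "constant",
                                                  tau_ms = 1.5),
                          block_T = 0, block_h = 0) {
  Cm <- unname(Cm); g_leak <- unname(g_leak); E_leak <- unname(E_leak)
  g_T <- unname(g_T); E_Ca <- unname(E_Ca); g_h <- unname(g_h)
  E_h <- unname(E_h); g_HVA <- unname(g_HVA); g_Na <- unname(g_Na)
  g_K <- unname(g_K); E_Na <- unname(E_Na); E_K <- unname(E_K)
  v_spike <- unname(v_spike); block_T <- unname(block_T)
  block_h <- unname(block_h)
  g <- c(g_leak, g_T, g_h, g_HVA, g_Na, g_K)
  if (any(g < 0)) abort("conductances must be >= 0.")
  if (Cm <= 0) abort("Cm must be > 0.")
  if (block_T < 0 || block_T > 1 || block_h < 0 || block_h > 1)
    abort("block fractions must lie in [0, 1].")
  structure(list(Cm = Cm, g_leak = g_leak, E_leak = E_leak, g_T = g_T,
                 E_Ca = E_Ca, g_h = g_h, E_h = E_h, g_HVA = g_HVA,
                 g_Na = g_Na, g_K = g_K, E_Na = E_Na, E_K = E_K,
                 v_spike = v_spike, T_act = T_act, T_inact = T_inact,
                 h_act = h_act, HVA_act = HVA_act,
                 block_T = block_T, block_h = block_h),
            class = "neuron_params")
}

params_flat <- function(p) {
  c(cm = p$Cm, g_leak = p$g_leak, e_leak = p$E_leak, g_t = p$g_T,
    e_ca = p$E_Ca, g_h = p$g_h, e_h = p$E_h, g_hva = p$g_HVA,
    g_na = p$g_Na, g_k = p$g_K, e_na = p$E_Na, e_k = p$E_K,
    v_spike = p$v_spike, block_t = p$block_T, block_h = p$block_h)
}

gates_matrix <- function(p) {
  row <- function(gk) {
    code <- match(gk$tau_form, c("t_act_tc", "t_inact_tc", "hcn_tc",
                                 "constant")) - 1L
    c(gk$v_half, gk$slope, gk$tau_scale, code, gk$tau_ms)
  }
  rbind(row(p$T_act), row(p$T_inact), row(p$h_act), row(p$HVA_act))
}

#' Named model presets for the two-strain burst-firing study
#'
#' `NEC` is the non-epileptic control ventrobasal relay cell. `GAERS`
#' carries a larger HCN conductance (`g_h` x 2), a modestly smaller
#' T-type conductance (`g_T` x 0.95), the input-resistance decrease those
#' imply, and a slightly more negative leak reversal calibrated so the two
#' presets share the same resting potential (the epileptic strain shows
#' altered Ih density but an unchanged resting potential; see the package
#' vignette). `*_ZD` presets set `block_h = 1` (saturating ZD7288),
#' `NEC_Z944` sets `block_T = 1`. `P7P9_*` are the neonatal voltage-clamp
#' cells used for calcium-current work: smaller, with spiking and HCN
#' conductances zeroed to emulate recordings with a Cs/TEA internal
#' solution, and with the strain difference on the calcium conductances
#' (T-type density reduced, HVA density increased in the epileptic strain).
#' Absolute conductance magnitudes are package defaults chosen to put
#' rebound-burst threshold currents in the tens-of-pA range; see the
#' package vignette.
#'
#' @param name Preset name.
#' @return A [neuron_params()] object.
#' @examples
#' preset("GAERS")$g_h > preset("NEC")$g_h
#' @export
preset <- function(name = c("NEC", "GAERS", "NEC_ZD", "GAERS_ZD",
                            "NEC_Z944", "P7P9_NEC", "P7P9_GAERS")) {
  name <- match.arg(name)
  nec <- neuron_params()
  gaers <- modify_params(nec, g_h = nec$g_h * 2, g_T = nec$g_T * 0.95,
                         E_leak = -91.93)
  p7p9 <- neuron_params(Cm = 25, g_leak = 2, E_leak = -75, g_T = 8.4,
                        g_h = 0, g_HVA = 6.5, g_Na = 0, g_K = 0)
  switch(name,
    NEC = nec,
    GAERS = gaers,
    NEC_ZD = modify_params(nec, block_h = 1),
    GAERS_ZD = modify_params(gaers, block_h = 1),
    NEC_Z944 = modify_params(nec, block_T = 1),
    P7P9_NEC = p7p9,
    P7P9_GAERS = modify_params(p7p9, g_T = p7p9$g_T * 0.75,
                               g_HVA = p7p9$g_HVA * 1.2))
}

#' Modify fields of a parameter set
#' @param params A [neuron_params()] object.
#' @param ... Fields to replace, e.g. `block_T = 1`.
#' @return The modified `neuron_params`.
#' @export
modify_params <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), names(params))
  if (length(bad)) abort(sprintf("unknown field(s): %s", paste(bad, collapse = ", ")))
  out <- modifyList(unclass(params), repl)
  do.call(neuron_params, out[intersect(names(formals(neuron_params)), names(out))])
}

#' Amplifier/recording configuration for simulated sweeps
#'
#' @param mode Clamp mode.
#' @param R_series Pipette series resistance (MOhm).
#' @param rs_compensation Compensated fraction in `[0, 1]` (0.7 emulates the
#'   70 percent correction used in the recordings); the effective residual
#'   resistance is `(1 - rs_compensation) * R_series`.
#' @param noise_sd SD of additive Gaussian noise on the response (mV in
#'   current clamp, pA in voltage clamp), applied after integration.
#' @param seed Integer seed for the noise stream.
#' @return A `clamp_config` object.
#' @export
clamp_config <- function(mode = c("current_clamp", "voltage_clamp"),
                         R_series = 5, rs_compensation = 0.7,
                         noise_sd = if (mode == "current_clamp") 0.2 else 2,
                         seed = 1L) {
  mode <- match.arg(mode)
  if (rs_compensation < 0 || rs_compensation > 1)
    abort("rs_compensation must lie in [0, 1].")
  structure(list(mode = mode, R_series = R_series,
                 rs_compensation = rs_compensation,
                 noise_sd = noise_sd, seed = seed),
            class = "clamp_config")
}

r_effective <- function(clamp) (1 - clamp$rs_compensation) * clamp$R_series

#' Resting steady state of the model
#'
#' Finds the resting state by relaxation: the model is integrated for
#' `relax_ms` at the given holding level (injected current in current
#' clamp, clamp potential in voltage clamp) from a passive initial guess.
#' The default 8,000 ms covers several HCN time constants near rest.
#'
#' @param params A [neuron_params()] object.
#' @param holding Holding level (pA or mV).
#' @param mode Clamp mode.
#' @param clamp A [clamp_config()] (used for the residual series resistance
#'   in voltage clamp).
#' @param relax_ms Relaxation duration (ms).
#' @param dt Integration step (ms).
#' @return Named numeric state vector
#'   `(V, m_T, h_T, r, q, m_Na, h_Na, n_K)`.
#' @export
resting_state <- function(params, holding = 0,
                          mode = c("current_clamp", "voltage_clamp"),
                          clamp = NULL, relax_ms = 8000, dt = 0.025) {
  mode <- match.arg(mode)
  r_eff <- if (mode == "voltage_clamp") {
    if (is.null(clamp)) clamp <- clamp_config("voltage_clamp")
    r_effective(clamp)
  } else 0
  st <- neuron_relax_cpp(params_flat(params), gates_matrix(params), holding,
                         if (mode == "current_clamp") 0L else 1L,
                         r_eff, dt, relax_ms)
  setNames(st, c("V", "m_T", "h_T", "r", "q", "m_Na", "h_Na", "n_K"))
}

sim_core <- function(params, command, dt, mode, clamp, init_state,
                     return_states, dt_int = 0.025) {
  if (inherits(command, "sweep")) {
    dt <- command$dt
    command <- command$command
  }
  if (is.null(dt)) abort("`dt` is required when `command` is a bare vector.")
  dt_int <- min(dt_int, dt)
  mode_i <- if (mode == "current_clamp") 0L else 1L
  r_eff <- if (mode == "voltage_clamp") r_effective(clamp) else 0
  if (is.null(init_state))
    init_state <- resting_state(params, command[1], mode, clamp, dt = dt_int)
  out <- neuron_sim_cpp(params_flat(params), gates_matrix(params),
                        command, dt, mode_i, r_eff, dt_int,
                        as.numeric(init_state), return_states)
  response <- out$response
  if (clamp$noise_sd > 0) {
    if (!is.null(clamp$seed)) {
      response <- with_local_seed(clamp$seed, response +
                                    rnorm(length(response), 0, clamp$noise_sd))
    } else {
      response <- response + rnorm(length(response), 0, clamp$noise_sd)
    }
  }
  sw <- new_sweep(dt, command = command, response = response, mode = mode,
                  meta = list(simulated = TRUE, noise_sd = clamp$noise_sd))
  if (return_states) {
    colnames(out$states) <- c("V", "m_T", "h_T", "r", "q", "m_Na", "h_Na",
                              "n_K")
    sw$meta$states <- out$states
  }
  sw
}

with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulate a current-clamp or voltage-clamp sweep
#'
#' Integrates the conductance model (fixed-step fourth-order Runge-Kutta at
#' `dt_int = 0.025` ms) under the given command. In current clamp the
#' command is injected current (pA) and the response the membrane potential
#' (mV). In voltage clamp the command potential reaches the membrane
#' through the residual series resistance
#' `(1 - rs_compensation) * R_series`, and the response is the pipette
#' current, which therefore includes the capacitive transient and ohmic
#' leak. Additive Gaussian noise (seeded, `clamp$noise_sd`) is applied to
#' the response after integration, so the underlying dynamics are
#' deterministic given `(params, command, seed)`. The initial state is the
#' resting steady state found by relaxation at the first command sample
#' unless `init_state` is supplied.
#'
#' @param params A [neuron_params()] object.
#' @param command A command [new_sweep()] or bare numeric vector (then `dt`
#'   is required).
#' @param clamp A [clamp_config()].
#' @param dt Sampling interval (ms) when `command` is a bare vector.
#' @param init_state Optional state vector from [resting_state()].
#' @param return_states If `TRUE` the returned sweep carries the full gating
#'   state matrix in `meta$states`.
#' @param dt_int Integration step (ms); must be `<= dt`.
#' @return A [new_sweep()] with the response filled.
#' @export
simulate_current_clamp <- function(params, command,
                                   clamp = clamp_config("current_clamp"),
                                   dt = NULL, init_state = NULL,
                                   return_states = FALSE, dt_int = 0.025) {
  sim_core(params, command, dt, "current_clamp", clamp, init_state,
           return_states, dt_int)
}

#' @rdname simulate_current_clamp
#' @export
simulate_voltage_clamp <- function(params, command,
                                   clamp = clamp_config("voltage_clamp"),
                                   dt = NULL, init_state = NULL,
                                   return_states = FALSE, dt_int = 0.025) {
  sim_core(params, command, dt, "voltage_clamp", clamp, init_state,
           return_states, dt_int)
}

#' Run a whole protocol ladder through the model
#'
#' The resting state is computed once at the holding level and reused for
#' every sweep, emulating the inter-sweep interval of a real step protocol.
#' Per-sweep noise is drawn from a single stream seeded with `clamp$seed`,
#' so the whole ladder is reproducible.
#'
#' @param params A [neuron_params()] object.
#' @param ladder A command ladder from [make_step_protocol()] or
#'   [protocol_template()].
#' @param clamp A [clamp_config()]; its `mode` must match the ladder.
#' @param return_states Attach gating-state matrices to each sweep.
#' @return The ladder with responses filled.
#' @export
simulate_ladder <- function(params, ladder, clamp = NULL,
                            return_states = FALSE) {
  mode <- ladder$protocol$mode
  if (is.null(clamp)) clamp <- clamp_config(mode)
  if (!identical(clamp$mode, mode))
    abort("clamp mode does not match ladder mode.")
  init <- resting_state(params, ladder$protocol$holding, mode, clamp)
  noiseless <- clamp; noiseless$noise_sd <- 0
  sweeps <- lapply(ladder$sweeps, function(sw) {
    sim_core(params, sw, NULL, mode, noiseless, init, return_states)
  })
  if (clamp$noise_sd > 0) {
    sweeps <- with_local_seed(clamp$seed, lapply(sweeps, function(sw) {
      sw$response <- sw$response + rnorm(length(sw$response), 0,
                                         clamp$noise_sd)
      sw$meta$noise_sd <- clamp$noise_sd
      sw
    }))
  }
  new_ladder(ladder$protocol, sweeps)
}

#' Standard protocol templates
#'
#' Named command ladders for the study's protocols: `cc200`/`cc1000`
#' (current clamp, -110 to +200 pA in 10-pA increments, 200-ms or 1,000-ms
#' steps), `cavIV` (voltage clamp, 200-ms test pulses -70 to +10 mV in 5-mV
#' steps from -90 mV holding), `cavIV_prepulse` (the same with a
#' -50 mV/100-ms inactivating pre-pulse), `ihtail` (1,000-ms pre-pulses
#' -110 to -60 mV in 5-mV increments, tail step to -110 mV for 200 ms),
#' `leakcal` (small steps -100 to -80 mV around the -90 mV holding for
#' offline leak fitting), and `cmstep` (the 5-mV, 40-ms step from -90 to
#' -85 mV used for whole-cell capacitance).
#'
#' @param name Template name.
#' @param dt Sampling interval (ms).
#' @return A command ladder.
#' @export
protocol_template <- function(name = c("cc200", "cc1000", "cavIV",
                                       "cavIV_prepulse", "ihtail",
                                       "leakcal", "cmstep"),
                              dt = 0.025) {
  name <- match.arg(name)
  switch(name,
    cc200 = make_step_protocol(0, 200, 200, 600, -110, 200, 10, dt),
    cc1000 = make_step_protocol(0, 200, 1000, 600, -110, 200, 10, dt),
    cavIV = make_step_protocol(-90, 100, 200, 100, -70, 10, 5, dt,
                               mode = "voltage_clamp"),
    cavIV_prepulse = make_step_protocol(-90, 100, 200, 100, -70, 10, 5, dt,
                                        mode = "voltage_clamp",
                                        prepulse_mV = -50, prepulse_ms = 100),
    ihtail = make_step_protocol(-60, 200, 1000, 100, -110, -60, 5, dt,
                                mode = "voltage_clamp",
                                tail_mV = -110, tail_ms = 200),
    leakcal = make_step_protocol(-90, 100, 200, 100, -100, -80, 5, dt,
                                 mode = "voltage_clamp"),
    cmstep = make_step_protocol(-90, 20, 40, 20, -85, -85, 5, dt,
                                mode = "voltage_clamp"))
}

#' Draw a cohort of cells around a preset
#'
#' Emulates between-cell variability: each cell's conductances
#' (`g_leak`, `g_T`, `g_h`, `g_HVA`, `g_Na`, `g_K`) and capacitance are
#' drawn independently and log-normally around the preset values with
#' coefficient of variation `jitter_cv` (mean-preserving
#' parameterization). Reversal potentials, gating kinetics and block
#' fractions are left at the preset.
#'
#' @param preset_name A [preset()] name or a `neuron_params` object to
#'   jitter around.
#' @param n Number of cells (>= 1).
#' @param jitter_cv Coefficient of variation (>= 0); 0 returns `n`
#'   identical parameter sets.
#' @param seed Integer seed; cohorts are byte-identical across runs for a
#'   fixed seed.
#' @return A list of `n` [neuron_params()] objects.
#' @export
generate_cohort <- function(preset_name, n, jitter_cv = 0.2, seed = 1L) {
  if (n < 1) abort("`n` must be >= 1.")
  if (jitter_cv < 0) abort("`jitter_cv` must be >= 0.")
  base <- if (inherits(preset_name, "neuron_params")) preset_name
          else preset(preset_name)
  fields <- c("Cm", "g_leak", "g_T", "g_h", "g_HVA", "g_Na", "g_K")
  sdlog <- sqrt(log(1 + jitter_cv^2))
  with_local_seed(seed, {
    lapply(seq_len(n), function(i) {
      repl <- lapply(setNames(fields, fields), function(f) {
        x <- base[[f]]
        if (x == 0 || jitter_cv == 0) x
        else rlnorm(1, meanlog = log(x) - sdlog^2 / 2, sdlog = sdlog)
      })
      do.call(modify_params, c(list(base), repl))
    })
  })
}
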