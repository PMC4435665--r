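#' Whole-cell capacitance from the 5-mV step transient
#'
#' Applies the transient-integral rule: the capacitive transient of a small
#' voltage step is integrated after subtracting the steady-state (leak)
#' current, and the charge is divided by the commanded step size,
#' `Cm = integral(I - I_ss) dt / dV`, in pF. Integration is trapezoidal
#' over the step; the steady state is the mean of the last quarter of the
#' step.
#'
#' @param sweep A voltage-clamp sweep containing the step (default
#'   protocol: 5 mV from -90 to -85 mV for 40 ms).
#' @return Capacitance in pF.
#' @examples
#' # a rectangular transient of area 250 pA*ms over a 5-mV step is 50 pF
#' @export
whole_cell_capacitance <- function(sweep) {
  if (sweep$mode != "voltage_clamp")
    abort("capacitance estimation requires a voltage-clamp sweep.")
  seg <- parse_step_command(sweep)
  if (is.na(seg$step_on))
    abort("no voltage step found in the command trace.")
  dV <- seg$amplitude - seg$holding
  t <- sweep_times(sweep)
  instep <- t >= seg$step_on & t < seg$step_off
  i_step <- sweep$response[instep]
  dur <- seg$step_off - seg$step_on
  ss <- t >= seg$step_off - dur / 4 & t < seg$step_off
  i_ss <- mean(sweep$response[ss])
  y <- i_step - i_ss
  q <- sum((head(y, -1) + tail(y, -1)) / 2) * sweep$dt # pA*ms
  q / dV
}

steady_state_current <- function(sweep, seg, frac = 0.25) {
  t <- sweep_times(sweep)
  dur <- seg$step_off - seg$step_on
  mean(sweep$response[t >= seg$step_off - dur * frac & t < seg$step_off])
}

#' Offline linear leak correction of a voltage-clamp ladder
#'
#' Fits the ohmic leak `I = g (V - E)` to the steady-state currents of
#' calibration steps in a voltage range where the gated channels are closed
#' (default around -90 mV), then subtracts the fitted leak, evaluated on
#' each sweep's command trace, from every response. The fit is recorded in
#' each sweep's `meta`, and correcting an already-corrected ladder is a
#' near no-op (the refitted leak conductance is ~0).
#'
#' @param ladder A voltage-clamp ladder.
#' @param calib Optional separate calibration ladder (e.g. the `leakcal`
#'   template); defaults to using `ladder` itself.
#' @param calib_range Voltage window (mV) whose steps are used for the fit.
#' @return The leak-corrected ladder.
#' @export
leak_correct <- function(ladder, calib = NULL, calib_range = c(-105, -80)) {
  if (is.null(calib)) calib <- ladder
  p <- calib$protocol
  seg <- protocol_segments(p)
  use <- which(p$amplitudes >= calib_range[1] & p$amplitudes <= calib_range[2])
  volts <- p$amplitudes[use]
  if (length(unique(volts)) < 2)
    abort(sprintf(
      "leak fit needs >= 2 calibration steps in [%g, %g] mV; found %d.",
      calib_range[1], calib_range[2], length(unique(volts))))
  iss <- vapply(use, function(i) {
    sw <- calib$sweeps[[i]]
    steady_state_current(sw, list(step_on = seg$step_on,
                                  step_off = seg$step_off))
  }, 0)
  fit <- lm(iss ~ volts)
  g <- unname(coef(fit)[2]); b <- unname(coef(fit)[1])
  sweeps <- lapply(ladder$sweeps, function(sw) {
    sw$response <- sw$response - (b + g * sw$command)
    sw$meta$leak_corrected <- TRUE
    sw$meta$leak_g_nS <- g
    sw$meta$leak_E_mV <- if (g != 0) -b / g else NA_real_
    sw
  })
  new_ladder(ladder$protocol, sweeps)
}

#' Current-voltage curve with current densities
#'
#' For each test voltage, the peak inward current (signed minimum) within
#' the pulse is extracted from the leak-corrected sweep; densities are the
#' peaks divided by the whole-cell capacitance.
#'
#' @param ladder A leak-corrected voltage-clamp ladder.
#' @param capacitance_pF Whole-cell capacitance from
#'   [whole_cell_capacitance()].
#' @param blank_ms Time blanked after pulse onset to skip the capacitive
#'   transient.
#' @return An `iv_curve` tibble: `voltage_mV`, `peak_pA`,
#'   `density_pA_per_pF`, with the capacitance as attribute
#'   `capacitance_pF`.
#' @export
build_iv <- function(ladder, capacitance_pF, blank_ms = 1) {
  if (missing(capacitance_pF) || is.null(capacitance_pF) ||
      !is.finite(capacitance_pF))
    abort("`capacitance_pF` is required for current densities.")
  p <- ladder$protocol
  seg <- protocol_segments(p)
  peaks <- vapply(ladder$sweeps, function(sw) {
    t <- sweep_times(sw)
    w <- t >= seg$step_on + blank_ms & t < seg$step_off
    min(sw$response[w])
  }, 0)
  out <- tibble(voltage_mV = p$amplitudes, peak_pA = peaks,
                density_pA_per_pF = peaks / capacitance_pF)
  attr(out, "capacitance_pF") <- capacitance_pF
  class(out) <- c("iv_curve", class(out))
  out
}

subtract_ladders <- function(a, b, label) {
  if (!isTRUE(all.equal(a$protocol$amplitudes, b$protocol$amplitudes)))
    abort(sprintf("%s: the two ladders have different step voltages.", label))
  sweeps <- purrr::map2(a$sweeps, b$sweeps, function(x, y) {
    if (length(x$response) != length(y$response))
      abort(sprintf("%s: sweep lengths differ.", label))
    x$response <- x$response - y$response
    x$meta$subtraction <- label
    x
  })
  new_ladder(a$protocol, sweeps)
}

#' Pre-pulse separation of T-type and HVA calcium currents
#'
#' The ladder recorded with a -50 mV/100-ms inactivating pre-pulse contains
#' only the high-voltage-activated (HVA) component; subtracting it
#' sweep-wise from the total-current ladder recovers the T-type component.
#' The two protocols differ by the pre-pulse segment, so the sweeps are
#' aligned at the onset of the variable test pulse before subtraction.
#'
#' @param total_ladder Leak-corrected I-V ladder without pre-pulse.
#' @param prepulse_ladder Leak-corrected I-V ladder with the inactivating
#'   pre-pulse; same test voltages.
#' @param capacitance_pF Whole-cell capacitance (pF).
#' @return A list with `t_type` and `hva` [build_iv()] curves and the
#'   difference ladder `t_ladder` (on the total ladder's time base).
#' @export
isolate_t_type <- function(total_ladder, prepulse_ladder, capacitance_pF) {
  a <- total_ladder; b <- prepulse_ladder
  if (!isTRUE(all.equal(a$protocol$amplitudes, b$protocol$amplitudes)))
    abort("T-type isolation: the two ladders have different step voltages.")
  if (!isTRUE(all.equal(a$protocol$dt, b$protocol$dt)))
    abort("T-type isolation: sampling intervals differ.")
  seg_a <- protocol_segments(a$protocol)
  seg_b <- protocol_segments(b$protocol)
  off <- round((seg_b$step_on - seg_a$step_on) / a$protocol$dt)
  sweeps <- purrr::map2(a$sweeps, b$sweeps, function(x, y) {
    n <- length(x$response)
    j <- pmin(pmax(seq_len(n) + off, 1L), length(y$response))
    x$response <- x$response - y$response[j]
    x$meta$subtraction <- "T-type isolation"
    x
  })
  t_lad <- new_ladder(a$protocol, sweeps)
  list(t_type = build_iv(t_lad, capacitance_pF),
       hva = build_iv(prepulse_ladder, capacitance_pF),
       t_ladder = t_lad)
}

#' ZD7288-sensitive current by subtraction
#'
#' Sweep-wise subtraction `control - blocked`: with a saturating Ih blocker
#' only the leak remains in the blocked recording, so the difference
#' isolates the Ih (blocker-sensitive) component.
#'
#' @param control_ladder,blocked_ladder Matching voltage-clamp ladders.
#' @return The difference ladder.
#' @export
zd_sensitive_current <- function(control_ladder, blocked_ladder) {
  subtract_ladders(control_ladder, blocked_ladder, "blocker-sensitive")
}

#' Tail-current activation curve
#'
#' For each pre-pulse voltage the tail current at the common post-pulse
#' step is measured as the signed extremum toward the expected (inward)
#' direction within a short window after a 2-ms blanking of the capacitive
#' transient, baseline-subtracted using the pre-step holding current. The
#' amplitudes are normalized to the most hyperpolarized pre-pulse (which
#' therefore attains 1 by construction).
#'
#' @param ladder The blocker-subtracted tail ladder (pre-pulse amplitudes
#'   with a common tail segment, e.g. the `ihtail` template).
#' @param blank_ms Post-step blanking (ms).
#' @param measure_ms Measurement window after the blanking (ms); kept short
#'   so the measured amplitude reports the channel open fraction set by the
#'   pre-pulse before it relaxes at the tail potential.
#' @return An `activation_curve` tibble: `prepulse_mV`, `tail_peak_pA`,
#'   `normalized`.
#' @export
tail_current_activation <- function(ladder, blank_ms = 2, measure_ms = 3) {
  p <- ladder$protocol
  if (is.null(p$tail_mV))
    abort("ladder has no tail segment; use a tail protocol (e.g. 'ihtail').")
  seg <- protocol_segments(p)
  amps <- vapply(seq_along(ladder$sweeps), function(i) {
    sw <- ladder$sweeps[[i]]
    t <- sweep_times(sw)
    base <- mean(sw$response[t >= seg$step_on - 50 & t < seg$step_on])
    w <- t >= seg$tail_on + blank_ms & t < seg$tail_on + blank_ms + measure_ms
    if (!any(w)) abort("tail segment missing or too short.")
    min(sw$response[w] - base) # inward tail
  }, 0)
  ref <- which.min(p$amplitudes) # most hyperpolarized pre-pulse
  out <- tibble(prepulse_mV = p$amplitudes, tail_peak_pA = amps,
                normalized = amps / amps[ref])
  class(out) <- c("activation_curve", class(out))
  out
}
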