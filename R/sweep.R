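#' Construct a single sweep
#'
#' A sweep is one recorded or simulated trace: a uniformly sampled command
#' signal (the stimulus) and response signal (the measurement). In current
#' clamp the command is injected current (pA) and the response membrane
#' potential (mV); in voltage clamp the command is the clamp potential (mV)
#' and the response the clamp current (pA).
#'
#' @param dt Sampling interval in ms (scalar, > 0).
#' @param command Numeric vector of per-sample stimulus values.
#' @param response Numeric vector of per-sample measurements, same length as
#'   `command`. May be `NA` (e.g. a protocol not yet run).
#' @param mode `"current_clamp"` or `"voltage_clamp"`.
#' @param t0 Time of the first sample in ms.
#' @param meta Named list of free-form annotations (cell id, condition, ...).
#'   Unit labels `units_command`/`units_response`, when present, must match
#'   the mode.
#' @return An object of class `sweep` with fields `dt`, `t0`, `command`,
#'   `response`, `mode`, `meta`.
#' @examples
#' sw <- new_sweep(0.1, command = rep(0, 100), response = rep(-78, 100))
#' sweep_times(sw)[1:3]
#' @export
new_sweep <- function(dt, command, response = rep(NA_real_, length(command)),
                      mode = c("current_clamp", "voltage_clamp"),
                      t0 = 0, meta = list()) {
  mode <- match.arg(mode)
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    abort("`dt` must be a single positive number (ms).")
  if (length(command) < 2L)
    abort("`command` must contain at least 2 samples.")
  if (length(response) != length(command))
    abort("`command` and `response` must have identical length.")
  units <- sweep_units(mode)
  for (key in c("units_command", "units_response")) {
    if (!is.null(meta[[key]]) && !identical(meta[[key]], units[[key]]))
      abort(sprintf("meta$%s = '%s' does not match mode '%s' (expected '%s').",
                    key, meta[[key]], mode, units[[key]]))
  }
  meta$units_command <- units$units_command
  meta$units_response <- units$units_response
  structure(list(dt = dt, t0 = t0, command = as.numeric(command),
                 response = as.numeric(response), mode = mode, meta = meta),
            class = "sweep")
}

sweep_units <- function(mode) {
  if (mode == "current_clamp")
    list(units_command = "pA", units_response = "mV")
  else
    list(units_command = "mV", units_response = "pA")
}

#' Sample times of a sweep
#' @param sweep A [new_sweep()] object.
#' @return Numeric vector of sample times in ms.
#' @export
sweep_times <- function(sweep) {
  sweep$t0 + sweep$dt * (seq_along(sweep$command) - 1)
}

#' @export
print.sweep <- function(x, ...) {
  cat(sprintf("<sweep> %s, %d samples @ dt = %g ms (%.1f ms)\n",
              x$mode, length(x$command), x$dt, x$dt * length(x$command)))
  invisible(x)
}

#' @export
as_tibble.sweep <- function(x, ...) {
  tibble(time_ms = sweep_times(x), command = x$command, response = x$response)
}

#' Build a step-protocol ladder of command sweeps
#'
#' Generates the family of command traces for a step protocol: the command
#' sits at `holding`, steps to each amplitude for `step_ms`, and returns to
#' `holding` (optionally via a fixed tail segment, as used by tail-current
#' protocols). Responses are left empty; run the ladder through
#' [simulate_ladder()] or fill it from recordings.
#'
#' The amplitudes run from `first` to `last` in steps of `increment`. The
#' standard rebound-burst ladder (`first = -110`, `last = 200`,
#' `increment = 10` pA) has 32 amplitudes; the calcium I-V ladder
#' (`first = -70`, `last = 10`, `increment = 5` mV) has 17.
#'
#' @param holding Baseline command level (pA or mV depending on `mode`).
#' @param pre_ms,step_ms,post_ms Segment durations in ms; `step_ms > 0`.
#' @param first,last,increment Step amplitudes; `(last - first)` must be an
#'   integer multiple of `increment`.
#' @param dt Sampling interval in ms.
#' @param mode Clamp mode of the commands.
#' @param prepulse_mV,prepulse_ms Optional fixed pre-pulse segment inserted
#'   between the pre segment and the step (used by the -50 mV/100-ms
#'   T-type inactivation protocol).
#' @param tail_mV,tail_ms Optional fixed tail segment inserted between the
#'   step and the post segment (used by the Ih tail protocol).
#' @return A `ladder` object: list with `protocol` (class `step_protocol`)
#'   and `sweeps` (list of [new_sweep()] commands).
#' @examples
#' lad <- make_step_protocol(0, 100, 200, 100, first = -110, last = 200,
#'                           increment = 10, dt = 0.1)
#' length(lad$sweeps)
#' @export
make_step_protocol <- function(holding, pre_ms, step_ms, post_ms,
                               first, last, increment, dt = 0.025,
                               mode = c("current_clamp", "voltage_clamp"),
                               prepulse_mV = NULL, prepulse_ms = 0,
                               tail_mV = NULL, tail_ms = 0) {
  mode <- match.arg(mode)
  if (increment == 0) abort("`increment` must be nonzero.")
  if (any(c(pre_ms, post_ms) < 0) || step_ms <= 0)
    abort("segment durations must be >= 0 and `step_ms` > 0.")
  n_inc <- (last - first) / increment
  if (n_inc < 0 || abs(n_inc - round(n_inc)) > 1e-8)
    abort(sprintf(
      "amplitude range not divisible: (last - first)/increment = (%g - %g)/%g = %g is not a non-negative integer.",
      last, first, increment, n_inc))
  amplitudes <- first + increment * seq(0, round(n_inc))
  protocol <- structure(
    list(holding = holding, pre_ms = pre_ms, step_ms = step_ms,
         post_ms = post_ms, amplitudes = amplitudes, dt = dt, mode = mode,
         prepulse_mV = prepulse_mV, prepulse_ms = if (is.null(prepulse_mV)) 0 else prepulse_ms,
         tail_mV = tail_mV, tail_ms = if (is.null(tail_mV)) 0 else tail_ms),
    class = "step_protocol")
  sweeps <- lapply(amplitudes, function(a) {
    new_sweep(dt, command = protocol_command(protocol, a), mode = mode)
  })
  new_ladder(protocol, sweeps)
}

protocol_command <- function(protocol, amplitude) {
  p <- protocol
  n <- function(ms) round(ms / p$dt)
  c(rep(p$holding, n(p$pre_ms)),
    if (!is.null(p$prepulse_mV)) rep(p$prepulse_mV, n(p$prepulse_ms)),
    rep(amplitude, n(p$step_ms)),
    if (!is.null(p$tail_mV)) rep(p$tail_mV, n(p$tail_ms)),
    rep(p$holding, n(p$post_ms)))
}

#' Segment boundaries of a step protocol
#'
#' @param protocol A `step_protocol`.
#' @return Named list of times in ms: `step_on`, `step_off` (the variable
#'   step), and `tail_on`/`tail_off` when a tail segment is present.
#' @export
protocol_segments <- function(protocol) {
  p <- protocol
  on <- p$pre_ms + p$prepulse_ms
  off <- on + p$step_ms
  out <- list(step_on = on, step_off = off)
  if (!is.null(p$tail_mV)) {
    out$tail_on <- off
    out$tail_off <- off + p$tail_ms
  }
  out
}

new_ladder <- function(protocol, sweeps) {
  if (length(sweeps) != length(protocol$amplitudes))
    abort("ladder must have one sweep per protocol amplitude.")
  structure(list(protocol = protocol, sweeps = sweeps), class = "ladder")
}

#' @export
print.ladder <- function(x, ...) {
  a <- x$protocol$amplitudes
  cat(sprintf("<ladder> %d sweeps, %s; steps %g to %g (holding %g), %g-ms step\n",
              length(x$sweeps), x$protocol$mode, a[1], a[length(a)],
              x$protocol$holding, x$protocol$step_ms))
  invisible(x)
}

#' @export
as_tibble.ladder <- function(x, ...) {
  purrr::imap(x$sweeps, function(sw, i) {
    mutate(as_tibble(sw), sweep = i, amplitude = x$protocol$amplitudes[i])
  }) %>% list_rbind() %>%
    select(sweep, amplitude, time_ms, command, response)
}

#' Recover step-protocol structure from a command trace
#'
#' Inverse of [protocol_command()]: given a command sweep generated from a
#' step protocol, recovers the holding level, step amplitude and segment
#' boundaries exactly.
#'
#' @param sweep A sweep whose command is piecewise constant with one step.
#' @return A list with `holding`, `amplitude`, `step_on`, `step_off` (ms).
#' @export
parse_step_command <- function(sweep) {
  cmd <- sweep$command
  holding <- cmd[1]
  changed <- which(cmd != holding)
  if (length(changed) == 0)
    return(list(holding = holding, amplitude = holding,
                step_on = NA_real_, step_off = NA_real_))
  i0 <- changed[1]
  amplitude <- cmd[i0]
  i1 <- i0
  while (i1 < length(cmd) && cmd[i1 + 1] == amplitude) i1 <- i1 + 1
  list(holding = holding, amplitude = amplitude,
       step_on = sweep$t0 + (i0 - 1) * sweep$dt,
       step_off = sweep$t0 + i1 * sweep$dt)
}

#' Apply an offline liquid-junction-potential correction
#'
#' Current-clamp potentials are recorded against the pipette solution; the
#' liquid junction potential (LJP) at the pipette tip offsets them. The
#' correction subtracts the (positive) LJP from every response sample, making
#' the corrected potential more negative, and records the value in `meta` so
#' it cannot be applied twice.
#'
#' @param sweep A current-clamp sweep.
#' @param ljp_mV The calculated junction potential in mV (pipette-minus-bath
#'   convention, as returned by [henderson_ljp()]).
#' @return The corrected sweep.
#' @examples
#' sw <- new_sweep(0.1, rep(0, 50), rep(-64.6, 50))
#' apply_junction_correction(sw, 13.3)$response[1]  # -77.9
#' @export
apply_junction_correction <- function(sweep, ljp_mV) {
  if (sweep$mode != "current_clamp")
    abort("offline junction correction applies to current-clamp sweeps only.")
  if (!is.null(sweep$meta$ljp_corrected_mV))
    abort(sprintf("sweep is already junction-corrected (by %g mV).",
                  sweep$meta$ljp_corrected_mV))
  sweep$response <- sweep$response - ljp_mV
  sweep$meta$ljp_corrected_mV <- ljp_mV
  sweep
}

#' Validate a sweep or ladder against its invariants
#'
#' Checks uniform sampling bookkeeping, equal command/response lengths,
#' unit/mode consistency, and (for ladders) that each sweep's command matches
#' the protocol's piecewise description of its amplitude.
#'
#' @param x A `sweep` or `ladder`.
#' @param tol Numeric tolerance for the command/protocol comparison.
#' @return `TRUE` invisibly; aborts with a message otherwise.
#' @export
validate_ephys <- function(x, tol = 1e-9) {
  if (inherits(x, "sweep")) {
    stopifnot(length(x$command) == length(x$response), x$dt > 0)
    units <- sweep_units(x$mode)
    if (!identical(x$meta$units_response, units$units_response))
      abort("response units do not match mode.")
  } else if (inherits(x, "ladder")) {
    if (length(x$sweeps) != length(x$protocol$amplitudes))
      abort("sweep count does not match amplitude count.")
    for (i in seq_along(x$sweeps)) {
      ref <- protocol_command(x$protocol, x$protocol$amplitudes[i])
      if (length(ref) != length(x$sweeps[[i]]$command) ||
          max(abs(ref - x$sweeps[[i]]$command)) > tol)
        abort(sprintf("sweep %d command deviates from its protocol description.", i))
      validate_ephys(x$sweeps[[i]])
    }
  } else abort("not a sweep or ladder.")
  invisible(TRUE)
}
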