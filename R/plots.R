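#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   geom_errorbar labs facet_wrap theme_minimal
NULL

#' Plot a sweep or ladder
#'
#' `autoplot.sweep` draws command and response against time;
#' `autoplot.ladder` overlays all sweeps coloured by step amplitude.
#'
#' @param object A `sweep` or `ladder`.
#' @param every Plot every `every`-th sample (traces are dense).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sweep <- function(object, every = 10, ...) {
  df <- as_tibble(object)
  df <- df[seq(1, nrow(df), by = every), ]
  units <- sweep_units(object$mode)
  ggplot(df, aes(x = .data$time_ms, y = .data$response)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (ms)", y = sprintf("response (%s)", units$units_response)) +
    theme_minimal()
}

#' @rdname autoplot.sweep
#' @export
autoplot.ladder <- function(object, every = 10, ...) {
  df <- as_tibble(object)
  df <- df[seq(1, nrow(df), by = every), ]
  units <- sweep_units(object$protocol$mode)
  ggplot(df, aes(x = .data$time_ms, y = .data$response,
                 group = .data$sweep, colour = .data$amplitude)) +
    geom_line(linewidth = 0.25, alpha = 0.8) +
    labs(x = "time (ms)", y = sprintf("response (%s)", units$units_response),
         colour = sprintf("step (%s)", units$units_command)) +
    theme_minimal()
}

#' Plot an I-V curve
#' @param object An `iv_curve` from [build_iv()].
#' @param density Plot current density rather than raw peak current.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.iv_curve <- function(object, density = TRUE, ...) {
  y <- if (density) "density_pA_per_pF" else "peak_pA"
  lab <- if (density) "peak current density (pA/pF)" else "peak current (pA)"
  ggplot(object, aes(x = .data$voltage_mV, y = .data[[y]])) +
    geom_line() + geom_point() +
    labs(x = "test potential (mV)", y = lab) +
    theme_minimal()
}

#' Plot a tail-current activation curve with its Boltzmann fit
#' @param object An `activation_curve`; if `fit` is missing it is fitted
#'   here.
#' @param fit Optional [fit_boltzmann()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.activation_curve <- function(object, fit = NULL, ...) {
  if (is.null(fit)) fit <- tryCatch(fit_boltzmann(object),
                                    error = function(e) NULL)
  p <- ggplot(object, aes(x = .data$prepulse_mV, y = .data$normalized)) +
    geom_point() +
    labs(x = "pre-pulse potential (mV)", y = "normalized tail current") +
    theme_minimal()
  if (!is.null(fit)) {
    vv <- seq(min(object$prepulse_mV), max(object$prepulse_mV),
              length.out = 200)
    p <- p + geom_line(data = tibble(
      prepulse_mV = vv,
      normalized = 1 / (1 + exp((vv - fit$v50_mV) / fit$slope_mV))))
  }
  p
}

#' Plot a cohort comparison as mean +/- SEM columns
#' @param object A [cohort_comparison()] table.
#' @param metrics Optional subset of metric rows.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cohort_comparison <- function(object, metrics = NULL, ...) {
  labels <- attr(object, "labels") %||% c("A", "B")
  df <- as_tibble(object)
  if (!is.null(metrics)) df <- dplyr::filter(df, .data$metric %in% metrics)
  long <- dplyr::bind_rows(
    tibble(metric = df$metric, group = labels[1], mean = df$mean_a,
           sem = df$sem_a),
    tibble(metric = df$metric, group = labels[2], mean = df$mean_b,
           sem = df$sem_b))
  ggplot(long, aes(x = .data$group, y = .data$mean, fill = .data$group)) +
    geom_col(width = 0.6) +
    geom_errorbar(aes(ymin = .data$mean - .data$sem,
                      ymax = .data$mean + .data$sem), width = 0.2) +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = NULL, y = "mean +/- SEM") +
    theme_minimal()
}

#' Input-output curve plot
#' @param curve Output of [input_output_curve()].
#' @param normalized Use the threshold-normalized amplitude axis if
#'   present.
#' @return A ggplot object.
#' @export
plot_input_output <- function(curve, normalized = FALSE) {
  x <- if (normalized && "norm_amplitude_pA" %in% names(curve))
    "norm_amplitude_pA" else "amplitude_pA"
  ggplot(curve, aes(x = .data[[x]], y = .data$freq_hz)) +
    geom_line() + geom_point(aes(shape = .data$is_burst)) +
    labs(x = if (normalized) "current relative to threshold (pA)"
             else "injected current (pA)",
         y = "firing frequency (Hz)", shape = "burst") +
    theme_minimal()
}
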