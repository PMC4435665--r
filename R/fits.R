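#' Fit a Boltzmann activation function
#'
#' Least-squares fit of `f(V) = 1/(1 + exp((V - V50)/k))` to a normalized
#' activation curve. The optimizer is Levenberg-Marquardt started from every
#' point of a coarse deterministic grid (V50 over the data range, k over
#' 1-15 mV); the best converged fit is returned, so the procedure is
#' reproducible without random restarts.
#'
#' @param curve An `activation_curve` from [tail_current_activation()], or
#'   any data frame with columns `prepulse_mV` (or `voltage_mV`) and
#'   `normalized`.
#' @return A `boltzmann_fit` object with elements `v50_mV`, `slope_mV`,
#'   `rss`, `fitted`, `data`. `tidy()` and `glance()` methods are
#'   available.
#' @examples
#' v <- seq(-110, -60, 5)
#' curve <- tibble::tibble(prepulse_mV = v,
#'                         normalized = 1 / (1 + exp((v + 86.2) / 4.2)))
#' coef(fit_boltzmann(curve))
#' @export
fit_boltzmann <- function(curve) {
  v <- curve[["prepulse_mV"]] %||% curve[["voltage_mV"]]
  y <- curve[["normalized"]]
  if (is.null(v) || is.null(y)) abort("curve must have voltage and normalized columns.")
  ok <- is.finite(v) & is.finite(y)
  v <- v[ok]; y <- y[ok]
  if (length(v) < 4)
    abort("Boltzmann fit needs >= 4 points spanning the transition.")
  grid <- expand.grid(v50 = seq(min(v), max(v), length.out = 8),
                      k = c(1, 2, 4, 6, 10, 15))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ 1 / (1 + exp((v - v50) / k)),
                        start = list(v50 = grid$v50[i], k = grid$k[i]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) {
    # fall back to the grid-search candidate
    rss_grid <- vapply(seq_len(nrow(grid)), function(i) {
      sum((y - 1 / (1 + exp((v - grid$v50[i]) / grid$k[i])))^2)
    }, 0)
    i <- which.min(rss_grid)
    abort(sprintf(
      "Boltzmann fit did not converge; best grid candidate V50 = %.1f, k = %.1f (rss %.4g).",
      grid$v50[i], grid$k[i], rss_grid[i]))
  }
  cf <- coef(best$fit)
  structure(list(v50_mV = unname(cf["v50"]), slope_mV = unname(cf["k"]),
                 rss = best$rss, fitted = stats::fitted(best$fit),
                 data = tibble(prepulse_mV = v, normalized = y),
                 nls = best$fit),
            class = "boltzmann_fit")
}

#' @export
coef.boltzmann_fit <- function(object, ...) {
  c(v50_mV = object$v50_mV, slope_mV = object$slope_mV)
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V50 = %.2f mV, slope = %.2f mV (rss %.4g, n = %d)\n",
              x$v50_mV, x$slope_mV, x$rss, nrow(x$data)))
  invisible(x)
}

#' @export
tidy.boltzmann_fit <- function(x, ...) {
  s <- tryCatch(summary(x$nls)$coefficients, error = function(e) NULL)
  tibble(term = c("v50_mV", "slope_mV"),
         estimate = c(x$v50_mV, x$slope_mV),
         std.error = if (is.null(s)) NA_real_ else unname(s[, "Std. Error"]))
}

#' @export
glance.boltzmann_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data),
         sigma = sqrt(x$rss / max(1, nrow(x$data) - 2)))
}

#' Fit a Hill dose-response curve
#'
#' Fits `fraction = c^n / (c^n + EC50^n)` to fractional block data by
#' Levenberg-Marquardt from a deterministic log-spaced grid of starting
#' values.
#'
#' @param dose_response A data frame with columns `concentration_nM` and
#'   `fraction_blocked` (in `[0, 1]`, with at least two interior points).
#' @return A `hill_fit` object with `ec50_nM`, `hill_n`, `rss`, `data`;
#'   `tidy()`/`glance()` methods available.
#' @examples
#' conc <- c(0.5, 1, 2, 4, 8, 16, 64)
#' dr <- tibble::tibble(concentration_nM = conc,
#'                      fraction_blocked = conc / (conc + 3.8))
#' coef(fit_hill_ec50(dr))
#' @export
fit_hill_ec50 <- function(dose_response) {
  cc <- dose_response[["concentration_nM"]]
  y <- dose_response[["fraction_blocked"]]
  if (is.null(cc) || is.null(y))
    abort("dose_response must have concentration_nM and fraction_blocked.")
  if (length(cc) < 3) abort("Hill fit needs >= 3 concentrations.")
  if (sum(y > 0 & y < 1) < 2)
    abort("degenerate dose-response: need >= 2 fractions strictly inside (0, 1).")
  grid <- expand.grid(lec = seq(log(min(cc[cc > 0])), log(max(cc)),
                                length.out = 8),
                      n = c(0.5, 1, 2, 3))
  best <- NULL
  for (i in seq_len(nrow(grid))) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ cc^n / (cc^n + exp(lec)^n),
                        start = list(lec = grid$lec[i], n = grid$n[i]),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::resid(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best)) abort("Hill fit did not converge from any grid start.")
  cf <- coef(best$fit)
  structure(list(ec50_nM = exp(unname(cf["lec"])), hill_n = unname(cf["n"]),
                 rss = best$rss,
                 data = tibble(concentration_nM = cc, fraction_blocked = y),
                 nls = best$fit),
            class = "hill_fit")
}

#' @export
coef.hill_fit <- function(object, ...) {
  c(ec50_nM = object$ec50_nM, hill_n = object$hill_n)
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("Hill fit: EC50 = %.3g nM, n = %.2f (rss %.4g)\n",
              x$ec50_nM, x$hill_n, x$rss))
  invisible(x)
}

#' @export
tidy.hill_fit <- function(x, ...) {
  tibble(term = c("ec50_nM", "hill_n"), estimate = c(x$ec50_nM, x$hill_n))
}

#' @export
glance.hill_fit <- function(x, ...) {
  tibble(rss = x$rss, n = nrow(x$data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
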