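#' Characterize one simulated cell with the standard battery
#'
#' Runs the protocols a patch-clamp study would apply to a single neuron
#' and collects the per-cell metrics: rebound burst thresholds for the
#' 1,000-ms and 200-ms ladders with the burst morphology of the threshold
#' sweep, resting potential, input resistance and sag from the -100 pA
#' sweep, whole-cell capacitance from the 5-mV transient, and the Ih tail
#' current density at the -110 mV pre-pulse obtained by blocker
#' subtraction (the same cell re-simulated with `block_h = 1` plays the
#' role of the ZD7288 recording).
#'
#' @param params A [neuron_params()] object (one cell).
#' @param clamp_cc,clamp_vc [clamp_config()]s for the two modes.
#' @param dt Sampling interval (ms).
#' @param protocols Subset of `c("cc1000", "cc200", "ihtail")` to run.
#' @return A one-row tibble of metrics (NA where a protocol was skipped or
#'   the cell never reached burst threshold).
#' @export
characterize_cell <- function(params,
                              clamp_cc = clamp_config("current_clamp"),
                              clamp_vc = clamp_config("voltage_clamp"),
                              dt = 0.05,
                              protocols = c("cc1000", "cc200", "ihtail")) {
  out <- tibble(threshold_1000_pA = NA_real_, threshold_200_pA = NA_real_,
                aps_per_burst = NA_real_, rmp_mV = NA_real_,
                rin_MOhm = NA_real_, sag_mV = NA_real_,
                max_hyperpolarization_mV = NA_real_,
                pre_burst_potential_mV = NA_real_,
                inflection_mV = NA_real_, deflection_mV = NA_real_,
                latency_to_ap_ms = NA_real_,
                capacitance_pF = NA_real_,
                ih_tail_density_pA_per_pF = NA_real_)
  if ("cc1000" %in% protocols) {
    lad <- simulate_ladder(params, protocol_template("cc1000", dt), clamp_cc)
    thr <- rebound_burst_threshold(lad)
    if (!thr$no_burst) {
      out$threshold_1000_pA <- thr$threshold_pA
      out$aps_per_burst <- thr$aps_per_burst
      out$inflection_mV <- thr$burst$inflection_mV
      out$deflection_mV <- thr$burst$deflection_mV
      out$latency_to_ap_ms <- thr$burst$latency_to_ap_ms
      out$max_hyperpolarization_mV <- thr$passive$max_hyperpolarization_mV
      out$pre_burst_potential_mV <- thr$passive$pre_burst_potential_mV
    }
    std <- lad$sweeps[[which(lad$protocol$amplitudes == -100)]]
    pp <- passive_properties(std)
    out$rmp_mV <- pp$rmp_mV
    out$sag_mV <- pp$sag_mV
    out$rin_MOhm <- input_resistance(std)
  }
  if ("cc200" %in% protocols) {
    lad <- simulate_ladder(params, protocol_template("cc200", dt), clamp_cc)
    thr <- rebound_burst_threshold(lad)
    if (!thr$no_burst) out$threshold_200_pA <- thr$threshold_pA
  }
  if ("ihtail" %in% protocols) {
    # the transient-integral rule assumes gated channels are closed at the
    # holding potential; HCN is substantially open at -90 mV, so the
    # capacitance step is taken from the blocker condition
    cmlad <- simulate_ladder(modify_params(params, block_h = 1),
                             protocol_template("cmstep", dt),
                             clamp_vc)
    out$capacitance_pF <- whole_cell_capacitance(cmlad$sweeps[[1]])
    tpl <- protocol_template("ihtail", dt)
    ctrl <- simulate_ladder(params, tpl, clamp_vc)
    blocked <- simulate_ladder(modify_params(params, block_h = 1), tpl,
                               clamp_vc)
    ih <- zd_sensitive_current(ctrl, blocked)
    act <- tail_current_activation(ih)
    ref <- which.min(act$prepulse_mV)
    out$ih_tail_density_pA_per_pF <- act$tail_peak_pA[ref] /
      out$capacitance_pF
  }
  out
}

derive_seed <- function(seed, i) (as.integer(seed) + 7919L * i) %% 2147483629L

#' Two-cohort simulated strain comparison
#'
#' The package's end-to-end study: draws a cohort of cells around each of
#' two presets, runs the per-cell battery ([characterize_cell()]) on every
#' cell, and compares the groups metric by metric with Student t tests
#' ([cohort_comparison()]). Cells that never reach burst threshold
#' contribute `NA` to the threshold rows (the experimental analogue is a
#' discarded neuron).
#'
#' @param preset_a,preset_b Preset names or [neuron_params()] objects.
#' @param n Cells per group.
#' @param jitter_cv Between-cell coefficient of variation
#'   ([generate_cohort()]).
#' @param seed Study seed; drives the cohort draw and every per-cell noise
#'   stream.
#' @param noise_sd_cc,noise_sd_vc Recording noise SDs (mV, pA).
#' @param dt Sampling interval (ms).
#' @param protocols Passed to [characterize_cell()].
#' @return A list of class `cohort_study`: `cells` (per-cell metric tibble
#'   with `group`), `comparison` (the [cohort_comparison()] table),
#'   `labels`.
#' @examples
#' \dontrun{
#' study <- cohort_study("NEC", "GAERS", n = 15, seed = 11)
#' study$comparison
#' }
#' @export
cohort_study <- function(preset_a = "NEC", preset_b = "GAERS", n = 15,
                         jitter_cv = 0.15, seed = 11, noise_sd_cc = 0.2,
                         noise_sd_vc = 2, dt = 0.05,
                         protocols = c("cc1000", "cc200", "ihtail")) {
  labels <- c(if (is.character(preset_a)) preset_a else "A",
              if (is.character(preset_b)) preset_b else "B")
  cohorts <- list(generate_cohort(preset_a, n, jitter_cv, seed),
                  generate_cohort(preset_b, n, jitter_cv,
                                  derive_seed(seed, 1000L)))
  cells <- purrr::imap(cohorts, function(cohort, g) {
    purrr::imap(cohort, function(p, i) {
      cc <- clamp_config("current_clamp", noise_sd = noise_sd_cc,
                         seed = derive_seed(seed, 2L * i + g))
      vc <- clamp_config("voltage_clamp", noise_sd = noise_sd_vc,
                         seed = derive_seed(seed, 2L * i + g + 500L))
      mutate(characterize_cell(p, cc, vc, dt, protocols),
             group = labels[g], cell = i)
    }) %>% list_rbind()
  }) %>% list_rbind() %>%
    select(group, cell, dplyr::everything())
  comparison <- cohort_comparison(
    dplyr::filter(cells, .data$group == labels[1]),
    dplyr::filter(cells, .data$group == labels[2]),
    metrics = setdiff(names(cells)[vapply(cells, is.numeric, TRUE)], "cell"),
    labels = labels)
  structure(list(cells = cells, comparison = comparison, labels = labels),
            class = "cohort_study")
}

#' @export
print.cohort_study <- function(x, ...) {
  cat(sprintf("<cohort_study> %s vs %s, %d cells/group\n",
              x$labels[1], x$labels[2],
              sum(x$cells$group == x$labels[1])))
  print(x$comparison)
  invisible(x)
}
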