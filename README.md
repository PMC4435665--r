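# vbephys

Burst-firing and ion-channel analysis for thalamic relay neurons, with a
built-in conductance-based simulator.

Thalamocortical ventrobasal (VB) relay neurons fire stereotyped rebound
bursts when released from hyperpolarization: a slow low-threshold calcium
potential (T-type, Ca_V3) crowned by sodium spikes, shaped by the
hyperpolarization-activated cation current I_h. Characterizing how much
current it takes to reach burst threshold, how the burst is built
(latencies, inflection/deflection points, APs per burst), and how the
underlying T-type and HCN conductances differ between an epileptic and a
control strain is the bread-and-butter analysis of absence-epilepsy slice
electrophysiology. vbephys implements that entire analysis chain as
tested, reusable R functions, and pairs it with a single-compartment
Hodgkin-Huxley-style VB neuron so every estimator can be validated by
parameter recovery instead of trust.

## What is in the box

* **Data model and I/O** — `new_sweep()`, `make_step_protocol()`,
  `protocol_template()` (the standard ladders: -110 to +200 pA in 10-pA
  steps at 200 or 1,000 ms; calcium I-V from -70 to +10 mV in 5-mV steps;
  I_h tail protocol; leak calibration; 5-mV capacitance step), plus a
  plain-text sweep interchange format (`read_sweeps()`/`write_sweeps()`).
* **Simulator** — `simulate_current_clamp()`, `simulate_voltage_clamp()`,
  `simulate_ladder()` over a model with T-type, HCN, HVA, leak and spiking
  currents (`neuron_params()`); strain presets `preset("NEC")`,
  `preset("GAERS")`, pharmacology presets (`*_ZD`, `NEC_Z944`), neonatal
  voltage-clamp presets (`P7P9_*`); `generate_cohort()` for between-cell
  variability.
* **Current-clamp analysis** — `detect_action_potentials()`,
  `classify_burst()` (>= 3 APs in 100 ms), `rebound_burst_threshold()`,
  `depolarizing_burst_threshold()`, `input_resistance()`,
  `passive_properties()`, `burst_inflection_deflection()`,
  `tonic_firing_frequency()`, `input_output_curve()`.
* **Voltage-clamp analysis** — `whole_cell_capacitance()` (transient
  integral over the 5-mV step), `leak_correct()`, `build_iv()`,
  `isolate_t_type()` (-50 mV/100-ms pre-pulse subtraction),
  `zd_sensitive_current()`, `tail_current_activation()`,
  `fit_boltzmann()`, `fit_hill_ec50()`.
* **Junction potentials** — `henderson_ljp()` with a documented ion
  mobility table and `solution()` compositions.
* **Cohort statistics** — `two_sample_t()`, `cohort_comparison()`,
  `characterize_cell()`, `cohort_study()`; `tidy()`/`glance()` methods and
  `autoplot()` for every result type.

## Worked example

Simulate a control VB neuron through the 1,000-ms rebound ladder and
analyze it:

```r
library(vbephys)

nec    <- preset("NEC")
ladder <- simulate_ladder(nec, protocol_template("cc1000", dt = 0.05),
                          clamp_config("current_clamp", noise_sd = 0))
thr <- rebound_burst_threshold(ladder)
thr
#> <burst_threshold> -50 pA (sweep 7), 4 APs/burst
round(as.data.frame(tidy(thr))[, c("threshold_pA", "aps_per_burst",
                                   "rmp_mV", "rin_MOhm", "sag_mV",
                                   "inflection_mV")], 2)
#>   threshold_pA aps_per_burst rmp_mV rin_MOhm sag_mV inflection_mV
#> 1          -50             4 -77.06   185.64   5.78        -69.02
```

The cell rests near -77 mV, needs -50 pA of 1,000-ms hyperpolarization to
reach burst threshold, and its low-threshold spike takes off at -69 mV —
the same quantities a rig operator would read off the threshold sweep.

Isolate I_h by blocker subtraction and fit its activation:

```r
vc   <- clamp_config("voltage_clamp", noise_sd = 0)
tail <- protocol_template("ihtail", dt = 0.05)
ih   <- zd_sensitive_current(
          simulate_ladder(nec, tail, vc),
          simulate_ladder(modify_params(nec, block_h = 1), tail, vc))
fit  <- fit_boltzmann(tail_current_activation(ih))
fit
#> Boltzmann fit: V50 = -87.86 mV, slope = 5.19 mV (rss 0.005631, n = 11)
```

The generator's gate sits at V50 = -86 mV, slope 4.2 mV; the measured
curve is slightly right-shifted because the 1,000-ms pre-pulses do not
fully equilibrate the slow HCN gate near -85 mV — the same bias the real
protocol carries (see the methods vignette).

Junction potentials for the two recording configurations:

```r
henderson_ljp(solution_preset("cc_pipette"), solution_preset("cc_bath"))
#> Henderson liquid junction potential: +13.48 mV at 307 K
```

And the whole two-strain study in one call:

```r
study <- cohort_study("NEC", "GAERS", n = 15, seed = 11)
study$comparison   # one row per metric: means, SEMs, Student t, p
autoplot(study$comparison, metrics = c("threshold_1000_pA", "rin_MOhm"))
```

## Notes

The simulator's conductance magnitudes are package defaults, chosen to
put rebound thresholds in the tens-of-pA range; directions and protocol
parameters follow the published slice-physiology conventions. See
`vignettes/vbephys-methods.Rmd` for the model, every analysis convention,
and known limitations — including one strain-comparison property under
HCN block that a single-compartment model provably cannot reproduce and
that the test suite reports as a failed expectation rather than hiding.
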