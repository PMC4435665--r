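---
title: "Models and methods behind vbephys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind vbephys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(vbephys)
```

vbephys packages the complete electrophysiological characterization of
burst firing in thalamic ventrobasal (VB) relay neurons: rebound-burst
detection and threshold analysis in current clamp, voltage-clamp isolation
of the T-type calcium current and the hyperpolarization-activated cation
current (Ih), liquid-junction-potential calculation, and two-strain cohort
statistics. Because the recordings this style of study rests on are rarely
shared, the package includes a conductance-based synthetic neuron whose
cohort presets emulate the statistical structure of a non-epileptic
control strain (NEC) versus an absence-epileptic strain (GAERS): every
analysis stage can therefore be validated by parameter recovery against a
known ground truth. This vignette documents the model, its parameters, the
analysis conventions, and the design decisions a maintainer would want to
know, including the points where the minimal model cannot reproduce the
biology.

## The conductance model

A single compartment obeys

$$C_m \frac{dV}{dt} = -\left(I_T + I_h + I_{HVA} + I_{Na} + I_K +
I_{leak}\right) + I_{inj}$$

with, in the units used throughout (mV, ms, nS, pA, pF):

* $I_T = g_T\, m^2 h\,(V - E_{Ca})$ — the low-voltage-activated T-type
  calcium current. Activation is a Boltzmann with $V_{50} = -60$ mV and
  slope $-5.5$ mV; inactivation has $V_{50} = -81$ mV, slope $4$ mV, and
  the classic thalamocortical piecewise-exponential time constant, scaled
  by $0.5$ so that recovery from inactivation near $-90$ mV takes on the
  order of 150 ms. The slow recovery is the heart of the rebound-burst
  phenomenology: a 1,000-ms hyperpolarizing step de-inactivates far more
  T conductance than a 200-ms step of the same amplitude, and the package
  tests assert that there are amplitudes which elicit a rebound burst only
  after the long step.
* $I_h = g_h\, r\,(V - E_h)$ — the HCN current. Steady-state activation is
  a Boltzmann with $V_{50} = -86$ mV and slope $4.2$ mV, the values the
  tail-current analysis recovers. $E_h = -35$ mV and the activation time
  constant follows the usual thalamocortical form at hyperpolarized
  potentials (hundreds of ms, scaled by 0.7) but is made to collapse to a
  1-ms floor above roughly $-60$ mV. Both choices are deliberate: with a
  slowly deactivating Ih, the GAERS preset's larger conductance turns
  outward above $E_h$ during the low-threshold spike and clips one or two
  action potentials off every burst, producing a spurious strain
  difference in APs per burst that the experimental literature does not
  show. Fast depolarized-range deactivation removes the clipping while
  preserving the rebound dynamics that Ih actually drives.
* $I_{HVA} = g_{HVA}\, q^2 (V - E_{Ca})$ — a high-threshold,
  non-inactivating calcium current ($V_{50} = -20$ mV, slope $-6.5$ mV,
  $\tau = 1.5$ ms).
* $I_{Na}, I_K$ — Traub-type spiking currents with threshold parameter
  $-52$ mV.
* $I_{leak} = g_{leak}(V - E_{leak})$.

Pharmacology is modeled as fractional conductance scaling: `block_T = 1`
is a saturating pan-T-type blocker (Z944), `block_h = 1` a saturating HCN
blocker (ZD7288). State-dependent block is out of scope; conductance
scaling is sufficient for every analysis the package performs.

Integration is fixed-step fourth-order Runge-Kutta at 0.025 ms. A fixed
step keeps outputs bit-reproducible across platforms and independent of
solver heuristics; halving the step changes test-protocol voltage traces
by well under 0.1 mV. The initial state is found by relaxation (8,000 ms
at the holding level), long enough to settle the slowest HCN time
constants near rest. Recording noise is additive Gaussian on the response
only, applied after integration from a seeded stream, so the dynamics stay
deterministic given `(params, command, seed)`.

In voltage clamp the command reaches the membrane through the residual
series resistance $(1 - c)\,R_s$ with compensation $c = 0.7$ by default
(the compensation level used in the recordings this emulates) and
$R_s = 5$ M$\Omega$; the response is the pipette current, which therefore
contains the capacitive transient and the ohmic leak, as a real amplifier
records them.

## Preset calibration

Absolute conductance magnitudes are package choices: the study constrains
directions and orders of magnitude (threshold currents of tens of pA,
capacitances of 50-70 pF) but not the conductances themselves. The NEC
preset is $C_m = 55$ pF, $g_{leak} = 4.5$ nS, $E_{leak} = -85$ mV,
$g_T = 45$ nS, $g_h = 7$ nS, $g_{HVA} = 6$ nS, $g_{Na} = 1200$ nS,
$g_K = 1000$ nS, which yields a resting potential near $-77$ mV, an input
resistance near 180 M$\Omega$, a 1,000-ms rebound threshold of $-50$ pA
and bursts of 4-6 action potentials.

The GAERS preset multiplies $g_h$ by 2 and $g_T$ by 0.95, and sets
$E_{leak} = -91.93$ mV. The leak-reversal offset deserves explanation. If
the strains differed only in $g_h$, the extra resting Ih would depolarize
the GAERS resting potential, and — under the cohort generator's
multiplicative conductance jitter — the t statistic of the resting
potential difference would be *identical* to that of the Ih-density
difference, since both scale as $\ln(\text{ratio})/\text{CV}$. The
experimental picture (Ih density roughly doubled, resting potential and
APs per burst indistinguishable) would then be unreachable for any choice
of magnitudes. The GAERS preset therefore carries a slightly more negative
leak reversal, calibrated so the two presets' resting potentials coincide;
biophysically this stands for the background-conductance differences that
co-vary with HCN expression in the epileptic strain. The T-conductance
reduction is kept modest because the T-current density difference was
established in neonatal (P7-P9) cells, which have their own presets:
`P7P9_NEC` and `P7P9_GAERS` are smaller cells ($C_m = 25$ pF) with spiking
and HCN conductances zeroed (emulating a Cs/TEA intracellular solution)
and calcium conductances scaled to land peak densities near $-21$ versus
$-16$ pA/pF (T-type) and $-29$ versus $-34$ pA/pF (HVA).

Cohorts are drawn log-normally around a preset (mean-preserving) with a
default coefficient of variation of 0.2 for all conductances and the
capacitance — slightly below the scatter of the published capacitance
tables (CV near 0.3), because the emulated study design fixes 15 cells
per group, roughly half the group sizes behind the published threshold
comparisons, and the tighter cohorts give the desk-scale study comparable
statistical power to the original. Consequences of these
choices are visible in the tests: with the default generator, the 1,000-ms
threshold difference is significant at $n = 15$, APs per burst and resting
potential are not, input resistance and Ih tail density separate in the
documented directions.

## What the generator does and does not emulate

The simulator reproduces: rebound bursts riding a low-threshold calcium
potential; their dependence on hyperpolarization duration; sag and its
growth with $g_h$ (sag saturates at high $g_h$ because the voltage trough
self-limits — the same feedback that makes trough-based input-resistance
measurements relatively insensitive to $g_h$); hyperpolarization of the
resting potential under HCN block, with rebound bursting abolished and
depolarization-evoked bursting unmasked; complete loss of rebound bursting
under T-type block; and the voltage-clamp phenomenology (capacitive
transients, ohmic leak, pre-pulse T/HVA separation, blocker-subtracted
tail currents).

It does not emulate: membrane bistability under HCN block (deliberately
not engineered in); dendritic space-clamp artifacts; temperature effects;
state-dependent pharmacology; or slow drifts and seal instabilities —
noise is white and stationary. Passing tests therefore demonstrate that
the analysis code does what it claims on data whose ground truth is known,
not that the model is a complete account of VB-neuron biophysics.

One limitation is structural and worth stating precisely. Under HCN block
the two strain presets settle near their respective leak reversals, which
the resting-potential calibration above forces apart by about 8 mV; the
depolarizing burst thresholds measured from those rests then differ by
roughly the GAERS preset's extra resting Ih current (about 35 pA), and the
difference is statistically significant. The emulated study instead found
that HCN block *normalizes* the strain threshold difference. Within a
single-compartment model with conductance-scaled pharmacology, that
normalization is incompatible with the combination of (i) a doubled Ih
density, (ii) equal control resting potentials, and (iii) an
Ih-block-induced hyperpolarization: the three fix the resting-Ih
difference that reappears as a rheobase offset after block. The package
keeps the mechanistically central properties green and reports this one
honestly as a failed expectation rather than bending the generator.

## Analysis conventions

* **Spikes**: upward crossings of $-20$ mV followed by a downward
  crossing; spike time at the local maximum; peaks closer than 1 ms
  merged. The threshold is a package default (robust for both
  Hodgkin-Huxley spikes and synthetic fixtures); it is not stated in the
  emulated methods.
* **Burst criterion**: at least 3 action potentials within a 100-ms
  sliding window, applied literally. `n_aps` is the count of the maximal
  qualifying window, ties resolved to the earliest.
* **Rebound threshold**: hyperpolarizing amplitudes scanned from smallest
  magnitude; the rebound window is 300 ms after step offset, chosen to
  enclose the longest latencies to AP observed under HCN block (around
  270 ms). The depolarizing variant uses the in-step window. "No burst"
  is a value, not an error: saturating T-type block legitimately produces
  it.
* **Passive properties**: resting potential as the mean over the last
  50 ms before the step; maximum hyperpolarization as the in-step minimum;
  pre-burst potential as the mean over the last 10 ms of the step; sag as
  pre-burst minus trough, reported depolarizing-positive. The published
  table this mirrors prints opposite sag signs for its two age groups
  with no stated convention change; the package treats that as a printing
  inconsistency and normalizes.
* **Input resistance**: maximal voltage deflection divided by injected
  current. Table-style burst morphology is reported for exactly the
  threshold sweep; input resistance, resting potential and sag for the
  standard $-100$ pA sweep, which is far less noisy across cells than the
  threshold sweep.
* **Inflection/deflection**: the chart-recorder measurement ("the time
  point at which the neuron begins to exponentially depolarize /
  repolarize") is not algorithmically complete, so the package uses a
  documented surrogate: spikes are clipped (linear interpolation across
  $\pm 2$ ms), the trace box-car smoothed (1 ms), and the inflection
  taken at the end of the $dV/dt$ valley between the passive rebound
  relaxation and the regenerative rise, validated by a sustained
  suprathreshold rise afterwards; the deflection is the first sustained
  $dV/dt$ drop below threshold after the last AP. The detector is
  validated on constructed low-threshold events with known onset (within
  2 ms) and places the inflection of model threshold sweeps in the
  expected $-75$ to $-65$ mV band. Its outputs should not be presented as
  identical to the original chart-based measurements.
* **Capacitance**: transient integral over the 5-mV/40-ms step divided by
  the 5-mV command, trapezoidal integration, steady state from the last
  quarter of the step. With 70% series-resistance compensation the
  steady-state voltage-divider bias stays within the 2% recovery
  tolerance for physiological leak values.
* **Leak correction**: linear ohmic fit to steady-state currents of
  calibration steps in a window around $-90$ mV where the gated channels
  are closed (the `leakcal` template provides them), subtracted pointwise
  using each sweep's command; idempotent by construction.
* **Tail currents**: the first 2 ms after the tail step are blanked
  (capacitive transient); the amplitude is the signed inward extremum in
  the following 3 ms, baseline-subtracted, so it reports the open
  fraction set by the pre-pulse before it relaxes at the tail potential.
  Normalization is to the most hyperpolarized (-110 mV) pre-pulse. With
  the default HCN kinetics the 1,000-ms pre-pulse does not fully
  equilibrate near $-85$ mV (the time constant there approaches 800 ms),
  so the measured activation curve is slightly right-shifted relative to
  the steady-state Boltzmann — as it is in real recordings with this
  protocol; the recovery-contract tests therefore use a
  constant-time-constant gate that separates the equilibration and
  measurement timescales.
* **Fits**: Boltzmann $1/(1+e^{(V-V_{50})/k})$ and Hill
  $c^n/(c^n + EC_{50}^n)$ by Levenberg-Marquardt from a deterministic
  coarse grid of starts (no random restarts), best converged fit
  returned, grid-search candidate reported on failure.
* **Statistics**: pooled-variance Student t by default (the emulated
  methods say "Student's two-sample t test"), Welch via a flag, paired
  where stated; no multiplicity correction, matching the emulated
  practice — a caveat users should carry when reading whole comparison
  tables. Within-cell drug comparisons default to paired, strain
  comparisons to unpaired.
* **Junction potentials**: generalized Henderson equation with a shipped
  relative-mobility table (K $\equiv$ 1) derived from limiting molar
  conductivities via $u = \lambda/(z^2 \lambda_K)$; 307 K default (the
  34 °C bath). Compositions are entered exactly as printed in a methods
  table: the titration base is not added, HEPES carries a fixed
  fractional charge of 0.334 (pKa 7.5 at pH 7.2), EGTA enters as the
  divalent anion, 4-AP as a monovalent cation, and chelated species
  (MgATP, NaGTP) are excluded. Mobilities for 4-aminopyridinium and
  kynurenate are documented estimates; the two printed validation values
  are reproduced within 0.2 mV, and the package claims no better than
  $\pm 1.5$ mV in general.

## Numerical and degenerate-input behavior

Non-finite integration states abort with the failure time. Protocol
builders reject non-divisible amplitude ranges, zero increments and
non-positive step durations. The sweep file format round-trips doubles at
15 significant digits; parse errors name the offending line. Degenerate
statistics (zero variance in both groups) are flagged, not raised.
Cells that never reach burst threshold return an explicit no-burst result
and enter cohort tables as missing values, the analogue of the discarded
neurons in the emulated inclusion criteria.

## Problem sizes

The shipped tests and the cohort study run at the sizes the emulated
study prescribes where it prescribes them (15 cells per group for the
strain comparison; 10,000 replicates for the t-test calibration; 200
Monte-Carlo replicates for fit recovery; 50 simulated ladders and 1,000
random spike trains for the oracle-equivalence checks) and at small
fixture sizes elsewhere. Simulated sweeps are sampled at 0.05-0.1 ms
while the integrator always runs at 0.025 ms.
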