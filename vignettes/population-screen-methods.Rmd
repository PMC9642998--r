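---
title: "Methods: the SAN pacemaker model, the population screen, and the rhythm statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the SAN pacemaker model, the population screen, and the rhythm statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its science: the pacemaker cell
model and its assumptions, the population-of-models procedure, the rhythm
definitions, the statistical conventions, and the design choices made where
more than one reasonable convention exists. It states no empirical result
that the test suite or `scripts/acceptance.R` does not itself compute.

## The pacemaker cell model

`pacemaker_model()` is a single-cell mouse sinoatrial-node (SAN) myocyte
model in the coupled-clock tradition of the Zhang, Kurata and Kharche
lineage of SAN formulations. The membrane clock comprises the funny current
I_f, L- and T-type Ca^2+ currents, a fast (Nav1.5-type) Na^+ current, rapid
and slow delayed-rectifier K^+ currents, transient-outward and sustained K^+
currents, the acetylcholine-activated K^+ current I_KACh, the Na^+/K^+ pump,
the Na^+/Ca^2+ exchanger (NCX), and background Na^+/Ca^2+ conductances. The
calcium clock is a four-compartment scheme (submembrane space, bulk cytosol,
junctional and network SR) with ryanodine-receptor release activated
sigmoidally by submembrane Ca^2+, SERCA uptake, an NSR-to-JSR transfer delay,
and instantaneous-buffer approximations (calmodulin, troponin-C,
calsequestrin). Voltages are mV, concentrations mM, current densities pA/pF;
the right-hand side is compiled C integrated with `deSolve::ode`
(`lsoda`).

The formulation is authored in this package: the gating sigmoids, time
constants and maximal conductances were set to the canonical shapes of this
model family and then tuned so that the nominal cell (i) fires spontaneously
and steadily near the murine heart rate, with a maximum diastolic potential
near −75 mV and an overshoot near +12 mV; (ii) accelerates under the
isoproterenol transform; (iii) decelerates under the carbachol transform;
and (iv) falls silent when all depolarizing pathways are removed. It is a
faithful member of the model family rather than an equation-level
transcription of any single published parameter set, and the model metadata
records this provenance.

Two assumptions simplify the dynamics deliberately: intracellular Na^+ and
K^+ are clamped (autonomic protocols here last tens of seconds, short
relative to bulk ionic drift), and there is no applied pacing — the model is
analyzed only in free-running mode.

### Autonomic condition transforms

The baseline / isoproterenol (ISO) / carbachol (CCh) transforms are
configuration data (`inst/extdata/san_conditions.yaml`), not code, so the
effect lists are auditable and replaceable. The shipped ISO transform scales
G_CaL ×1.3, G_Ks ×1.2 and SERCA uptake ×1.4 and shifts ICaL/ICaT activation
5 mV and I_f activation 7 mV toward more negative potentials (depolarizing
direction) — the classical β-adrenergic signature on the voltage-gated Ca^2+
currents and the funny current. The CCh transform engages I_KACh through a
Hill dose–response (K_0.5 = 0.1 µM, Hill coefficient 1.5, inward
rectification) at 0.3 µM, the ex vivo superfusion dose used in isolated-atria
experiments, plus a 4 mV hyperpolarizing I_f shift. The dose is a
configuration knob (`kach_dose_uM`).

### Simulation and beat analysis

`simulate_pacemaker()` integrates from a stored resting state (gates at
their steady state for −60 mV) and analyzes only the terminal window, so
initial transients never contaminate rates. Defaults: 150 s simulated, final
20 s analyzed, 1 ms output sampling, relative/absolute tolerances 1e−6/1e−8.
Beats are upward crossings of −20 mV with a 30 ms refractory floor, with the
crossing time refined by linear interpolation between samples. The firing
rate is 60/mean(terminal cycle lengths); `steady` requires the coefficient
of variation of the last ten cycle lengths to stay below 2%. There is no
published rule for "steady-state firing rate", so this criterion is the
package's convention, chosen to be insensitive to window placement for a
regularly firing cell. Integrator failures and silent cells downgrade to
`status = "integration_failure"` / `"no_firing"` rather than raising, so a
population run can never be aborted by one pathological variant, and a
silent cell never reports a rate (no division by zero cycle counts).

The test suite and the acceptance script run the model at 10–30 s with
5–10 s analysis windows. At murine rates this still yields 40–80 analyzed
beats per condition, and the terminal-window rates agree to well under 1 bpm
with long runs; the shorter horizon is simply the package's chosen working
scale for its own checks.

## The population screen

`sample_scalings()` draws one multiplicative factor per varied parameter per
variant, `exp(ε)` with `ε ~ N(0, σ²)`. σ is the standard deviation of the
underlying normal on the log scale — the standard population-of-models
convention, stated here explicitly because "log-normal σ" is ambiguous — so
the factors have median exactly 1, and σ = 0.26 gives a central 95% range of
roughly 0.60–1.66. The whole matrix is drawn in one seeded pass, which makes
results independent of execution order and of any later parallel chunking.

`run_population()` evaluates each variant under the three conditions with
either the full ODE model or the analytic surrogate (below).
`filter_physiological()` discards a variant if **any** condition fails to
fire, fails to integrate, is unsteady, or leaves broad rate bounds (default
60–900 bpm; the published description of discarding names only "lack of
firing activity", so the bounds and the steadiness requirement are this
package's explicit, configurable sharpening of "non-physiological").

### Classification

`classify_variants()` labels a variant SSS-like when all three hold
strictly:

* baseline rate below the reference baseline rate;
* fractional ISO response above the reference response;
* |fractional CCh response| below the reference magnitude.

The reference is the **unscaled nominal cell** run through the same engine
and settings. The alternative convention — population medians — would make
every variant's label depend on the realized population; the nominal cell is
deterministic, matches the interpretation of the screen ("which variants
behave like the mutant relative to wild type"), and keeps labels stable
under resampling. Ties go to WT-like: the mutant phenotype is the
conjunction of three strict abnormalities, so a variant indistinguishable
from the nominal cell on any axis is not abnormal on that axis. Because the
classification boundary is a measure-zero surface, the tie rule matters only
for constructed inputs, but it is fixed and tested. Fractional responses are
relative to the *same variant's* baseline, matching the "relative rate
variation" reading of autonomic response.

The resulting SSS-like fraction is seed- and rule-sensitive; the package
treats the partition identity (SSS + WT + discarded = total) and the
direction of parameter shifts as the reproducible findings, and reports
counts as stochastic outcomes, not targets.

### Group comparison

`compare_groups()` reports, per parameter: group medians, boxplot notch
intervals q50 ± 1.57·(q75 − q25)/√n, the two-sided Wilcoxon rank-sum
p-value, the sign of the median difference (SSS − WT), and a significance
flag at α = 0.05. Non-overlapping notches and rank-sum significance are
approximately — not exactly — equivalent criteria; the package computes
both and asserts only the rank-sum flag in its tests.

## The analytic surrogate population

`surrogate_spec()` defines a closed-form stand-in for the ODE population:
log rate under condition c is `log(base_c) + Σ_j coef[j,c]·log(s_j)`, with
optional Gaussian noise (default 0). With zero noise the map is
deterministic and invertible, so classification fractions and
selection-induced median shifts can be enumerated exactly — this is the
oracle used by the property tests, and the engine behind the full-size
(10,000-variant) pipeline runs in the test suite, where ~30,000 stiff ODE
integrations would be a multi-hour batch job. The default elasticities are
arbitrary in magnitude and carry no biophysical content; only their signs
are structured, chosen so the screen's selection logic produces the
qualitative shift pattern the method is meant to resolve (baseline rate
coupled positively to G_CaL, G_Na and v_RyR and negatively to v_NCX; CCh
response carried by G_KACh). The surrogate validates the *pipeline*, not the
cell model; conclusions about ionic mechanism always require the ODE
engine.

The base rates (350/440/270 bpm for baseline/ISO/CCh) are realistic
isolated-mouse-SAN values and define reference responses of +25.7% (ISO) and
−22.9% (CCh).

## Rhythm definitions

* **Sinus arrest (SA)**: one episode per PP interval *strictly* greater than
  the threshold; 1.5 s is the zebrafish convention. For other species no
  published threshold exists, so the default is 2× the recording's median PP
  — a package convention, selected by the species tag and overridable.
  When P fiducials are absent the detector runs on RR with a warning (RR is
  the measurable proxy).
* **AV block (AVB)**: published screens report AVB only as counts, with no
  detection rule, so the rule here is invented and flagged as such: greedy
  one-to-one P→R pairing in time order; a P with no unused R within the
  pairing window (default median + 4 SD of the provisional P-to-next-R
  delays) is one AVB call.
* **SANRT / cSANRT**: time from the last pacing stimulus to the first
  strictly later spontaneous beat; the corrected form subtracts the
  pre-pacing resting cycle length. No post-pacing beat is an error — the
  "suppressed SAN" edge is surfaced, not silently zeroed.
* **Cycle-length variation**: sample SD (n−1) of successive cycle lengths;
  coefficient of variation available as an option.
* **R-peak detection**: zero-phase Butterworth band-pass (0.5 Hz high-pass;
  200 Hz low-pass or just under Nyquist), rectified-derivative envelope
  smoothed over ~10 ms, threshold at a fraction of the rolling 99.5th
  envelope percentile floored at 80% of the global percentile (so pauses and
  recording tails do not collapse the threshold onto the noise floor), one
  peak per supra-threshold region, 30 ms lockout. The envelope is
  polarity-invariant by construction.

## Statistical conventions

* **Incidence**: percentages round half-up to one decimal (table
  formatting), not banker's rounding.
* **Chi-square**: Pearson 2×2 with 1 df; Yates correction **off by
  default**. The motivating small-sample screening comparison (1/20 vs
  4/10) is significant only without the correction, so the uncorrected test
  is evidently the convention of the tables this package mirrors; the
  correction is exposed as a flag.
* **Summary t-test**: pooled-variance Student's t with df = n₁ + n₂ − 2,
  computed from summaries; SEM inputs are converted to SD by ×√n. The
  package supports both dispersion kinds because screening tables are
  inconsistent about which "±" denotes: the echocardiography heart-rate
  comparison (481±16 vs 447±11, n = 6 each) reproduces its published
  p = 0.0017 only under the SD reading, while the same tables' footnotes
  elsewhere say SEM. The implementation documents the discrepancy and lets
  the caller choose rather than resolving it.
* **Rank-sum**: exact two-sided p from the null distribution when the
  smaller sample is ≤ 10 and there are no ties; otherwise normal
  approximation with midranks, tie-corrected variance and a continuity
  correction that vanishes at the null centre (identical samples give
  p = 1 exactly).
* **Notch interval**: quartiles by linear interpolation between order
  statistics (`quantile` type 7, the convention of the plotting environments
  the notch display comes from), fixed so the worked examples are exact.

## Synthetic data: what it does and does not emulate

The beat-train generator emulates fiducial-level recordings — near-periodic
P trains with Gaussian cycle jitter, injected pauses, conduction delays and
dropped ventricular responses — with ground truth emitted alongside. The
waveform generator renders stylized Gaussian P/QRS/T deflections plus white
noise. Neither reproduces real electrode noise spectra, baseline wander,
T-wave morphology or movement artifacts; detector tests on these data
establish correctness of the detection logic on separable events, not
field performance on noisy recordings. Likewise the surrogate population
establishes correctness of the screening pipeline, not of the cell model.
All generators are deterministic under a fixed seed and restore the caller's
RNG state.

## Problem sizes and limitations

The test suite runs the ODE model at 10–25 s horizons, a 6-variant ODE
population, and surrogate populations of 500–10,000 variants; the
acceptance script adds a 200-variant ODE population (600 stiff
integrations, ~2 minutes on one CPU) and a 10,000-variant surrogate run.
A full 10,000-variant ODE screen is a straightforward but multi-hour batch
job with `run_population(engine = "ode")`; its per-variant independence
makes it trivially parallelizable by splitting the scaling matrix.

Known limitations: single-cell only (no tissue coupling, no pacemaker
hierarchy or exit block, although those are the phenomena a whole-organ SSS
phenotype ultimately involves); clamped Na^+/K^+; stylized I_KACh
rectification; the AVB rule and non-zebrafish SA threshold are package
conventions; and the model is a tuned family member, not a transcription of
a published parameter set, so quantitative current densities should not be
quoted as measurements.
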