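---
title: "Models and methods behind ergofit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ergofit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ergofit)
```

ergofit turns four families of laboratory time series — breath-by-breath
gas exchange, dynamometer torque, muscle NIRS and arterial
diameter/velocity — into the parameters physiologists use to describe
the endurance phenotype. This vignette explains each model, the
assumptions behind it, the tunable parameters and their defaults, the
numerical choices, and what the synthetic-data generators do and do not
emulate.

## Pulmonary V̇O2 on-kinetics

### Cleaning chain

Breath-by-breath V̇O2 is noisy and occasionally corrupted by coughs,
swallows and sighs. The chain applied to each rest-to-exercise
transition is:

1. **Errant-breath screen** (`remove_errant_breaths()`): a breath is
   removed when its V̇O2 deviates from the mean of its neighbours by
   more than 3 local standard deviations. The neighbourhood is a
   centred 5-breath window *excluding* the candidate breath; the window
   width is not part of the 3-SD rule itself and had to be chosen — a
   5-breath window matches common breath-by-breath practice and is
   narrow enough to track the on-transient mean. The screen makes a
   single pass over the original series, so it is idempotent on clean
   data. A breath exactly at 3 SD is retained (strict inequality, with
   a 1e-9 relative guard so floating-point rounding cannot flip the
   boundary case), and a zero-spread neighbourhood never removes
   anything. Only the V̇O2 channel is screened — it is the fitted
   channel — while V̇CO2, V̇E and RER ride along untouched for the
   threshold and efficiency analyses.
2. **1-s linear interpolation** (`interpolate_1s()`) onto integer
   seconds within the observed span; no extrapolation.
3. **Time alignment** to the load-onset marker (`align_to_onset()`):
   phase boundaries come from protocol markers, not from thresholding
   the signal.
4. **Ensemble averaging** (`ensemble_average()`) across transitions
   (three in the standard protocol) over the common time range.
5. **5-s binning** (`bin_5s()`) of consecutive non-overlapping blocks.
   The bin timestamp is the block *midpoint*: the kinetics fit is
   time-sensitive, and a start-of-bin convention would bias the time
   delay by ~2.5 s. A trailing partial bin is dropped.

### The phase-II model

The binned ensemble response after load onset is fitted with

$$\dot VO_2(t) = \dot VO_{2BASE} + \dot VO_{2AMP}\left[1 - e^{-(t-TD)/\tau}\right],$$

for $t \ge TD$. Two modelling decisions were genuinely open:

* **Baseline fixed, not free.** $\dot VO_{2BASE}$ is the mean of the
  final 60 s of unloaded pedalling (`compute_baseline()`, window
  configurable) and enters the fit as a constant, leaving three free
  parameters. This matches the symbol's physiological definition and
  stabilises the well-known TD/τ trade-off on 44-point datasets.
* **Flat before the delay.** For $t < TD$ the exponential argument is
  positive and the formula would rise *backwards*; the model is defined
  as flat at baseline before TD, treating TD as a pure delay so
  pre-delay bins cannot bias τ.

The fit window is $(20, 240]$ s after onset: the first 20 s are the
cardiodynamic phase-I response, which reflects circulatory transit
rather than muscle O2 consumption and is excluded; 240 s is ample for a
moderate-domain response (τ ≤ ~35 s reaches >99.8% of its amplitude).
Samples are included when their *bin midpoint* falls in the window.

**Optimisation.** Levenberg–Marquardt with box constraints
(`minpack.lm::nls.lm`), bounds $\tau \in (0, 120]$ s, $TD \in [0, 40]$ s,
$\dot VO_{2AMP} \ge 0$, and three deterministic starts
($\tau_0 \in \{15, 25, 40\}$ s, $TD_0 = 10$ s, amplitude from the last
60 s of the window minus baseline); the lowest-RSS solution is kept, so
the returned fit is never worse than any start. A flat input returns
`converged = FALSE` with an `NA` τ — a zero-amplitude response cannot
identify a time constant — and a solution pinned at the τ bound is also
flagged unconverged rather than reported as a finite estimate.

## Ramp test and the gas-exchange threshold

V̇O2peak is the maximum 30-s rolling mean of the 1-s interpolated ramp
V̇O2. Peak power subtracts two thirds of the ramp rate from the
cessation power (16.67 W at 25 W/min), the standard correction for the
V̇O2 lag behind a fast ramp; `power_at_get()` applies the same
correction at the threshold crossing and floors the result at zero.

The threshold itself is located algorithmically, where the original
practice is visual agreement between two assessors. The package does
not pretend to reproduce human judgement; it makes the criteria
explicit and surfaces disagreement:

* **Primary (v-slope):** after 10-s binning (a declared default — the
  binning is not prescribed by the v-slope method itself and is
  configurable), a continuous two-segment piecewise-linear regression
  of V̇CO2 on V̇O2 is fitted at every candidate knot; the knot
  minimising pooled RSS is the GET, accepted only when the upper
  segment is steeper and the two-segment model improves on a single
  line by more than 5% of its RSS. When a single line already fits to
  numerical precision there is no knee, whatever the ratio of two
  near-zero RSS values — a guard rejects this case explicitly.
* **Secondary (ventilatory equivalents), as QC:** in the 60 s after the
  breakpoint V̇E/V̇O2 must rise while V̇E/V̇CO2 does not. "Does not
  rise" is operationalised as *not both* statistically positive
  (one-sided t-test at 5%) *and* materially positive (>0.1% relative
  rise over the window), so neither breath noise nor floating-point
  residue can veto a true threshold. Disagreement raises a `review`
  flag in place of the second assessor.

The breakpoint scan is invariant to a shared rescaling of both gas
axes, which the test suite checks as a property.

## Gross efficiency

Steady-state V̇O2 and RER are means over the final 120 s of the
constant-load phase. Metabolic power is
$\dot VO_2 \times (4940\,\mathrm{RER} + 16040)/60$ W with V̇O2 in
L/min. The bracket is the energy equivalent of oxygen in J/L — about
20.5 kJ/L at RER 0.9, the physiological anchor that pins down the
otherwise ambiguous placement of the division by 60 (J/min → W). The
expression assumes purely aerobic metabolism; above RER 1.0 the value
is still computed but flagged invalid rather than silently corrected.

## Critical torque

Segmentation of the 5-min all-out test is protocol-driven: cycle $k$
occupies $[5(k-1), 5k)$ s and its contraction sub-window is the first
3 s. Onset detection from the torque signal is deliberately *not* the
default (the schedule is imposed by the verbal cues), but a
threshold-based refinement (`onset_threshold`) is available for
recordings whose clock is misaligned. Per-cycle impulse is the
trapezoidal integral over the contraction window only — rest-interval
torque is essentially zero, and whether it was included in the original
definition is not stated; contraction-window-only is assumed and
documented. Window boundaries are inclusive at both ends so that a
constant 80 N·m contraction yields exactly 240 N·m·s at 100 Hz.

CT is the mean torque of the last six contractions (the final 30 s).
I′ = I − CT × Tlim with Tlim = 300 s as printed. Note the structural
consequence: contraction occupies 3 of every 5 s, so a test sitting at
CT throughout has I = 180·CT < 300·CT and a *negative* I′. The package
computes the formula faithfully and flags negative values
(`negative_i_prime`); passing `tlim = 180` (total contraction time)
selects the alternative convention. Faithfulness first, usability
second.

## Muscle oxygenation and critical ratios

Per-contraction means of TSI and Δ[HHb] over each 3-s window are
normalized to percent of their own maxima, mirroring the treatment of
torque (percent of the best in-test contraction). Two signal-specific
choices:

* Δ[HHb] is a *relative* concentration; its pre-test 30-s resting mean
  is subtracted before normalization (window configurable). TSI is
  already an absolute percentage and needs no zeroing.
* The time point X of each ratio is not pinned by the ratio definition;
  the contraction-window midpoint ($t_{on} + 1.5$ s, X = 0 at test
  start) is used and configurable.

The torque-%/oxygenation-% ratio series is fitted with
$R(X) = CR + (0R - CR)e^{-X/\tau}$ under the same multi-start LM scheme
as the kinetics fit ($\tau_0 \in \{30, 60, 120\}$ s, bounds
$CR, 0R \ge 0$, $\tau \in (0, 600]$). A flat series returns the series
mean as CR with `converged = FALSE`; a rising series is fitted but
flagged `"rising"`. τ½ is reported as $\tau \ln 2$ — the half-life of
the fitted decay; since the reporting convention for τ½ in this
literature is ambiguous, both τ and τ½ are emitted and no agreement
with any particular published table is forced.

**Identifiability note.** Because both numerator and denominator are
max-normalized, the ratio curve is only identified up to a positive
scale: multiplying all oxygenation values by a constant leaves the
normalized series unchanged. `gen_nirs_trace()` therefore rescales the
requested $(0R, CR)$ once so that the back-solved oxygenation series
peaks at exactly 100%, and records the *effective* parameters in its
truth object; τ is scale-invariant and unchanged. The analysis chain
recovers these effective parameters exactly on noiseless input.

## Flow-mediated dilation

Baseline diameter is the mean over the 60 s before cuff inflation; the
occlusion period is excluded from every computation. The post-deflation
peak is taken from a 3-s centred moving average (configurable, 0
disables) — single-frame noise spikes otherwise dominate the maximum of
a 1-Hz trace with ~0.02 mm noise; whether the original analyses
smoothed before peak-picking is unknown, so the default is declared
rather than claimed. Ties break to the earliest time, and a trace that
never exceeds its deflation value is flagged `no_dilation`.
"Beginning of vasodilation" for the SR_AUC integral is the
cuff-deflation time. Shear rate is 4V/D per frame, with non-positive
diameters excluded and flagged; SR_AUC is the trapezoidal integral from
deflation to the time of peak diameter, exact for affine shear rate.

## The synthetic-data generators

Each generator draws from one seeded RNG (`withr::with_seed`), leaves
the global RNG stream untouched, and returns data plus a truth object
sufficient to regenerate it bit-identically.

* **Breath transitions**: 3-min rest / 3-min unloaded / 5-min loaded
  bouts; breath times from a gamma renewal process (mean 2.5 s, shape
  8, a realistic ~35% interval CV); loaded-phase mean from the phase-II
  model; Gaussian breath noise (default SD 80 mL/min); errant breaths
  injected at 2% with ≥5-SD offsets. Defaults (baseline 900 mL/min,
  amplitude 1100 mL/min, TD 11 s, τ 25 s) sit mid-range for
  recreationally trained adults in the moderate domain.
* **Ramp**: linear V̇O2 rise with a programmed v-slope knee; V̇E
  proportional to V̇CO2 so the ventilatory-equivalent QC has the
  correct sign structure.
* **Torque test**: per-cycle expected torque decays as
  $CT + (T_0 - CT)e^{-X_k/\tau_f}$ (cycle midpoints $X_k$); within each
  contraction a trapezoidal ramp (0.3 s rise/fall) is scaled so the
  3-s window *mean* equals the expected torque; rests are silent; white
  noise (3% of $T_0$) overlays everything. Defaults $T_0 = 160$,
  $CT = 70$ N·m put the end-test plateau at ~44% of the starting
  torque, the fatigue depth typical of this protocol.
* **NIRS**: per-cycle oxygenation back-solved from a target ratio decay
  and the paired torque percentages (see the identifiability note),
  bridged linearly across rests, upsampled to 10 Hz with within-cycle
  noise, preceded by a 30-s resting baseline.
* **FMD**: baseline plateau, occlusion gap, log-normal-shaped
  hyperaemic rise peaking exactly at `t_peak`, velocity surge decaying
  over ~40 s; 1-s sampling with 0.02 mm diameter noise.

**What they do not emulate**: cardiopulmonary coupling (each channel's
noise is independent), slow-component V̇O2 kinetics, pacing strategies
or non-stationary effort in the all-out test, adipose-tissue effects on
NIRS, ultrasound speckle or edge-detection failure modes. Passing the
recovery suites therefore demonstrates that the estimators are correct
and stable under realistic noise levels — not that every idiosyncrasy
of real recordings is handled.

## Verification strategy and problem sizes

Every stage is tested three ways: closed-form oracles (line and
polynomial integrals, boundary arithmetic), independent brute-force
re-implementations (the errant-breath screen, the exhaustive breakpoint
scan), and parameter recovery on generator output. The recovery suites
use 200 simulated subjects (three transitions each, breath noise
80 mL/min, τ drawn from 18–35 s) for the kinetics chain — median
absolute τ error below 2 s with bias below 1 s — and 100 seeds at 5%
multiplicative noise for the critical-ratio fit, with CR recovered
within 5% of truth (0.5% noiseless). These sizes give stable medians
while keeping the full suite's runtime modest. `scripts/acceptance.R`
recomputes the same quantities from scratch for any seed.

## Known limitations

* The GET detector assumes a single breakpoint; respiratory
  compensation is out of scope and data extending far past the GET can
  pull the knot upward.
* The kinetics model is mono-exponential: heavy-domain transitions with
  a slow component will show structured residuals and a biased
  amplitude.
* I′ inherits the Tlim ambiguity described above; compare conventions
  before pooling across studies.
* Readers expect breath-tabulated exports; breath detection from raw
  flow signals is upstream of this package.
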