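---
title: "Methods: the cerebrovascular response pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the cerebrovascular response pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvrpipe)
```

## The measurement and the outcome

Transcranial Doppler insonation of the middle cerebral artery yields a
beat-resolved velocity signal (MCAv, cm/s) that tracks cerebral blood
flow as long as vessel diameter is stable — a reasonable assumption at
moderate exercise intensity. The protocol modelled here is a continuous
7.5-min recording: 90 s of seated rest, then 6 min of cycling at 45–55%
of heart-rate reserve (Karvonen method; `hr_max()` uses `220 − age`, or
`164 − 0.72·age` for subjects on beta-blockade, and the prescription is
never rounded).

Each hemisphere is summarised by the cerebrovascular response to
exercise,

$$\mathrm{CVR} = \overline{\mathrm{MCAv}}_{[180,270)} -
\overline{\mathrm{MCAv}}_{[0,90)},$$

and by the percent change $\%\Delta\mathrm{MCAv} = 100\cdot
\mathrm{CVR}/\overline{\mathrm{MCAv}}_{[0,90)}$, which removes the
dependence on the resting baseline. Two window conventions had to be
fixed:

- *"Between minute 3 and 4.5"* is anchored to the **continuous recording
  clock**, i.e. [180, 270) s, which is 90–180 s into exercise. The
  alternative (minutes 3–4.5 of exercise, [270, 360) s) was rejected
  because the rest period is indexed as the first 90 s of the same
  continuous recording; with a rise time constant of tens of seconds
  either window sits on the steady-state plateau, so the choice moves
  CVR by far less than its between-subject spread.
- All windows are **half-open** ([a, b)) so boundary samples are never
  double-counted.

Resting MCAv is computed from the bout-averaged series (not from the
first bout alone): averaging repeated bouts is the protocol's stated
rationale for recording them, and it applies to the baseline as much as
to the response.

## Preprocessing

Raw acquisition is nominally 500 Hz with beat-onset markers. The chain
is:

1. **Cycle segmentation** (`extract_cycles`): each inter-onset interval
   becomes one cardiac cycle with its time-average (`mean_v`) and
   maximum (`peak_v`) velocity.
2. **Censoring** (`censor_cycles`): a cycle is artifact if its
   instantaneous cardiac frequency `1/RR` exceeds 5 Hz, or if its peak
   velocity differs by more than 10 cm/s from the most recent *accepted*
   peak. Both thresholds are strict inequalities. Two readings deserve
   comment:
   - The rate rule is stated in the field as "RR intervals > 5 Hz",
     which is dimensionally a frequency criterion; we implement it as
     `1/RR > 5 Hz` (RR < 0.2 s, i.e. > 300 bpm — physiologically
     impossible, hence artifact).
   - Referencing the last accepted peak instead of the immediate
     predecessor is equivalent whenever the predecessor is clean, but it
     prevents a single spike-contaminated cycle from dragging its clean
     successor into the censored set on the recovery edge: one spike
     censors exactly one cycle.
   The first cycle (or any cycle without an accepted predecessor) is
   exempt from the jump test. Whether the original rule compared mean or
   peak cycle velocity is not decidable from the protocol text; peak
   velocity is implemented as printed.
3. **Discard rule** (`apply_discard_rule`): an acquisition with strictly
   more than 15% censored cycles is dropped entirely. A subject with no
   surviving bout for a hemisphere is excluded from analysis, and the
   run report accounts for every exclusion.
4. **Resampling** (`resample_to_2hz`): surviving cycle means, placed at
   cycle midpoints, are linearly interpolated onto a uniform 0.5-s grid
   ("interpolated to 2.0 Hz"; linearity is the minimal reading of
   "interpolated"). Grid points outside the convex hull of surviving
   beats are missing, never extrapolated.
5. **Smoothing** (`smooth_3s_9s`): non-overlapping 3-s block means
   (blocks anchored at t = 0; a final partial block is dropped),
   followed by a centred moving average over 3 blocks (a 9-s window);
   the edge blocks average the 2 available blocks. Both stages are
   linear, so smoothing commutes with affine rescaling of the velocity
   channel — a property the test suite checks directly.
6. **Bout averaging** (`average_bouts`): pointwise means across bouts on
   the common grid, with missing points excluded pairwise.

## Group inference

Subjects are split at HbA1c 7% (`split_by_hba1c`); a value of exactly
7.0 goes to the low group — the guideline defines only "< 7%" and
"> 7%", and the convention only matters on a measure-zero boundary.

The group comparison is the Mann–Whitney U test, implemented from first
principles because its internals are the package's verification
surface:

- `midranks` assigns average ranks to ties.
- `U = R_a − n_a(n_a+1)/2` for the first group's midrank sum `R_a`; the
  complement identity `U_a + U_b = n_a n_b` and rank-sum conservation
  are property-tested.
- The normal deviate uses the tie-corrected variance
  $\sigma^2 = \frac{n_1 n_2}{12}\left[(N+1) -
  \frac{\sum_t (t^3-t)}{N(N-1)}\right]$ and **no continuity
  correction**: at group sizes 6 vs 13, U = 10 gives z = −2.543 under
  the uncorrected formula (the corrected one gives −2.50), which is the
  convention large statistical packages print.
- The exact p enumerates the U null distribution by the recursive
  counting method (`exact_u_distribution`), validated against
  brute-force enumeration for all group sizes up to 8 and against the
  base-R Wilcoxon distribution; under ties it falls back to complete
  permutation over all group assignments. The two-sided value is the
  doubled smaller tail, capped at 1 — the dominant package convention.
  Both exact and asymptotic p are reported; published p-values of
  unknown provenance are asserted against neither.

Fisher's exact test (`fisher_exact_2x2`) sums hypergeometric point
probabilities (computed in log space via `lchoose`, stable far beyond
n = 200) over all tables, with margins fixed, whose point probability
does not exceed the observed table's (relative guard 1 + 1e-7 against
floating-point ties). This point-probability convention reproduces the
published categorical comparisons (1.000, 0.605, 0.517) exactly.
`pearson_r` reports the sample correlation with the two-sided p from
$t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom.

`summarize_table1` assembles the clinical-style summary: continuous rows
as mean ± SD with the rank test, categorical rows as count (%) with the
Fisher test, flagged at α = 0.05. Single-subject groups report SD as
missing. No multiplicity correction is applied and no covariate
adjustment is attempted: at n = 19 a multivariable model would be badly
overfit, and the analysis this package mirrors made the same choice.

## The synthetic cohort generator

No participant recordings are publicly deposited, so validation rests on
a generator whose ground truth is known by construction
(`synth_params`, `simulate_cohort`, `simulate_recording`,
`inject_artifacts`). What it emulates, and the defaults:

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `n_low`, `n_high` | 13, 6 | subjects | the study's group split (68% controlled) |
| `cvr_mean/sd` low | 6.8, 5.0 | cm/s | published stroke-affected CVR, controlled group |
| `cvr_mean/sd` high | 0.9, 3.7 | cm/s | published stroke-affected CVR, hyperglycemic group |
| `rest_mcav_mean/sd` | 55, 15 | cm/s | spans the published resting baselines (~51–75) |
| `tau` | 30 | s | typical MCAv on-kinetics time constant at moderate intensity |
| `time_delay` | 5 | s | short cardiodynamic delay before the rise |
| `pulsatility_amp` | 15 | cm/s | systolic-diastolic excursion of similar magnitude to clinical TCD traces |
| `noise_sd` | 2 | cm/s | beat-scale measurement noise after envelope extraction |
| `hemi_correlation` | 0.7 | — | bilateral concordance of baseline and response |
| `n_bouts` | 2 | — | the protocol's repeated-bout design |

Design choices where the generator had latitude:

- **Kinetics.** The exercise rise is mono-exponential with delay. The
  parent protocol fits a nonlinear dynamic response model whose exact
  form is out of scope here; to keep validation model-agnostic, the
  ground-truth CVR is *defined* as the noise-free mean increment over
  the steady-state window, and the amplitude is scaled as
  `A = CVR / w̄` where `w̄` is the closed-form window mean of
  `1 − exp(−(t − 95)/τ)` (for the defaults, `w̄ = 0.98137`, so a CVR of
  7 cm/s needs `A ≈ 7.133`). Recovery is then exact by construction, up
  to smoothing error.
- **Distributions.** CVR within groups is Gaussian — the published
  summaries state only mean ± SD, and at these sample sizes the rank
  test is insensitive to the tail shape. HbA1c is uniform on 5.0–6.8%
  (low) and 7.2–11.0% (high), spanning the plotted clinical range.
- **Randomness.** One root seed; per-subject and per-bout substreams are
  derived by stable hashing of `(seed, subject_id, stream, bout)`, so
  enlarging one group never reshuffles existing subjects — a property
  the test suite pins down.
- **Artifacts.** Spikes are added at the systolic peak of a chosen
  cycle, so the cycle's peak velocity changes by exactly the configured
  magnitude (which must exceed 10 cm/s, the censoring threshold);
  short-RR events insert a spurious beat marker 0.1 s after an onset
  (10 Hz instantaneous rate). Every injection is logged with its time
  and kind, giving the censoring tests an exact oracle.

What the generator does **not** emulate: cerebral autoregulation and
CO2 reactivity dynamics, baroreflex coupling between MAP and MCAv,
probe-angle drift, or Doppler spectral-envelope physics. Passing the
recovery and power checks therefore shows the *computational* chain is
correct and well-calibrated — not that the physiological model captures
real TCD data in full.

## Numerical choices and degenerate inputs

- Thresholds (5 Hz, 10 cm/s, 15%) are strict inequalities throughout.
- An acquisition whose every cycle is censored, an empty analysis
  window, a non-positive resting MCAv, or a subject with zero surviving
  bouts each raise an error naming the stage; the pipeline removes the
  subject and conserves counts (`subjects_out + excluded =
  subjects_in`).
- Interpolation never extends beyond the convex hull of surviving
  beats; all-missing blocks stay missing through both smoothing stages.
- The exact Mann–Whitney enumeration is capped at 2e6 permutations
  under ties (far above anything the study sizes need); beyond it the
  exact p is `NA` with a warning rather than a silent approximation.

## Validation scale

The shipped tests validate at deliberately modest problem sizes chosen
to make the suite comfortably reproducible: noise-free recovery on 4
subjects at the full 500 Hz (tolerance 0.1 cm/s; observed error is
~100× smaller), generator calibration on 2,000 subjects per group
(within 3 standard errors of the target mean and SD), operating
characteristics of the exact test over 500 simulated cohorts at the
published effect sizes (power ≈ 0.65–0.70; null rejection compatible
with the exact test's attainable size of 0.046 at n = 13/6), and
brute-force agreement of the exact U null distribution for all group
sizes up to 8.

## Known limitations

- The steady-state-window anchoring and the RR-rule interpretation are
  documented conventions, not certainties about the original analysis;
  both are single configuration fields (`ss_window`, `rate_max_hz`) so
  sensitivity reruns are one-line changes.
- Published group means/SDs of the real cohort, and the HbA1c–CVR
  correlation among diabetic participants, depend on recordings that
  were never deposited; the package calibrates its generator to those
  summaries instead of claiming to reproduce them.
- Beat detection itself is out of scope: beat onsets are an input
  channel, as delivered by standard acquisition hardware.
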