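---
title: "Models and methods behind pharmfc"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind pharmfc}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pharmfc)
```

# Scope and study design

`pharmfc` analyses pharmacological resting-state fMRI experiments in
which a drug is injected during a continuous acquisition. The default
design, to which all defaults in the package are keyed, is an 80-minute
run sampled at TR = 1 s (4800 volumes): 20 minutes of baseline, a vehicle
injection, 30 minutes of vehicle condition, a drug injection, and a final
30 minutes. Two genotypes of n = 7 animals each are compared: a responder
("WT") and a receptor-deficient non-responder ("KO"). The pipeline starts
at ROI time series; spatial preprocessing (registration, smoothing,
atlas normalization) is out of scope, though ROI extraction from
already-registered labeled 4D volumes is provided.

# Temporal preprocessing

Each ROI series is (1) polynomial-detrended (default linear), (2)
residualized against nuisance regressors (pseudo WM/CSF series, motion
parameters — any matrix the caller supplies), and (3) band-pass filtered
to 0.008–0.1 Hz with a zero-phase forward–backward 4th-order Butterworth
filter. Steps 1–2 are carried out as a single least-squares projection so
the nuisance fit is not confounded by drift; filtering comes last so
filtered drift is not reintroduced. The order detrend → regression →
filter is fixed; zero-phase filtering is used because any phase delay
would shift windowed-correlation timing. Collinear nuisance columns are
dropped with a warning. A second application of the operator changes the
series only through filter edge effects, which is why the idempotence
test compares the central portion of the run.

# Condition segmentation

The run is split into `baseline = [0, vehicle_onset)`,
`vehicle = [vehicle_onset, drug_onset)` and `drug = [drug_onset, end)`,
each divided into consecutive 10-minute intervals (2 + 3 + 3 under the
default design). Intervals are half-open in sample space and the sample
acquired at an injection time belongs to the post-injection interval.
Spans that are not divisible by the interval length are an error rather
than silently producing partial intervals.

# Static and dynamic connectivity

Edge connectivity is Pearson's r per interval, mapped to Fisher z =
atanh(r) before any statistics (correlations with |r| ≥ 1 − 1e−7 are
clamped, with a warning). Group matrices are averaged in z space and
inverse-transformed only for display. "FC variability" is defined here as
the population variance (denominator N) of the pooled upper-triangle z
values over a condition's intervals — one scalar per animal, entering a
two-sample genotype t-test with df = n1 + n2 − 2. An alternative
definition (variance across sliding windows) would capture faster
fluctuations; the pooled-interval variance was chosen because it yields
exactly one scalar per animal per condition, matching the degrees of
freedom of the genotype comparison it feeds.

Dynamic FC uses a 300-s rectangular (unweighted) window stepped by one
TR. The window-count convention is `n_windows = n_t − W`: a 4800-sample
run yields exactly 4500 windows and the final sample is never a window
start. The inclusive convention would give 4501; the adopted one is kept
deliberately and asserted in the tests. A window equal to the full series
is an error (zero windows). For large ROI counts the stack need not be
materialized: `dfc_apply()` streams window-wise, and `global_fc_series()`
uses it, so memory stays flat in the number of windows. Global FC per ROI
and window is the sum of off-diagonal z entries of that window's matrix.

# The drug contrast and artifact exclusion

The drug-specific test compares, per edge and animal, z in the *first
post-drug interval* against the mean of the *terminal vehicle* and
*terminal drug* intervals. Using the terminal intervals as reference
(rather than baseline) cancels slow time-in-scanner drifts in FC; using
both conditions' terminal intervals centers the reference on the
post-injection state. Per edge, a paired t-test (t = mean/(sd/√n),
df = n − 1, two-sided) is Benjamini–Hochberg corrected. Two thresholds
are exposed and deliberately not reconciled: q = 0.01 (the default for
edge discovery) and q = 0.05; both appear in the source experimental
practice and the choice is a config parameter, not a hidden constant.

Injection-common effects are removed by a mirrored vehicle contrast
(first post-vehicle interval vs mean of terminal baseline and terminal
vehicle intervals): an edge significant in *both* contrasts *with the
same direction* is flagged as an injection artifact and excluded from the
significant set. Direction matching makes the exclusion conservative — an
edge that moves opposite ways after the two injections is evidence of a
drug-specific effect, not an artifact. The mirrored construction is the
package's own design; only the exclusion *principle* (effects following
both injections are not drug effects) is inherited from experimental
practice. Degenerate edges (zero variance across animals) are flagged and
given p → 0 or p = 1 as appropriate rather than dropped silently.

# Group ICA and spectral statistics

Group spatial ICA concatenates the animals' runs in time, centers each
ROI, whitens the ROI dimension to `n_comp` principal dimensions, and
unmixes by symmetric fixed-point FastICA with the logcosh (negentropy)
contrast — the package's own implementation, deterministic given the
seed, with random orthonormal initialisation, symmetric decorrelation,
and tolerance 1e−5 / 200 iterations (non-convergence produces a warning,
not an error, matching common practice). Components are ranked by
explained variance (mixing-column energy), maps are unit-normalized with
the maximum-magnitude feature positive, and per-animal time courses are
obtained by applying the unmixing to each run (back-projection).

Because visual identification of "meaningful" components is not
reproducible, `flag_components()` applies two stated criteria instead: a
component is excluded if its time course correlates > 0.6 |r| with a
nuisance regressor or if > 50% of its map energy sits in one feature.

Component amplitude per condition is the within-condition standard
deviation of the time course (RMS about zero is exposed as an
alternative). Spectra use Welch's method — mean-removed, Hann-tapered
256-s segments with 50% overlap, averaged one-sided periodograms in
signal²/Hz. The 256-s default resolves ~0.004 Hz, comfortably below the
slow-5 lower edge at 0.01 Hz, while still averaging ≥ 12 segments per
30-minute condition. Band powers are trapezoidal integrals over slow-5
(0.01–0.027 Hz), slow-4 (0.027–0.073 Hz) and slow-3 (0.073–0.1 Hz), with
linear interpolation at band edges so adjacent bands tile exactly;
vehicle-vs-drug comparisons are paired t-tests per genotype.

# The synthetic cohort generator

The generator is the package's ground-truth instrument, and its defaults
*are* the study conditions: 7 animals per genotype, 30 ROIs, TR = 1 s,
4800 samples, injections at 1200 s and 3000 s.

**Construction.** Signals are mixtures of latent factors — one global,
one per community block, one per special edge, one unique per ROI — all
low-pass filtered to < 0.1 Hz and standardized, combined with
*time-varying loadings*. Because the construction is a factor model, the
instantaneous covariance is positive semi-definite at every sample by
construction (a per-window Cholesky approach would need explicit
projection and can produce non-smooth covariance paths). Unique-factor
loadings shrink as effect loadings grow so every ROI keeps unit signal
variance; configurations whose effect loadings exceed the available
variance are rejected as non-PSD. On top of the unit-variance signal the
generator adds per-ROI polynomial drift, two pseudo WM/CSF confound
series shared across ROIs (returned per animal for nuisance regression),
optional global spikes, and white measurement noise (SD 0.2).

**Drug response.** Modulated edges follow the envelope
e(t) ∝ (1 − exp(−t/τ))·2^(−t/h), normalized to peak 1, with rise τ = 60 s
and decay half-life h = 780 s — the ~13-minute circulating half-life of a
fast-acting satiation hormone. The peak time has the closed form
`drug_envelope_peak_time()`; well past the peak the envelope halves every
h, which the tests assert analytically.

**Injection artifacts.** After *both* injections and in *both* genotypes:
a multiplicative global amplitude transient (decay 30 s, hard cutoff
120 s) — which raises signal variance without changing correlations, as a
common gain must — and a fixed set of three spurious edges shifted for
exactly one 600-s interval. The spurious edges are what the
artifact-exclusion rule must catch; the amplitude transient contributes
the vehicle-condition variance rise seen in both genotypes.

**Oscillators.** One coherent sinusoid per slow band (0.018, 0.050,
0.085 Hz) with random per-animal phase is added to the last community
block; during the drug condition its amplitude is scaled by √gain, with a
default slow-5 *power* gain of 2.5 in WT only. Coherence across the block
is what lets group ICA isolate the oscillator community as a component.

**Randomness.** One root seed spawns per-animal child streams; WT and KO
animal k share the same child stream, so the knockout cohort is identical
to the responder cohort except for the genotype-conditional effects —
genotype differences in any statistic are then attributable to the
effects alone, not to sampling. Identical seeds give bit-identical
cohorts, and cohorts can be extended without resampling existing animals.

**Effect sizes.** The experimental literature reports only figure-scale
FC changes, so the effect scale was an open choice. It was fixed by a
design-time power analysis rather than by fidelity to any printed number:
a band-limited 600-s interval carries ≈ 2·B·T ≈ 110 effective samples
(B ≈ 0.092 Hz), giving a per-animal Fisher-z SD of ≈ 0.12 for the paired
contrast; with df = 6 and a BH threshold near |t| ≈ 8 at q = 0.01 over
435 edges, reliable (≥ 95% per-edge power) recovery requires peak
Δz ≈ 0.8–1.0. Defaults are therefore Δr = ±0.70 on drug edges and +0.70
on artifact edges over a 0.10 between-block baseline, with within-block
baseline correlation 0.25 so the factor loadings stay within the
unit-variance budget. Smaller effects (Δr ≈ 0.3) are simply not
detectable at q = 0.01 with n = 7 under this design — a statement about
the design's power, verified by the same analysis, not about the code.

**What the generator does not emulate.** Anatomically realistic atlas
geometry, hemodynamic convolution (signals are already band-limited;
an optional smoothing flag exists), aliased physiological rhythms,
motion-correlated artifacts, sex effects, and between-animal
heterogeneity of effect size. Passing tests therefore demonstrate that
the analysis recovers effects *of the modeled kind* at realistic noise
levels — not that real data meet the model's assumptions.

# Numerical choices and degenerate inputs

* Correlations are clamped at |r| = 1 − 1e−7 before atanh; constant ROIs
  give NaN edges with warnings, and NaN edges are excluded pairwise from
  group means with a count.
* The z-space diagonal is excluded (NA), so global FC and variability
  never mix self-connectivity into sums.
* BH adjustment excludes non-finite p-values and reports how many.
* `n_comp` above the data rank is reduced with a warning; eigenvalues
  below 1e−10 of the largest are treated as rank-deficient.
* Welch segments longer than the series fall back to one segment with a
  warning rather than erroring.

# Problem sizes used in the validation suite

The test suite exercises the full default design (14 animals, 30 ROIs,
4800 samples) for the recovery properties, 20 seeds for the
majority-vote phenotype checks, and 200 null cohorts of 32 ROIs (496
edges) for empirical FDR control; oracle tests use small random inputs
(e.g. 5×50 matrices, 512-sample spectra) where brute-force references are
exact. These sizes were chosen to keep each property's Monte-Carlo error
well below its assertion margin.

# Known limitations

* The vehicle-mirror artifact contrast has lower power than the drug
  contrast when few artifact edges exist (its adaptive BH threshold is
  stricter), so very weak injection artifacts may escape flagging.
* FC variability is interval-based; window-based variability would be
  needed to study sub-interval dynamics.
* Group ICA operates on ROI features in the default pipeline; voxel-level
  decompositions are possible only via the volume input path.
* The pipeline assumes a single vehicle and a single drug injection per
  run; crossover or repeated-dosing designs are out of scope.
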