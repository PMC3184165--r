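---
title: "Methods: MALDI imaging MS of prodynorphin peptides in experimental dyskinesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MALDI imaging MS of prodynorphin peptides in experimental dyskinesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdynims)
```

## The scientific problem

In the unilateral 6-OHDA rat model of Parkinson's disease, chronic L-DOPA
treatment induces abnormal involuntary movements (dyskinesia, rated as AIM
scores). Opioid peptides derived from the precursor prodynorphin —
dynorphin B, alpha-neoendorphin, and their bioconversion products such as
Leu-enkephalin-Arg — are expressed by striatonigral projection neurons and
released in the substantia nigra (SN). `pdynims` implements a desk-scale,
fully testable version of the analysis that links spatially resolved
peptide levels in the SN, measured by MALDI-TOF imaging mass spectrometry
(IMS), to dyskinesia severity: spectral preprocessing, peak quantification,
region-of-interest (ROI) statistics with a duplicate-run covariate,
mass-based peptide annotation, behavioral scoring, and peptide–behavior
correlation — plus a synthetic-data generator that plants known effects so
that every stage can be verified against ground truth.

## Data model

A `mass_spectrum` is a pair of aligned arrays (strictly increasing m/z in
daltons, non-negative intensities). An `ims_section` is one tissue section
in one analysis run: a grid of matrix spots at 250 µm spacing, each with a
spectrum and a hemisphere label (`intact` / `lesioned`). Experiments are
duplicated on consecutive sections (`run_id` 1 or 2). ROI masks assign
spots to `SN_medial`, `SN_lateral` or `other`; hemisphere labels are data,
never inferred from image geometry, because left/right conventions vary
across animals and imaging setups.

Two on-disk dialects are provided: a minimal continuous-mode imzML
writer/reader (shared m/z axis, little-endian doubles in the `.ibd`
companion) for interoperability, and a human-readable CSV/JSON pair that
round-trips bit-exactly (doubles serialized at 17 significant digits) and
serves as the fixture format for tests.

## Peptide mass calculus

Theoretical peak positions are singly protonated monoisotopic masses,

$$[M+H]^+ = \sum_i m_{\text{res}}(a_i) + m_{\mathrm{H_2O}} + m_{\mathrm{H^+}}
  \;(+\,\Delta_{\text{amide}}),$$

with standard residue monoisotopic masses, water 18.010565 Da, proton
1.007276 Da, and the C-terminal amidation change −0.984016 Da (substance
P). The shipped catalog covers the classical prodynorphin products —
Dyn A(1–17), Dyn A(1–8), Dyn A(10–17), Dyn B, alpha/beta-neoendorphin —
and the bioconversion fragments Leu-Enk, Leu-Enk-Arg, Leu-Enk-Arg-Arg,
aNeo(1–7) and the des-tyrosine metabolites (N-terminal Tyr removal, the
inactivating conversion, exactly 163.0633 Da lighter). Integer peak labels
follow the truncation convention, which reproduces the commonly printed
712 (Leu-Enk-Arg), 840 (aNeo 1–7), 981 (Dyn A 1–8) and 1347 (substance P).
Three catalog entries (Leu-Enk 555, Leu-Enk-Arg-Arg 867, Dyn A(1–17) 2145)
are commonly printed with integer m/z that no rounding convention of the
computed masses reproduces (556.28, 868.48, 2147.20); the catalog stores
full-precision values and flags these entries in a `note` column rather
than guessing the intent. Annotation (`annotate_peaks()`) matches observed
m/z against the catalog within a tolerance (default 0.3 Da, matching
unit-resolution TOF bins), sorted by absolute ppm error.

## The processing chain

The stage order is fixed and mirrors standard IMS practice: baseline →
normalization → alignment → peak detection → binning → integration.

**Baseline.** The lower convex hull (greatest convex minorant) of the
(m/z, intensity) points is subtracted. Constant, linear and convexly
decaying backgrounds are removed exactly; both endpoints map to zero, and
the operation is idempotent.

**Normalization.** Each spectrum is scaled so its total ion current (TIC)
equals a common target (by default the section's mean raw TIC, keeping
intensities on a familiar scale). Sections whose raw TIC is uneven across
spots — coefficient of variation above a threshold, default 0.5 — or that
contain empty spectra fail QC and are excluded before normalization; the
threshold is configuration because no standard value exists.

**Alignment.** One rigid m/z shift per spectrum is estimated by maximizing
the correlation of the spectrum with Gaussian templates at reference peak
positions, searched on a 0.01 Da grid, then applied by linear
interpolation. TOF drift over this mass range is locally rigid, so a
single shift parameter (no stretch) is used; it is testable by planting
known shifts, which are recovered within ±0.05 Da. Estimates at the search
boundary are flagged `clamped`; spectra containing no reference peak are
returned unshifted and flagged.

**Peak detection.** Peaks are strict local maxima with S/N > 3. Both the
local baseline level (window median) and noise (median absolute deviation
× 1.4826) are estimated over a sliding 201-sample window centred on each
candidate; S/N is the apex height above the window median divided by the
noise. For a zero-centred residual this reduces to apex/noise, but it
stays calibrated when the hull baseline leaves the small positive offset
it necessarily does on noisy data (the hull tracks the minima of the noise
band, roughly 2.5 standard deviations below its centre). The windowed
statistics are computed in C; the test suite checks the implementation
against an exhaustive pure-R scan of every local maximum.

**Binning.** Apex m/z values pooled across spectra are sorted and scanned
once: a new bin opens whenever the next apex is more than `tol` (default
0.3 Da) from the running mean of the current bin. Centers are member
means; half-widths cover the member spread with a floor of `tol`/2, capped
so adjacent bins never overlap. On well-separated clusters this greedy
pass coincides with single-linkage clustering cut at `tol`, which the
tests use as an oracle. Sporadic noise peaks are removed by requiring a
bin's member count to reach half the spot count (`min_bin_frac`). No
deisotoping is performed: isotope peaks, when present, form separate bins.

**Integration.** Per spot and bin, the trapezoidal area over
center ± half-width (floored at 0.25 Da — about 4 peak standard deviations
at the synthetic TOF width, so truncation error is negligible). Bins
outside a spectrum's mass range are recorded as missing (`NA`), never
zero.

## ROI geometry and summaries

The SN ROI is divided into medial and lateral halves by the perpendicular
bisector of the segment from the ventromedial to the dorsolateral corner;
spots exactly on the boundary go medial (fixed tie rule). This is one
reading of "bisecting a line between the corners" — the wording is
ambiguous, and the chosen semantics is pinned by a signed-distance oracle
test. Summaries are arithmetic means of spot areas per (region,
hemisphere, bin), always reported with spot counts so imbalance stays
visible. Effects are expressed as `percent_of_intact()` — lesioned mean as
% of the intact mean, so 144 means "44% higher". Ion images place areas on
the section grid with missing spots masked, never imputed, and no
smoothing; RGB composites min-max scale each channel per image (a constant
channel renders at 0.5 rather than dividing by zero range).

## Statistics

The tested quantity per bin is the log2 ratio of lesioned to intact ROI
mean within each section — the paired-within-animal form that matches the
"% of intact side" reporting and cancels per-animal scale. The model is
ordinary least squares with treatment group (dummy-coded, lesion control
as reference) and analysis run as covariates; p-values come from the
t-test on the contrast of interest and are corrected across bins by
Benjamini–Hochberg step-up (α = 0.05, two-sided throughout). No
empirical-Bayes variance moderation is applied: at 4–5 animals per group
the plain OLS t-test is transparent, exactly calibrated under the
generator's lognormal noise, and easy to verify (on a two-group design it
reduces exactly to the pooled t-test; a balanced batch offset leaves the
treatment estimate unchanged to machine precision).

Peptide–behavior association uses Pearson correlation (two-sided t-based
p) with the least-squares line reported alongside; duplicate runs are
averaged within animal first (config switch `average_runs`). Group
comparisons use one-way ANOVA with Tukey HSD; dyskinesia trajectories use
two-way mixed (split-plot) ANOVA — between factor group, within factor
session — with per-session two-sample t-tests Bonferroni-corrected by the
number of sessions.

## Behavioral scoring

AIM sessions score four categories (limb, axial, orolingual,
rotational/locomotor) 0–4 at each rating timepoint (1-min observation
every 20 min; nine timepoints per session by default); the session score
is the plain sum, and the cumulative score sums all eight sessions (rated
every other day over the 15-day treatment, days 1, 3, …, 15). All four
categories are included by default, with an option to drop the locomotor
category, a common variant. The cylinder test records left/right forelimb
wall touches (design target 20); inclusion requires strictly less than 30%
left-forelimb use. Trajectories are least-squares lines score = m·day + b;
`predict_day_to()` returns (threshold − b)/m. With the low-dyskinetic
parameters (m = 0.68, b = 0.41) and the high-dyskinetic offset 29.94 as
threshold this gives 43.4 days; the value sometimes quoted as "about 42
days" is not exactly reproducible from those coefficients, and the
function returns the formula value.

## The synthetic cohort and what it does (not) show

The generator's defaults are the study conditions: 14 animals (4 lesion
controls, 5 low-, 5 high-dyskinetic), duplicate runs, 250 µm grids, 30%
CV lognormal noise on per-spot peak areas, and the planted high-dyskinetic
lesion-side folds — Dyn B 1.75 lateral / 1.44 whole-SN, aNeo 1.54 / 1.26,
Leu-Enk-Arg 1.5 lateral (this last is a package default, no literature
value exists). Medial folds follow from the whole-SN and lateral targets
by weighted-mean algebra given the spatial pattern. All other species,
including substance P and the des-Tyr forms, are true nulls.

Choices made once and documented here rather than tuned:

* **Grid 8 × 6 spots per section** (2 × 1.5 mm at 250 µm), giving 12 spots
  per hemisphere-region — a realistic SN footprint.
* **Peak width σ = 0.06 Da, axis step 0.05 Da** over m/z 500–2200:
  reflector-TOF-like resolution; the trapezoid rule is essentially exact
  at this sampling.
* **40 inert background species** carrying ~99% of the TIC, so TIC
  normalization perturbs planted ratios by well under 1% (as in real data,
  where a thousand species dominate the ion current).
* **Severity coupling:** one latent Gaussian per animal enters both the
  behavior offset (gain 2 score units) and the planted log2 folds (sd
  0.1), with a second independent latent mixed in to set the target
  correlation (default ρ = 0.8) — the simplest construction with a
  tunable correlation.
* **Lesioned-region amplitudes are renormalized** so realized region-mean
  folds equal the planted targets exactly; the dorsolateral "conversion
  patch" (locally high Leu-Enk-Arg where Dyn B is locally low) then adds
  spatial texture without biasing region-level effects.
* **Trajectory noise:** session-score noise sd 1.5, and between-animal
  slope spread sd 0.3 score/day around the group-mean slopes (the printed
  slope uncertainties imply substantial animal-to-animal spread; without
  it, the small 0.68 vs 0.81 group difference would register as a
  spurious time-by-group interaction).

Two output tiers share this machinery: full spectra (`level = "spectra"`),
exercised by the noiseless end-to-end recovery test, and per-spot areas
(`level = "areas"`), used for the Monte-Carlo statistical checks (effect
coverage over 200 seeds, correlation recovery over 500 seeds, null false
discovery rate over 200 replicates) where simulating raw spectra would add
nothing but runtime. These sizes keep the full suite within minutes on one
CPU while leaving the Monte-Carlo error small relative to the tested
tolerances.

The generator emulates grid geometry, Gaussian peaks at exact catalog
masses, convex chemical baseline, white noise, per-spectrum TIC scale and
rigid m/z jitter. It does **not** emulate physically realistic TOF peak
shapes, detector saturation, matrix cluster ions, isotope envelopes (off
by default), spatial autocorrelation between neighbouring spots, or
anatomically realistic ROI boundaries. Passing tests therefore demonstrate
correctness of the computational chain under controlled conditions, not
performance on real instrument data.

## Numerical and degenerate-input conventions

Zero-TIC spectra are QC failures, not normalizable inputs. Empty peak
lists and empty bins are legal; integration windows with no signal are 0,
windows outside the mass range are `NA`. ANOVA with zero between-group
variation reports F = 0, p = 1 rather than 0/0. Correlation of a constant
vector is an error ("undefined correlation"), as is des-Tyr of a peptide
without an N-terminal tyrosine. All generators and the pipeline are
bit-deterministic under a fixed master seed, with derived per-animal seeds
recorded in the output.

## Known limitations

Mass-based annotation cannot distinguish isobaric peptides (Leu/Ile are
identical by mass); MS/MS identification is out of scope. The linear model
treats runs as fixed batches, not random effects. The medial/lateral split
assumes the ROI is convex enough that the perpendicular bisector is
meaningful. The pipeline does not deisotope; real spectra would contribute
isotope bins that mass annotation would leave unnamed.
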