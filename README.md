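# pdynims

MALDI-TOF imaging mass spectrometry (IMS) analysis of prodynorphin-derived
neuropeptides in the substantia nigra (SN) of the unilateral 6-OHDA rat
model of L-DOPA-induced dyskinesia — as a tested, reusable R package.

Striatonigral neurons release prodynorphin products (dynorphin B,
alpha-neoendorphin, and bioconversion fragments such as Leu-Enk-Arg,
YGGFLR, m/z 712) into the SN. `pdynims` is for researchers who want to
quantify such peptides spot-by-spot across a tissue section and relate
them to behavioral severity. It implements:

* **Peptide mass calculus** — monoisotopic \[M+H\]⁺ from sequence,
  `[M+H]+ = Σ residue masses + H₂O + H⁺ (+ amidation Δ)`, des-Tyr
  metabolite generation (−163.0633 Da), and tolerance-based annotation
  against a shipped prodynorphin catalog.
* **Imaging data model and I/O** — per-spot spectra on a 250 µm grid with
  hemisphere labels (intact/lesioned), minimal continuous-mode imzML plus
  a bit-exact CSV/JSON dialect, and TIC-based section QC.
* **Spectral processing** — convex-hull baseline correction, total-ion-
  current normalization, rigid m/z alignment, S/N > 3 peak detection with
  windowed robust (median/MAD) noise estimation, greedy cross-spectrum
  m/z binning, and trapezoidal peak-area (AUC) integration.
* **ROI analysis** — SN medial/lateral split by the perpendicular bisector
  of the ventromedial–dorsolateral diagonal, per-region/hemisphere means,
  ion images and RGB composites, "% of intact side" effect reporting.
* **Statistics** — per-bin OLS of log2(lesioned/intact) on treatment group
  plus analysis run, Benjamini–Hochberg FDR, Pearson peptide–behavior
  correlation, one-way ANOVA + Tukey HSD, and Greenhouse–Geisser-corrected
  repeated-measures ANOVA.
* **Behavior** — AIM dyskinesia scoring (four 0–4 categories per
  timepoint), cumulative scores, cylinder-test asymmetry with the <30%
  inclusion rule, and linear trajectory fits `score = m·day + b`.
* **A synthetic-cohort generator** — 14 animals (4 lesion controls, 5 low-
  and 5 high-dyskinetic), duplicate runs, 30% CV peak-area noise, planted
  lesion-side folds (Dyn B ×1.75 lateral / ×1.44 whole-SN; aNeo ×1.54 /
  ×1.26) and a latent-severity coupling (target ρ = 0.8) — with full
  ground truth, so every stage is verifiable without any instrument data.

## Worked example

Simulate the default study at the peak-area tier and run the full
differential analysis:

```r
library(pdynims)
res <- run_pipeline(pipeline_config(list(level = "areas")),
                    out_dir = "pdynims_out", seed = 42, quiet = TRUE)
subset(res$results, annotation %in%
       c("Dyn B", "aNeo", "Leu-Enk-Arg", "Substance P"))
```

```
     mz  annotation  effect        p    p_adj significant
    712 Leu-Enk-Arg  0.6284 1.28e-07 6.49e-07        TRUE
   1229        aNeo  0.7362 1.39e-07 6.49e-07        TRUE
   1348 Substance P -0.0853 2.33e-01 6.53e-01       FALSE
   1571       Dyn B  0.9536 1.53e-10 2.14e-09        TRUE
```

`effect` is the high- vs low/control-group difference in
log2(lesioned/intact lateral-SN mean); for Dyn B the estimate 0.95 ≈
log2(1.75) + this cohort's severity modulation, and the planted nulls
(substance P, Dyn A species, des-Tyr forms) stay non-significant after
BH adjustment. `res$correlations` holds the per-bin Pearson correlation of
per-animal lateral peak areas with cumulative dyskinesia scores; in this
cohort Dyn B correlates at r = 0.97 while substance P sits at r = 0.08.

Single computations are just as accessible:

```r
monoisotopic_mh("YGGFLR")        # 712.3777  (Leu-Enk-Arg)
annotate_peaks(712.38)           # -> Leu-Enk-Arg, delta 3.2 ppm
predict_day_to(fit_trajectory(seq(1, 15, 2),
               0.68 * seq(1, 15, 2) + 0.41), 29.94)  # 43.4 days
```

## Documentation

The methods vignette (`vignettes/peptide-imaging-methods.Rmd`) documents
the models, the processing chain, every tunable parameter with its default
and rationale, what the synthetic generator does and does not emulate, and
known limitations. A thin command-line wrapper for simulation and full
runs is provided at `inst/cli/pdynims.R`.
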