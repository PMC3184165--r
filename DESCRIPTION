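Package: pdynims
Title: MALDI Imaging Mass Spectrometry Analysis of Prodynorphin Peptides in
    Experimental Dyskinesia
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for MALDI-TOF imaging mass spectrometry of
    neuropeptides in the unilaterally dopamine-denervated rat brain. Provides
    exact monoisotopic mass calculus and tolerance-based annotation for
    prodynorphin-derived peptides (dynorphins, neoendorphins and their
    bioconversion products), an imaging data model with imzML and plain-text
    readers, the spectral processing chain (convex-hull baseline correction,
    total-ion-current normalization, rigid spectrum alignment, signal-to-noise
    peak detection, cross-spectrum m/z binning and trapezoidal peak-area
    integration), substantia-nigra medial/lateral region-of-interest geometry
    and ion-image rendering, per-bin differential statistics with a run
    covariate and Benjamini-Hochberg correction, abnormal-involuntary-movement
    (AIM) dyskinesia scoring and cylinder-test asymmetry, and a synthetic-cohort
    generator with planted effect sizes and ground truth for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite,
    data.table,
    xml2,
    yaml,
    png,
    pracma
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
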