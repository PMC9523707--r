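---
title: "Untargeted and targeted fingerprinting of GC×GC-TOF MS volatilomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted and targeted fingerprinting of GC×GC-TOF MS volatilomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Comprehensive two-dimensional gas chromatography with time-of-flight mass
spectrometry (GC×GC-TOF MS) separates a headspace volatilome on two coupled
columns: a slow first dimension (retention time ${}^1t_R$, minutes) and a
fast second dimension re-injected every modulation period $P_M$
(${}^2t_R \in [0, P_M)$, seconds; $P_M = 3.5$ s here, sampled at up to
100 Hz over nominal m/z 35–350). A study of fermented maize silage — two
dry-matter levels, an untreated control and two lactic-acid-bacteria
inocula (*Lentilactobacillus buchneri*, *Lacticaseibacillus paracasei*),
plus quality-control mixtures, 35 runs in all — produces a stack of such
data cubes. The analysis question is which volatiles (free fatty acids,
alcohols, their esters, phenols, terpenoids, ...) distinguish the classes.

`gcxgcfp` implements the combined **untargeted + targeted (UT)
fingerprinting** workflow for this design as reusable, tested R functions:

1. **Peak detection** (`detect_peaks()`): watershed segmentation of the
   lightly smoothed TIC raster, S/N gate at 100, apex spectrum from the
   largest data point of each footprint.
2. **Template alignment** (`build_template()`, `match_peaks()`): *reliable
   peaks* are those matched in all but one of the runs under a retention
   window and NIST-style spectral gates (DMF/RMF ≥ 750); a per-run
   polynomial retention transform (degree 2 in ${}^1t_R$, degree 1 in
   ${}^2t_R$) registers the runs.
3. **Composite chromatograms and peak regions**
   (`build_composite()`, `delineate_regions()`): the per-point mean of the
   aligned rasters, segmented into peak-region features; regions not covered
   by a template peak become untargeted features.
4. **Feature table** (`assemble_feature_table()`): features × samples 2D
   peak volumes, plus *% normalized responses* over the two preloaded
   internal standards.
5. **Targeting last** (`assign_template_identities()`): each template entry
   is identified against the packaged 268-analyte library by DMF > 900,
   RMF > 950 and a linear retention-index window of ±10 units.
6. **Chemometrics** (`fisher_ratios()`, `sieve()`, `pca_features()`,
   `correlation_clustered_heatmap()`, `response_ratio()`,
   `two_way_anova()`, `t_test_unpaired()`).
7. **Visual comparison** (`composite_class_image()`,
   `fuzzy_ratio_image()`): class composites and colorized fuzzy-ratio
   difference images.

Because no raw chromatograms are publicly deposited for this kind of study,
the package ships a first-class synthetic-study generator
(`study_design()`, `simulate_run()`, `simulate_study()`) so every stage is
testable offline, closed-loop.

## The identification library and its known quirks

`inst/extdata/target_library.csv` transcribes the published target table
verbatim: 268 analyte rows in ten chemical-class sections with CAS numbers,
${}^1t_R$/${}^2t_R$ and their %RSDs, experimental and tabulated linear
retention indices $I^T$, and per-analyte Fisher ratios. Known internal
inconsistencies of the printed table are preserved rather than repaired:
the prose total of 269 and the aldehyde count of 37 do not match the 268
rows / 36 aldehyde rows actually printed, and the two
3,5-octadien-2-one isomers share one CAS number (loading warns; the
retention-index gate separates them). Sentinels are typed, not coerced:
`"ND"` (Fisher ratio not determinable) and `"NC"`/`">2500"` (index not
computable / beyond the ladder) become flags so that downstream filters can
distinguish *missing* from *zero*.

Reference mass spectra are not available offline, so
`simulate_spectrum()` derives a deterministic stick spectrum (8–20
channels, base peak 999) from a hash of each CAS number through the
package's own multiplicative congruential generator. Over all library
pairs with distinct CAS, no cross pair reaches the 750 match-factor gate,
so identification behaves like a (very clean) spectral database.

## Match factors

`dmf()` and `rmf()` score two stick spectra on the conventional 0–999
scale with weighted sticks $s_k = I_k^{0.5}\,(m/z)_k^{1}$ (the
Stein–Scott-style exponents; both are arguments) and the squared cosine
over the union of channels, rounded half-up. The reverse factor restricts
the comparison to the reference's channels, which makes it tolerant of
matrix interferences in the analyzed spectrum. The exact variant used by
the commercial software is not documented, so the exponents are
configuration and the tests anchor the scores to an independent
brute-force evaluation instead of to a specific database.

## Retention indices

`retention_index()` uses van den Dool–Kratz linear interpolation between
bracketing n-alkane anchors (the oven ramp is linear); a missing homologue
is spanned by the corresponding multiple of 100 units, and times outside
the ladder are flagged rather than extrapolated, mirroring the table's
`">2500"`/`"NC"` convention. Because no measured alkane times are
published, `derive_alkane_ladder()` constructs a **synthetic** C9–C25
calibration by monotone interpolation of the library's own
$({}^1t_R, I^T)$ pairs; the median absolute residual of the library
against this ladder is below 3 index units, so the ±10 identification
window retains useful discrimination. The identification tolerance
defaults to ±10 units (the method's stated criterion); the table footnote
uses ±15, available via `it_tol`.

## The synthetic study generator

`study_design()` encodes the study conditions:

* **Layout** — 3 + 3 herbage replicates (two dry-matter levels), 6 each of
  control, *Lbuc* and *Lpar*, 6 QC mixtures, plus one analytical duplicate
  per biological class: 35 runs, acquisition order randomized by the seed.
  QC expectations are the arithmetic mean of the parent control
  expectations, mirroring their physical mixing.
* **Panel** — 40 library analytes spanning all ten classes (with the
  propionic-acid / 1-propanol / propionate-ester signature included), plus
  three non-library unknowns and the two internal standards. Members were
  chosen mutually resolvable at the generator's peak widths (pairwise
  retention separation > 4.5 combined SDs) and index-consistent with the
  derived ladder (|residual| < 5 units); real co-elution and deconvolution
  are out of scope.
* **Effects** — multiplicative class fold-changes planting the published
  signatures: propionic acid ×46 and 1-propanol ×9 in *Lpar* over herbage,
  isoamyl propionate ×45, ethyl nonanoate ×219, furfuryl alcohol ×15,
  isoeugenol ×22 in *Lbuc*, C6 aldehyde and xylene depletion in all
  silages, and so on (`default_effect_matrix()`). The acid/ester
  correlation structure (e.g. 1-propanol with propionic acid, r ≥ 0.9)
  emerges from these shared class effects alone; an optional
  `correlated` field can add run-level shared variation, but none is
  planted by default.
* **Noise** — responses carry multiplicative log-normal noise
  (`response_sdlog = 0.12`, the reported mean response %RSD scale);
  baseline noise is additive Gaussian truncated at zero (SD 5 counts).
  Retention jitter is a run-level multiplicative drift (relative SDs
  0.008 / 0.04, the reported retention %RSD scale) plus a small per-peak
  residual (0.01 min / 0.02 s). The run-level form matters: drift in a
  real sequence is systematic within a run, which is exactly what the
  template's retention transform corrects; fully independent per-peak
  jitter of 0.8% at 40 min would defeat any fixed search window.
* **Peaks** — separable 2D Gaussians, σ = 2.5 modulations × 0.06 s,
  integrated volume = base × effect × noise, per-point spectra
  proportional to the compound's reference spectrum; overlapping apexes
  superpose with a warning.
* **Problem size** — cubes use the instrument's $P_M = 3.5$ s and the full
  m/z 35–350 range but 20 Hz within-period sampling (70 points/period) and
  a 44.5 min window, keeping a full 35-run study around two minutes of
  desk-scale compute. All of the pipeline's thresholds are expressed in
  physical units (minutes, seconds, S/N), so nothing downstream depends on
  the sampling rate.

What passing closed-loop tests show — and what they do not: the generator
emulates the *statistical* structure the analysis assumes (jitter,
response noise, class effects, QC mixing). It does not model
chromatographic tailing, detector saturation, spectral skewing,
co-elution requiring deconvolution, or wrap-around at the period boundary,
so green tests certify the pipeline's logic, not instrument-grade
robustness.

## Numerical choices and degenerate inputs

* **Noise estimate** (`estimate_noise()`): 1.4826 × the median absolute
  deviation from the raster median, over the lower half of the values
  only — peaks inflate only the upper tail, so the estimate is stable even
  next to very large peaks. An all-constant raster returns 0 with a
  warning.
* **Detection**: smoothing uses a fixed small Gaussian kernel (1 modulation
  × 0.03 s); watershed ties resolve by EBImage's flooding order; the peak
  footprint floods down to `baseline + 2×noise SD` with a small
  fractional-height cap (0.1% of the apex by default). The floor is
  noise-referenced rather than a 5%-of-apex cut because a 2D Gaussian
  holds only 95% of its mass above a 5% contour; with the noise-referenced
  floor a noiseless planted peak integrates back to its volume within
  ~0.1%, and fold-change ratios are unaffected by the residual truncation
  since it is common to both classes. Heights are apex TIC above the flat
  baseline (the raster median); no rolling-ball correction is applied.
* **Apex spectra** are taken literally from the single largest data point
  of the footprint (the method's description is self-contradictory —
  "average ... from the largest data point" — and the single-point reading
  is adopted), with channels below 3× the per-channel noise floor zeroed.
* **Template building**: the seed run is the medoid (highest total matched
  DMF in a pilot all-versus-all pass); matching is greedy in descending
  DMF with each peak used at most once; the transform is refit once after
  dropping residuals beyond 3 robust SDs; entry coordinates update to the
  mean matched position. Entries must be matched in ≥ N−1 runs (the
  all-but-one rule) to be retained. Search windows default to ±0.30 min /
  ±0.20 s, roughly 3× the reported retention %RSDs at mid-run.
* **Unmatched responses** are recorded as 0 with a `missing` flag
  (absence below the S/N floor), and statistics include them as 0 by
  default — the absolute-response semantics of the original workflow; the
  flag allows exclusion.
* **Fuzzy-ratio rendering**: saturation $|d|/(|d|+\varepsilon)$ with
  $\varepsilon$ defaulting to 3× the composite noise SD (the method gives
  no quantitative "nearly equal" band), intensity $\log(1+|d|)$ scaled to
  the image maximum (a linear option exists). The hue–intensity–saturation
  composition is rendered onto a **white** background (equal rasters give a
  uniformly white image; classic dark-background hexcone rendering would
  give black at zero intensity). Differences are computed on the TIC
  raster; per-channel differencing is a documented extension, not
  implemented.
* **Sieve threshold**: the method quotes both $F_{crit}(4,8) = 3.84$ and
  "$F_{calc} > 4$"; the sieve default is the single parameter 3.84. The
  printed "α = 0.5" alongside 3.84 is inconsistent — 3.84 is the 5%
  critical value — and both are documented here; `f_critical()` computes
  either. The degrees of freedom (4, 8) are not derivable from the 35-run
  layout; the sieve therefore treats the threshold as a plain number and
  the null-rate tests match α to the actual layout.
* **Bonferroni post hoc** (`two_way_anova()`): pairwise pooled-variance
  t statistics on the residual mean square with α divided by the number of
  comparisons, summarized as compact letter groups (the method names the
  test, not the mechanics).
* **PCA "normalization"** is per-feature unit-variance autoscaling
  (configurable); constant features are dropped with a warning.

## Open choices made

* The exact biological × analytical split behind the 35 runs is not fully
  specified; the default layout (one analytical duplicate per biological
  class) is one documented plausible reading.
* Whether the untargeted features of the original study were regions only
  or also unidentified template peaks is ambiguous; both are emitted with
  `kind = "untargeted"`.
* Run containers are R serialization with a format tag — a self-describing
  single-file container that round-trips losslessly; ANDI/netCDF import is
  an extension point, not implemented.
* The `run_pipeline()` stage runner (simulate → detect → align →
  fingerprint → sieve → compare → stats) keeps no hidden state: every
  artifact lands on disk with a manifest line (stage, file, seed, MD5), and
  identical config + seed reproduce identical manifests.

## A small worked run

```{r, eval = FALSE}
library(gcxgcfp)

design <- study_design(seed = 1)      # the full 35-run layout
fs <- fingerprint_study(design)       # simulate -> detect -> align -> table

ft <- fs$feature_table
table(ft$features$kind)               # targeted / untargeted / is

# class-discriminating features and the Lpar signature
sieved <- sieve(ft, threshold = 3.84)
head(sort(response_ratio(ft, "lpar", "herbage_low"), decreasing = TRUE))

# visual comparison of class composites
tr <- attr(fs$template, "transforms")
geometry <- attr(fs$peak_sets[[1]], "geometry")
aligned <- lapply(seq_along(fs$rasters), function(j)
  gcxgcfp:::warp_raster(fs$rasters[[j]], tr[[j]], geometry))
lpar <- composite_class_image(aligned[fs$meta$class_label == "lpar"])
herb <- composite_class_image(aligned[fs$meta$class_label == "herbage_low"])
img <- fuzzy_ratio_image(lpar, herb, epsilon = 3 * estimate_noise(herb))
write_image_png(img, "lpar_vs_herbage.png")
```

Known limitations: single-ionization TIC processing only (no tandem
ionization), no co-elution deconvolution, no vendor file formats, no
reproduction of the original study's real-data statistics (its raw
chromatograms are not deposited) — the closed-loop simulations plant
analogous structure instead.
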