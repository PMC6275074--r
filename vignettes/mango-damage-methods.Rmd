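---
title: "Methods: hyperspectral assessment of impact damage in mango"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hyperspectral assessment of impact damage in mango}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dropped mangoes bruise. The bruise is invisible at first, but the damaged
tissue ripens faster: pulp firmness (PF) and titratable acidity (TA) fall,
total soluble solids (TSS) and flesh yellowness (chroma, $\Delta b^*$) rise,
and all four move faster the greater the drop height. Near-infrared
hyperspectral imaging (900--1700 nm) sees these compositional changes in the
bruised region, so a line-scan camera plus chemometric models can grade
impact damage non-destructively.

`mangohsi` implements that pipeline end to end:

1. **Imaging**: ENVI-style cube I/O, dark/white reflectance calibration
   $R = (I_0 - B)/(W - B) \times 100$, conversion to absorbance
   $A = \log_{10}(100/R)$, and mean spectra over a bruise region of
   interest (ROI).
2. **Preprocessing**: Savitzky--Golay smoothing (S-G), standard normal
   variate (SNV) and multiplicative scatter correction (MSC).
3. **Regression**: NIPALS PLS1 per quality attribute, leave-one-out (LOO)
   cross-validation for the component count, a 3/5--2/5
   calibration/validation split, and $R^2$/RMSEP reporting.
4. **Wavelength selection**: competitive adaptive reweighted sampling
   (CARS) around the PLS models.
5. **Damage grading**: a ripening index
   $\mathrm{RPI} = \ln(100 \cdot \mathrm{PF} \cdot \mathrm{TA} /
   \mathrm{TSS})$ thresholded into slight ($>7$), moderate ($[5, 7]$) and
   serious ($<5$) classes, classified from CARS-selected spectral variables
   by Fisher discriminant analysis (DA) with a 3/4--1/4 split.
6. **Synthetic data**: a generator that emulates the drop-test study design
   so every stage is testable without instrument data.

# Models and conventions

## Calibration and spectra

Cubes are `(line, sample, band)` arrays. White/dark references may be full
cubes or per-line `samples x bands` frames (line-scan practice); 2-D frames
broadcast across lines. Pixels with $W - B \le 10^{-6}$ (dead or saturated)
are masked `NA` and excluded from ROI means. ROI masks are plain 0/1 CSV
grids so they stay portable; the coordinate convention is `(line, sample)`
with bands indexed by grid position. The ENVI dialect covers BIL/BIP/BSQ
interleaves, little-endian byte order and data types 4 (float32) and
12 (uint16), with wavelengths read from the `wavelength` header field.
Whether models run on percent reflectance or absorbance is a config choice;
the default is absorbance (log 1/R), which is also what the generator emits.

## Preprocessing

* **S-G**: local polynomial least squares; defaults window 11, order 2 —
  conventional smoothing choices, configurable. Edges are smoothed by the
  polynomial fitted to the leading/trailing window (mirror-free).
* **SNV**: per-spectrum centering and scaling. The *sample* standard
  deviation ($n-1$) is the pinned convention.
* **MSC**: each spectrum is regressed on a reference by OLS over bands and
  corrected as $(x - a)/b$. The reference is the calibration-set mean,
  frozen at fit time, so validation spectra never leak into it.

SNV is the pipeline default; S-G and MSC remain selectable for the
preprocessing comparison experiment.

## PLS regression

PLS1 per attribute (four separate models rather than one multi-response
model, matching attribute-wise reporting). $X$ and $y$ are mean-centred
only — no autoscaling, the usual convention for spectra. NIPALS extracts
components with deflation; the compact coefficient vector
$b = W(P^\top W)^{-1}q$ reproduces the score-space route to numerical
precision, and both routes are exposed (`predict(..., method =)`) as a
consistency check. Components are chosen by LOO RMSECV with ties broken
toward fewer components; the default ceiling is 10. Validation $R^2$ is
computed about the validation-set mean, so poor models can go negative.
Firmness units (N vs g) are carried as metadata and never converted.

## CARS

At iteration $i$ of $N$ the retained fraction follows the exponentially
decreasing schedule $r(i) = a e^{-ki}$ with $r(1) = 1$ and $r(N) = 2/p$.
Each iteration draws 80% of the calibration samples, fits PLS on the
currently retained variables, keeps the $\lceil r(i)\,p \rceil$ variables
of largest $|b|$ (enforced removal), redraws that count without replacement
with probability $\propto |b|$ (adaptive reweighting; zero-coefficient
variables get zero probability), and scores the survivors by LOO RMSECV on
the *full* calibration set. The subset with minimal RMSECV wins. The
internal fits use 5 components (capped by rank) to keep 50 iterations
cheap; the final model is refit with LOO-selected components on the chosen
subset. A with-replacement reweighting variant was rejected: losing
$\sim 1/e$ of the survivors every iteration collapses the path long before
$N$ and breaks the count-schedule diagnostics.

## Damage classification

Classes come from hard RPI thresholds; the moderate interval is closed
(`[5, 7]`) so the three regions partition the line. "Absolute RPI" in the
original wording is treated as the plain index (all tabulated values are
positive). Fisher DA uses the pooled within-class covariance, equal priors
and nearest-centroid assignment in canonical space (unstandardized
coefficients, $a^\top S_w a = 1$), ties to the earliest declared class. A
ridge $10^{-6}\,\mathrm{tr}(S_w)/p$ is added only when the pooled
covariance is singular. Splits are stratified by class — with three classes
and small groups an unstratified split can drop a class entirely. The DA
features are the preprocessed spectra restricted to a CARS selection
targeted at RPI itself, which outperformed selections targeted at any
single attribute in our experiments: RPI pools firmness, TA and TSS
information, and TA alone dominates its variance.

# The synthetic generator

No fruit-level measurements are published for this design, so the generator
*is* the study condition. Its defaults encode:

* **Design**: drop heights 0.5/1.0/1.5 m plus an undropped control, days
  1/3/5, 20 fruits per group (240 records).
* **Attributes**: per-group means and SDs from the tabulated group
  statistics (`mango_group_stats()`). The four attributes are drawn jointly
  with correlations firmness--TA $+0.5$ and firmness--TSS $-0.5$ (ripening
  physiology: a firmer, less ripe fruit keeps more acid and has less
  sugar); the published table gives only marginals, so the correlation is
  an explicit simulation choice. Draws are truncated at physical bounds
  (positive firmness/TSS, TA $\ge 0.05$%). Control-group statistics are not
  tabulated; controls reuse the 0.5 m group with its day trend shrunk to
  40% (undamaged fruit ripens more slowly) — a synthetic-only construction.
* **Spectra**: absorbance = sloped baseline + Gaussian bands at 970 nm
  (water, $\sigma$ 35 nm), 1190 nm (starch/sugar, $\sigma$ 30 nm) and
  1450 nm (water/OH, $\sigma$ 50 nm). Water bands at 1950/2250 nm fall
  outside the instrument range and are omitted. Water depths decrease with
  drop height (bruised tissue absorbs less), the sugar depth is affine in
  TSS, the 1450 nm depth gains an affine TA term, and the baseline slope is
  affine in firmness. Depth scales (0.1--0.45 AU on a 0.4 AU baseline) are
  typical of fruit NIR absorbance.
* **Noise**: multiplicative scatter (slope $\sim N(1, 0.04)$, offset
  $\sim N(0, 0.02)$ AU) plus additive band noise ($\sigma$ 0.003 AU) —
  scatter-dominated, as in diffuse-reflectance practice.
* **Cubes**: `simulate_cube()` embeds a record's spectrum in an elliptical
  bruise ROI, builds a smooth white frame and constant dark frame, and maps
  reflectance back to raw counts, so calibration + ROI averaging invert the
  construction exactly at zero pixel noise.

What the generator does **not** emulate: real covariance structure between
attributes beyond the two configured correlations, wavelength-dependent
scatter, peel/pulp layering, spatial bruise evolution, instrument
nonlinearity. Passing tests therefore demonstrate that the *algorithms*
recover what was planted under realistic noise — not that the models would
reach the same accuracy on real fruit.

# Numerical and testing choices

* **Problem sizes.** Tests run the full 240-fruit design where the claim
  needs it (attribute recovery, classification) and 20-replicate batches
  for selection-frequency claims; oracle equivalences use tiny instances
  (e.g. LOO vs a naive double loop at $n = 6$). The preprocessing
  comparison uses per-group models (12 calibration fruits each), the
  study's own modeling unit.
* **Planted-band recovery.** Recovery is assessed within one band-width
  ($1\sigma$) of each planted centre. Under SNV the discriminative weight
  provably concentrates on band *flanks* — the per-spectrum SD
  normalization cancels signal change at the absorbance maximum — so an
  exact-centre window misses even when CARS squarely brackets the band.
  One band-width is the tightest window consistent with the physics.
* **Preprocessing comparison regime.** At default noise, SNV and S-G tie
  statistically (pooled PLS can absorb the two scatter dimensions as extra
  components). The comparison experiment therefore uses the
  scatter-dominated regime (slope SD 0.12, offset SD 0.06, additive noise
  unchanged), where SNV's analytic scatter removal clearly wins over
  smoothing alone.
* **Classifier ceiling.** Serious/moderate fruits are separated by a hard
  threshold on a *continuous* index, and the tabulated day-5/1.0 m group
  (mean RPI 5.3, SD 0.58) puts real probability mass near the boundary.
  With only ~5--6 serious fruits in a 1/4 test split, demanding zero
  serious-class errors fails in a sizeable fraction of replicates even for
  a discriminant fitted on noise-free log-attributes. The spectral
  classifier reaches ~88% mean serious-class accuracy; occasional
  misclassifications concentrate at very low TA, where SNV's
  self-normalization makes the acid signal non-monotone. This is a genuine
  limitation of threshold-based grading, not an implementation defect
  (predictions agree with an independent DA implementation).
* **Determinism.** Every stochastic routine accepts a seed;
  `run_experiment()` seeds once at entry and lets all stages draw from the
  same stream, so a config + seed pair reproduces every table byte for
  byte.

# Known limitations

* The generator's attribute-to-band coefficients are free parameters; all
  claims on this module are parameter-recovery claims, never comparisons
  with published accuracy values on real mangoes.
* Regression on RPI directly is deliberately unsupported: the index mixes
  three attributes nonlinearly and is poorly predictable from spectra; the
  pipeline predicts the attributes and derives the index.
* Only linear DA is provided (no quadratic or kernel variants); the
  boundary-curvature error mode above is the visible cost.
* ENVI support is limited to the dialect described — little-endian,
  BIL/BIP/BSQ, types 4 and 12 — which covers the targeted line-scan
  instrument class.
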