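---
title: "mitophen: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mitophen: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## What the package computes

`mitophen` implements single-cell OXPHOS-deficiency phenotyping as used in
quantitative neuropathology of mitochondrial disease: per-cell
immunofluorescence densities of respiratory-chain subunits are normalised
to a mitochondrial mass marker, log-transformed, referenced to pooled
control cells, and binned into five deficiency classes. Everything
downstream — region × group breakdowns, mixed-model inference, glial
morphometry, qPCR copy number, survival — hangs off that classifier.

## The classification model and its assumptions

For a cell with target density $T$ and mass density $M$ (mean fluorescence
per µm² over the cell mask), the score is

$$ z = \frac{\log_{10}(T/M) - \hat\mu_c}{\hat\sigma_c} $$

with $\hat\mu_c$, $\hat\sigma_c$ the sample mean and SD (denominator
$n-1$) of the log-ratio over *pooled control cells of the same region*.
Classes: overexpressed ($z > 2$), normal ($-2 \le z \le 2$), low
($-3 \le z < -2$), deficient ($-4 \le z < -3$), severely deficient
($z < -4$). The assumptions this encodes:

* **Log-normality.** Per-cell densities are roughly log-normal, so the
  log-ratio is roughly Gaussian and the SD-limit bins have their nominal
  tail masses in controls (low-or-worse ≈ Φ(−2) ≈ 2.3%).
* **Mass-marker validity.** The denominator tracks mitochondrial content,
  so the ratio isolates per-mitochondrion subunit abundance. Raw
  (unnormalised) comparisons are available with `mass = "unity"`.
* **Pooling.** Controls are pooled across control animals within a region;
  animal-level correlation is *not* removed at calibration time but
  handled at inference time by the mixed model.

Two choices were genuinely open and are fixed as follows:

* **Transform order.** "Log-transform, then normalise" is ambiguous; we
  compute the log of the ratio (equivalently the difference of logs).
  z-scores of a ratio of separately-logged raw densities would change
  under a common rescaling of both channels (e.g. detector gain), whereas
  the log-ratio is exactly scale-invariant — a property the test suite
  asserts.
* **Boundaries.** The printed bin definitions use strict inequalities and
  leave the boundary points unassigned; boundary values fall to the
  less-severe class. The "overall reduction" summary uses $z \le -2$
  inclusive, as printed alongside the headline percentages. The
  disagreement at exactly $z = -2$ is measure-zero and documented. The
  five bins are treated as exclusive (stacked percentages sum to 100).

Cells with zero or negative density in either channel indicate
segmentation failure; they are excluded (no pseudo-count, since a
pseudo-count would re-introduce scale dependence) and the exclusion count
is reported.

## The synthetic world

`sim_cell_table()` generates the statistical structure the analysis
assumes, with ground truth carried alongside and never consumed by the
analysis stages:

* per-cell log10 densities = baseline + mouse random intercept + shared
  cell-size factor + cell noise; the size factor correlates target and
  mass channels like real soma-size variation does;
* knockout cells are a **two-component mixture**: with probability
  `affected_fraction` the target channel drops by `deficiency_shift`
  (uniform shifts cannot reproduce the within-region heterogeneity of the
  class breakdowns);
* affected flags are nested across ratios through a shared per-cell
  uniform, so complex I and complex IV deficiencies co-occur in the same
  cells.

**Units of the shift.** `deficiency_shift` is expressed in units of the
control log-ratio SD as the classifier sees it,
$\sigma_{\mathrm{ref}} = \sqrt{\sigma_{\mathrm{mouse}}^2 +
\sigma_{\mathrm{cell}}^2}$, so an affected cell's z-score is marginally
N(shift, 1). This is what makes planted-fraction recovery (fraction with
$z \le -2$ recovering `affected_fraction` for shifts of −4 and beyond)
hold at binomial tolerance, which the acceptance suite checks at
f ∈ {0.25, 0.5, 0.95}.

Defaults (the stated world; chosen once, not revisited):

| knob | default | why |
|------|---------|-----|
| mice | 3 control / 6 knockout | the modelled study's panel design |
| cells/mouse/region | 45 | ≈ 276 knockout Purkinje neurons from 6 mice |
| `cell_sd` (log10 ratio) | 0.15 | ~40% CV, typical of IF densitometry |
| `mouse_sd` | 0.5 · `cell_sd` | real clustering for the mixed model to detect |
| `deficiency_shift` | −4.5 | severe deficiency; knockout Purkinje medians sit below −4 |
| affected fractions | 0.97 (Purkinje) → 0.20 (hippocampus) | the region-dependent hierarchy, monotone; illustrative knobs, not measured constants |
| baseline density | 100 a.u./µm² (log10 = 2) | arbitrary fluorescence scale |
| qPCR curve | intercept 40, slope −1/log10(2), Cq SD 0.15 | perfect-doubling assay, typical replicate scatter |
| survival | exponential, median 94 d (knockout) | the knockout lifespan endpoint |

Acquisition noise characteristics are not published for the source
protocol (confocal settings were simply held constant), so rendering noise
is a free parameter defaulting to zero in `sim_cell_image()`; tests that
need noise set it explicitly and check the analytic standard-error bound
4σ/√n.

What the generator does **not** emulate: point-spread blur, channel
bleed-through, autofluorescence, touching/overlapping somata, manual-ROI
granularity, anisotropic process thickness. A green pipeline therefore
establishes *computational* correctness — calibration, recovery,
invariances — not robustness to optical artefacts.

## Densitometry and morphometry numerics

* Images are plain R matrices/arrays in a `channel_stack`; no raster-image
  package exists in the supported dependency set, so Otsu thresholding
  (256 bins, threshold at the bin edge maximising between-class variance),
  connected components (8-connectivity in 2D, 26 in 3D, via the pixel
  adjacency graph), binary morphology with a disk structuring element, and
  Zhang–Suen thinning are implemented in-package.
* Touching cells may merge — no watershed. This matches neither manual
  ROIs nor a full segmentation pipeline and is a documented limitation;
  the component count is only guaranteed ≤ the true count.
* Per-cell measurements are whole-mask means (the source protocol does not
  say whether nuclei were excluded); no background subtraction by default,
  a constant offset is available behind the `background` argument.
* The **soma** is the morphological opening of the object mask, disk
  radius 2 µm by default (the commercial 3D software used originally does
  not document its rule; the radius is a config knob). Radius 0 returns
  the full object, an upper bound.
* **Process lengths** skeletonize the object minus the soma core; each
  skeleton endpoint contributes the geodesic distance (orthogonal steps
  1 px, diagonal √2 px) from its component's root, the skeleton pixel
  nearest the core (plain adjacency is brittle to the ±1 px boundary
  roughness the opening leaves). Branches under 2 µm are discarded as
  opening crumbs. Lattice geodesics overestimate Euclidean length by up to
  ~8% at worst-case angles; the acceptance tolerance for mean recovery is
  15%.
* **Volumes** are voxel counts × voxel volume; 2D skeleton metrics on 3D
  stacks use the maximum-intensity projection, mirroring the parallel
  2D/3D analyses of the source protocol.
* **Contact** = dilated microglial mask (default 1 px, "touching")
  intersecting the Purkinje mask; the criterion is config-exposed because
  the original software's rule is undocumented.

## Statistics layer

* Student's t pools variances (that is the test the study names); Welch
  and Mann–Whitney (mid-rank ties, normal approximation with continuity
  correction; all-tied data returns p = 1) are explicit alternatives.
  Shapiro–Wilk screening is *advisory output only* — it never switches the
  test, keeping analyses reproducible from config.
* Benjamini–Hochberg families are user-declared; nothing is inferred.
* The mixed model is `nlme::lme(value ~ group, random = ~1|cluster)`,
  REML, with the fixed-effect t on containment (between-cluster) degrees
  of freedom — for a balanced two-group design, #clusters − 2 — matching
  the modelling framework the study used. A likelihood-ratio alternative
  (`method = "lrt"`) refits by ML. Singular fits (cluster SD below 1e−4 of
  the residual SD, nlme's boundary) are flagged, not fatal. Type-I
  calibration at 0.05 over 1000 clustered null replicates is an acceptance
  criterion.
* Fisher's exact uses probability summation for two-sidedness (stated
  because several two-sided conventions exist).
* Kaplan–Meier medians are the earliest time with S(t) ≤ 0.5 and are NA
  when never reached (e.g. fully censored cohorts); the two-group
  comparison is the Mantel–Cox log-rank chi-square.
* qPCR replicates average on the Cq scale (standard ΔCq practice) before
  inversion; a sample keeps its estimate if ≥ 2 replicates remain, else it
  is flagged unquantifiable; any no-template amplification raises a QC
  warning rather than an error, since the original thresholding policy is
  unstated.

## Known limitations

* No TIFF/OME-TIFF I/O: stacks enter as in-memory arrays; tables move as
  CSV with one shared schema, so simulated and measured data are
  interchangeable everywhere downstream.
* The human-cohort fixture carries the patient table only; control-group
  descriptives exist as summary counts (5 F / 11 M), not raw ages.
* The printed process-length pair mixes a knockout mean with a control
  median; the percent-change helper reproduces the printed arithmetic as
  printed.
* Per-mouse (rather than pooled per-region) control references and robust
  median/MAD calibration are out of scope by design.
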