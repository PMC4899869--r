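---
title: "Methods: the Monte-Carlo nearest-neighbour association score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Monte-Carlo nearest-neighbour association score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nncoloc)
```

## The model and its assumptions

`nncoloc` asks one question of a stained tissue image: does a query cell
class (say, CD45+ leukocytes) sit closer to a reference class (say,
senescent stromal cells) than random placement in the same tissue
geometry would allow?

The observed statistic is the median over query cells of each cell's
Euclidean distance to its nearest reference cell. The median, rather than
the mean, is used so that a few isolated cells at the image margin cannot
dominate the estimate. The null model is conditional complete spatial
randomness: reference cells are held fixed at their observed positions,
and the query cells are re-placed uniformly at random within the valid
region mask, `K` times (default 100,000). Each round's median
nearest-neighbour distance is recorded; with null mean $\mu$ and standard
deviation $\sigma$, the association score is
$S = (\mu - d_{obs})/\sigma$ — the number of null standard deviations the
observed median lies *below* random expectation. Positive $S$ indicates
attraction, negative repulsion.

Conditioning on the mask is what makes the score honest in irregular
tissue: edge effects, holes (follicles), and excluded bright structures
(epithelium) distort absolute distances identically in the observed and
null computations, so no analytic edge correction is needed. Because
query points are compared against a null that re-places *the same number
of points in the same geometry*, the score is also invariant to uniform
coordinate scaling and translation — it is unit-free, and `pixel_size`
matters only when distances themselves are reported in microns.

The percentile interpretation relies on the sampling distribution of the
median being approximately Gaussian, which holds well for the dozens to
hundreds of cells per image this analysis targets: a score of 2 then
corresponds to an observed median below roughly 97.5% of null medians.
The package reports the empirical percentile alongside the score, so the
approximation is never load-bearing. Both control analyses reuse the same
machinery: point-to-region mode (distance to the nearest pixel of a named
region such as the epithelial layer, only the points re-placed) and self
mode (distance to the nearest *other* point of the same class, the whole
set re-placed each round).

## Parameters that matter

* `n_rounds` (default 100,000): Monte-Carlo rounds. The score's own
  Monte-Carlo error scales as $K^{-1/2}$; at $K = 10^4$ versus $10^5$ the
  score typically moves by well under 0.1. The default keeps the
  percentile resolved to $10^{-5}$.
* `seed`: every stochastic stage (null sampling, generators) is
  bit-reproducible from its integer seed. Batch runs derive per-sample
  seeds as a hash of `(base_seed, sample_id)` so results do not depend on
  processing order.
* Detection (`detection_params`): `smoothing_sigma` (px) suppresses shot
  noise before thresholding; `min_area`/`max_area` (px) gate object
  sizes; `split_touching` enables watershed splitting of merged cells.
  Defaults (sigma 2, areas 20–2000) suit cell-scale blobs tens of pixels
  in area and are deliberately explicit — nothing adapts silently to the
  image.
* Generator (`synthetic_spec`): `sigma_c` (px) is the single
  effect-size knob for attraction — each query point is a Gaussian
  displacement of scale `sigma_c` from a random reference point
  (a Thomas-type cluster process, approaching CSR as `sigma_c` grows);
  `r_min` (px) is a hard exclusion radius for the inhibited pattern.

## Numerical choices

* **Placement resolution.** Random placement draws a uniform valid pixel,
  then uniform sub-pixel jitter in $[-0.5, 0.5]$ per axis — exactly
  uniform over the valid area and cheap to sample.
* **Standard deviation convention.** The null s.d. uses the population
  divisor $K$; at $K = 10^5$ the difference from $K - 1$ is below
  $10^{-5}$ relative, but one convention must be fixed for
  bit-reproducibility.
* **Medians.** Even-count medians are the mean of the two central order
  statistics.
* **Ties and duplicates.** The empirical percentile counts null medians
  *strictly* greater than the observed median, so ties count against
  association (conservative). Self-mode excludes by index, not by
  coordinate equality: coincident duplicate detections are mutual
  neighbours at distance 0. Re-placed points may coincide with reference
  points; distance 0 is legitimate.
* **Degenerate nulls.** If all sampled medians are identical
  ($\sigma = 0$, e.g. a one-pixel mask) the score is undefined and an
  error is raised rather than returning $\pm\infty$. An image with zero
  reference cells likewise errors; it does not yield distance $\infty$.
* **Exactness.** The compiled nearest-neighbour kernels minimise squared
  distances and take one square root; since `sqrt` is monotone and
  correctly rounded this is bitwise identical to the naive
  sqrt-then-minimum scan, and the test suite holds the compiled path to
  *exact* equality with a pure-R brute-force oracle.
* **Rasterization.** Polygon masks include a pixel iff its center
  (integer coordinates, 0-based, x = column) is inside the polygon
  (even-odd rule); self-intersecting polygons are rejected.
* **Connectivity.** Detection labels components with 8-connectivity in
  row-major scan order, so object counts and output order are
  reproducible across platforms.

## What the synthetic generator does and does not emulate

`generate_mask()` builds a tissue ellipse whose outer rim is an excluded
"epithelium" band, with circular "follicle" holes — the geometric
features (borders, internal holes, an adjacent excluded layer) that make
masked analysis necessary in skin sections. `generate_points()` places
the reference class uniformly and the query class by CSR, attraction or
inhibition; `render_image()` draws each cell as an isotropic Gaussian
spot (default scale 0.7 px, peak 150 above background 10) with Poisson
shot noise, the standard fluorescence forward model.

The spot scale deserves a note. Under strong attraction
(`sigma_c = 5` px) a substantial fraction of query cells lie within a few
pixels of another cell; any two spots closer than about twice the
effective spot scale merge into a unimodal blob with no intensity dip for
watershed to cut. The detector handles such dipless doublets by flux
conservation: a blob whose integrated intensity is about $m$ times the
image's median object flux is divided into $m$ objects by deterministic
intensity-weighted k-means. This recovers counts and positions to within
the spot scale, but it assumes roughly uniform per-cell brightness; the
default spot scale is additionally kept small enough that individual
cells remain resolvable at the densities the attraction model itself
produces — emulating an imaging setup adequate to its specimen, as real
acquisitions are.
A related limitation is thresholding on nearly-empty channels: Otsu's
between-class criterion prefers splitting the background mode when
genuine signal occupies well under 1% of the masked area (e.g. 30 cells
in a 512×512 field), so sparse channels should use an absolute threshold
chosen from the intensity histogram, as the end-to-end tests do.

What passing synthetic tests shows: the statistic is calibrated (type-I
error near nominal under CSR), powerful (score rises monotonically as
`sigma_c` falls), sign-correct under inhibition, and robust to the
render–detect–score pipeline. What they cannot show: performance on real
tissue, where staining variability, autofluorescence, sectioning
artefacts, irregular cell morphology and annotation error have no
synthetic counterpart here. Detection parameters in particular must be
re-tuned per marker and magnification on real data.

## Design choices where the design was open

* **Which class is re-placed.** Only the query class; the reference
  geometry is observed and conditioned on. Re-placing both classes would
  test a different (exchangeable) hypothesis and discard the reference
  pattern's structure.
* **Aggregation.** Cohorts are summarised by the mean per-sample score
  with a t-based 95% CI (the standard small-sample interval for the 4–9
  samples per group typical of imaging studies) plus the s.d.; the
  cohort-level call is association/repulsion only when the CI excludes 0.
  Scores from different modes are never pooled. Group comparisons use
  Welch's t-test, reported alongside (never instead of) per-group CIs.
* **Detection pipeline.** Smooth → threshold (Otsu on in-mask pixels
  only, so bright excluded regions cannot skew it, or absolute) →
  8-connected components → area gates → optional declumping (watershed at
  tolerance 1.5% of component peak — below the dip two resolvable spots
  create — then flux-quantized k-means for dipless doublets) →
  intensity-weighted centroids. Every step has an inspectable
  intermediate; nothing is learned or adaptive.
* **Sampling problem sizes in the test suite.** Calibration uses 500 CSR
  replicates at $K = 10^4$; power uses 50 seeds per attraction level;
  end-to-end uses 50 seeds per pattern at 512×512. These sizes give
  replicate-mean standard errors a factor ≳3 below the tested margins.

## Known limitations

* 2D only; no 3D stacks, time series, stitching or registration.
* The score tests *marginal* association against conditional CSR; it does
  not model covariates (local cell density gradients, distance to
  vasculature) that could induce association without direct interaction.
* One score per image; repeated images per donor are aggregated as
  independent samples, which overstates effective n if images from one
  donor are correlated — the manifest records the mapping so users can
  aggregate at the donor level instead.
* Detection assumes blob-like, roughly isotropic signal; elongated or
  ring-shaped stains need different segmentation upstream, after which
  `analyze_sample()` applies unchanged to any point table.
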