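# nncoloc

Monte-Carlo nearest-neighbour co-localization analysis for cells in masked
tissue images.

## The problem

In stained tissue sections one often needs to know whether one cell class
preferentially localizes near another — for example, whether CD45+ immune
cells accumulate around senescent stromal cells in skin. Raw counts cannot
answer this: the tissue's geometry (epithelium, hair follicles, muscle,
section borders) constrains where cells *can* be, so "close together" must
be judged against what random placement in the *same* geometry would
produce.

`nncoloc` implements that comparison for users quantifying multiplex
fluorescence micrographs: image and annotation I/O, automated spot/cell
detection, the Monte-Carlo association score, control analyses, and
cohort-level aggregation, plus a synthetic-data generator that makes every
stage testable against known ground truth.

## The statistic

For one image, let the query class (e.g. CD45+ cells) have points
$q_1,\dots,q_n$ and the reference class (e.g. senescent cells) points
$r_1,\dots,r_m$, inside a valid-region mask $W$ (interstitial stroma; all
other regions excluded). The observed statistic is the median
nearest-neighbour distance

$$d_{obs} = \mathrm{median}_i \left( \min_j \lVert q_i - r_j \rVert \right),$$

the median being robust to a few isolated cells. The null distribution is
built by $K$ rounds (default $K = 100{,}000$) of re-placing the $n$ query
points uniformly at random inside $W$ — reference points stay fixed — and
recording each round's median NN distance, giving draws
$d^{(1)},\dots,d^{(K)}$ with mean $\mu$ and standard deviation $\sigma$.
The normalized association score is

$$S = \frac{\mu - d_{obs}}{\sigma}.$$

Positive scores mean the query class sits closer to the reference class
than chance (association); zero means indistinguishable from random;
negative means repulsion. Because the sampling distribution of the median
is near-Gaussian for realistic $n$, $S = 2$ corresponds to an observed
median smaller than roughly 97.5% of the null medians; the empirical
percentile is also reported. Two control analyses use the same machinery:
distance of the query class to a named region (e.g. the epithelial layer)
and same-class self-association (nearest *other* neighbour). Per-sample
scores aggregate to cohort mean, s.d., and t-based 95% confidence
interval.

## Worked example

```r
library(nncoloc)

spec <- synthetic_spec(shape = c(256L, 256L), n_parents = 20L,
                       n_offspring = 80L, pattern = "attracted",
                       sigma_c = 5, seed = 42L)
s <- generate_sample(spec)   # irregular mask + two point classes
fit <- analyze_sample(s$offspring, s$parents, s$mask,
                      n_rounds = 10000, seed = 7)
fit
#> Nearest-neighbour co-localization analysis
#>   sample: sim42   mode: point_to_point
#>   observed median NN distance: 5.72 px (n_source = 80)
#>   null: mean 18.49, sd 1.494 (K = 10000 rounds, seed 7)
#>   association score: 8.551   empirical percentile: 1.0000
```

The 80 query cells were generated clustered around the 20 reference cells
(Gaussian displacement, scale 5 px), and the analysis recovers that: their
observed median NN distance (5.72 px) sits 8.6 null standard deviations
below the random-placement mean (18.49 px), so the score calls a strong
association. A `csr` pattern gives scores fluctuating around 0 and an
`inhibited` pattern gives negative scores.

Cohort aggregation over per-sample scores:

```r
summarize_group(c(3.1, 2.4, 4.0, 3.6, 2.9, 3.3), "senescent-stroma cohort")
#> Cohort 'senescent-stroma cohort': n = 6 samples
#>   mean association score 3.217, sd 0.556
#>   95% CI (2.633, 3.801) -> association
```

For real images: `read_image()` / `read_mask()` / `read_points()` bring in
TIFF channels, raster or polygon masks, and annotated cell tables;
`detect_cells()` converts a marker channel to centroids; the
`inst/exec/nncoloc` script exposes `simulate`, `detect`, `score`,
`aggregate` and `pipeline` subcommands for shell use.

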