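---
title: "Detecting, comparing and training focus detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting, comparing and training focus detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(findfoci)
```

## The detection model

A focus is a bright, roughly diffraction-limited accumulation of
fluorescent signal — a few pixels wide at typical magnifications —
sitting on a spatially varying background inside a nucleus. The
detector makes no shape assumption beyond "a local intensity maximum
with a surrounding region draining uphill into it":

1. **Smoothing.** An optional Gaussian blur (`blur_sigma`, pixels)
   suppresses single-pixel noise before peak identification. The
   separable kernel has radius `ceiling(3 * sigma)` with weights
   `exp(-d^2 / 2 sigma^2)` normalised to one, and replicate-edge
   padding, so constant images are preserved exactly and total
   intensity is conserved to well under 0.5% when the signal is
   interior. Whatever the blur, every *reported* intensity statistic
   (peak maximum, total intensity, height above background) comes from
   the original image — smoothing only decides geometry.
2. **Background.** A single level `B` separates foreground from
   ignored pixels. Methods: `absolute` (a raw intensity), `otsu`,
   `mean`, and `percentile`. Only pixels strictly above `B` take part
   in detection; the strictness matters for degenerate flat images,
   which yield no foreground at all. The menu of auto-threshold
   methods is this package's choice; Otsu is the conventional one for
   DAPI-style bimodal histograms.
3. **Candidates.** Every pixel exceeding all of its neighbours
   (8-connected in 2D, 26-connected in 3D — one convention fixed
   everywhere) and above `B` is a candidate focus. Connected
   equal-intensity plateaus whose entire boundary is lower count as a
   single candidate positioned at the unweighted centre of mass of the
   plateau; a plateau touching an equal-valued pixel that drains
   downhill elsewhere is not a maximum.
4. **Expansion.** Pixels are visited in descending intensity and each
   takes the label of its highest already-labelled neighbour — a
   deterministic realisation of "follow the steepest uphill path".
   Ties are broken by the lowest label id and then raster order, so
   results are bit-reproducible. A peak's expansion is limited by its
   floor `B + f (max − B)` (`search_fraction` f in [0, 1]): members at
   or below the floor revert to background, except the maximum itself.
   With `f = 1` only maxima/plateaus remain; with `f = 0` peaks extend
   down to the background.
5. **Saddles and merging.** For touching regions the saddle is the
   highest boundary intensity (the max over adjacent pixel pairs of
   the lower of the two values). Merging removes insignificant peaks
   in three stages, and after *every* merge the absorbing peak's
   members, area, maximum and saddles are updated before the next
   decision: stage 1 merges peaks whose height above their highest
   saddle falls below `min_height_above_saddle` into the neighbour
   across that saddle (processed in descending saddle order); stage 2
   merges peaks smaller than `min_size` pixels (smallest first);
   stage 3, off by default because it is the most expensive decision,
   merges peaks whose pixel count above their highest saddle is below
   `min_size`. The stage-1 threshold has an absolute mode (intensity
   units) and a relative mode (fraction of the peak's height above
   background); which a dataset prefers is an empirical matter, so the
   optimiser can search either.
6. **Filtering.** Surviving peaks can be filtered by minimum area,
   minimum total intensity and minimum height above background.

Isolated peaks (no touching neighbour) can never merge — there is
nothing to merge into — and so survive stages 1–3 regardless of size;
the area filter is the tool that removes them. Peaks are reported in
descending order of maximum intensity with ties broken by raster
order of the maximum pixel, so outputs are stable across runs.

## Defaults and units

All spatial parameters are in pixels and all intensities in the units
of the input image. `foci_params()` defaults are deliberately
permissive (no blur, absolute background 0, `f = 0`, `min_size = 1`,
no merging, no filters): the out-of-the-box behaviour is "every local
maximum", and each restriction is something the user (or the
optimiser) turns on. The 8-pixel matching radius used throughout the
comparison machinery corresponds to clicking either side of a ~5-pixel
focus; it is an argument everywhere it occurs.

## Comparing point sets

Annotations are 0-based (x, y[, z]) coordinates; the pixel of a point
is the floor of each coordinate. Greedy closest-pair matching commits
the globally closest unmatched pair within the radius, repeatedly;
distance ties take the smaller first-set index, then the smaller
second-set index. The scores follow the standard forms — Jaccard
`m/(n1+n2−m)`, the two recalls, and F1 `2m/(n1+n2)` — with the
identity `J = F1/(2−F1)`. Degenerate conventions are explicit: two
empty sets score 1 everywhere (vacuous agreement); exactly one empty
set scores 0.

The quartile breakdown ranks the union of a single global matching by
intensity (a matched pair counts once, at the mean of its two
endpoint pixel values — the mean is this package's choice, as a pair
straddles two pixels) and cuts it into four rank groups differing in
size by at most one, recomputing the counts per group. An alternative
would re-match within each quartile; partitioning the global matching
was chosen so that the quartile statistics decompose the overall one.

Three-way clustering merges two annotators' matches into size-2
clusters at the mean coordinate, then matches cluster centroids
against the third set. Cluster intensity is the mean member pixel
value, normalised by the median pixel value over all selected foci in
the image, making 1 "a typical selected focus for this image".

## Aligning clicks to maxima

Clicks aimed at a focus rarely land on its maximum. The alignment
helper detects every relevant maximum with the background set to the
minimum clicked pixel value minus the image standard deviation (so
maxima dimmer than any click are still found), `min_size` 1 and no
merging, then processes clicks brightest-first, assigning each the
maximum of the region it sits in. One click per maximum: a click
whose maximum is taken searches for the highest free maximum within a
radius equal to its distance to the taken one, and stays unmoved if
none exists. A click already on its free maximum counts as moved with
distance zero — one status fewer to reason about.

Gating prevents alignment onto insignificant bumps: a threshold is
computed from the heights of the aligned maxima (percentile with
linear interpolation between closest ranks; Q1 − 1.5 IQR; mean − k·SD
— SD taken over the aligned-maxima heights, one reading of an
ambiguous recipe, and stated here rather than guessed silently; or
adaptive) and assignments below it revert to the original coordinate.
The adaptive rule walks the distinct maxima heights downward while
the missed fraction — non-aligned maxima at or above the candidate
threshold over all maxima at or above it — stays at most `q`,
stopping just before the first violation. Counting inclusively at the
threshold makes the limiting case exact: with `q = 0` and the
second-highest maximum unclicked the threshold is the height of the
top maximum, which is also why the method relies on annotators
including the brightest focus. The default `q = 0.15` ("accept a new
maximum only where at least 85% of comparable maxima were clicked")
is a configurable default, not a claimed optimum. The threshold is
computed from a first unconstrained pass and applied once; gating is
not iterated, since releasing a gated maximum cannot free a brighter
one.

## Training

`foci_grid()` spans a parameter space as the cartesian product of
per-parameter ranges, enumerated deterministically with `blur_sigma`
outermost, then background, then `search_fraction`, then the
merge/filter parameters. `optimise_single()` exploits exactly that
nesting for its staged caches — blurred image per sigma, background
level per spec, expansion and saddles per search fraction — so only
merging, filtering and scoring are repeated per combination. Caching
is a contract, not a semantics change: the cached and cache-disabled
paths produce identical ranked lists, and a test asserts it. Ranking
ties go to the earlier combination in enumeration order, which also
acts as a mild preference for the simpler end of each range. If the
winning combination touches the edge of any multi-valued numeric
range a per-parameter boundary flag is raised, recommending a wider
range.

Multi-image training aggregates per-image score vectors after an
optional conversion: raw, relative (fraction of the image's top
score), z-score (zero-SD images contribute zeros — the documented
guard), or rank (1 best, ties equal). Aggregation is the mean
(median available); raw, relative and z-score are monotone within an
image, rank deliberately discards score magnitudes. The best
combination maximises the aggregate (minimises, for rank). Subset
designs over n annotated images use exact binomial counts
(`count_combinations`, exact below 2^53 — R has no native 64-bit
integer, which covers every n ≤ 55); up to 210 combinations are fully
enumerated to avoid sampling bias, above that 100 distinct random
subsets are drawn under a recorded seed.

## The synthetic study designs

The generator emulates what matters to the algorithms: an elliptical
nucleus-like region (axes 0.85/0.75 of the half-dimensions) on a
128×128 16-bit canvas, 60 spots by default with centre-to-centre
separation ≥ 6 px, isotropic Gaussian profiles with widths 1.6–2.6 px
(≈5 px full width), log-normal peak amplitudes (median 2000, log-SD
0.5) over a background of 500 counts with additive Gaussian read
noise of SD 100 — a median single-spot SNR of 20, with the faintest
spots around 7. Simulated annotators add the four human error modes:
Gaussian click jitter, a personal intensity cutoff (the largest
driver of disagreement), doublet interpretation of single blobs
(partners placed 2–3 px apart, deliberately fusing into one maximum
at these widths), and duplicate/false clicks.

The acceptance experiments run at desk scale, sized so the whole
suite completes in minutes: parameter recovery trains on 5 of 10
50-spot scenes and tests on the other 5 (mean held-out F1 ≥ 0.95);
the consistency experiment gives each of 12 pool scenes an annotator
with a different intensity cutoff (0–0.6 quantile), trains on random
subsets of 1 vs 5 scenes over 20 replicates, and evaluates against a
mid-cutoff annotator on 3 held-out scenes — the interquartile range
of held-out F1 under 5-scene training is consistently at or below the
1-scene one, with the 1-scene outliers (parameters chasing one
annotator's cutoff) removed by aggregation. Brute-force oracle checks
run on ≤12×12 images with ≤4 gray levels, where exhaustive
re-computation after every merge is affordable.

What passing these tests does *not* show: the generator has an ideal
flat background, isotropic spots, and uncorrelated Gaussian noise.
Real spreads have textured DNA background, chromatic blur, saturated
pixels and annotator drift within an image, so trained parameters
transfer to real data only in the sense the training procedure itself
provides — by training on annotated examples of the data at hand.

## Numerical and degenerate-input choices

* Otsu operates on a 256-bin histogram scaled to the image min–max
  range; the returned threshold is the bin edge maximising
  between-class variance, smallest edge on ties. A constant image
  returns the constant, so its foreground is empty.
* Images are validated as finite and non-negative and processed as
  doubles; the `bit_origin` tag only affects file output.
* Coordinates are 0-based everywhere; CSV point files say so in a
  header comment, and a `--one-based` flag shifts ImageJ-style input.
* Parameter and grid files are flat key=value text, written with
  17 significant digits so round-trips are bit-exact; results tables
  use 6 significant digits for readability.
* Merging recomputes bookkeeping after every single merge (the
  incremental update is exactly equivalent to full recomputation, and
  the oracle tests assert that); peak ids, processing orders and all
  tie-breaks are total orders, so every output is deterministic.
* The batch runner processes files in sorted name order, logs and
  skips unreadable images, and reports them in its return value (the
  CLI exits non-zero).

## Limitations

* 3D support treats the axial dimension like the lateral ones
  (26-connectivity, isotropic blur); anisotropic voxel sizes are not
  modelled.
* Only single-channel grayscale processing: a DNA mask comes from
  thresholding the same or another image supplied by the user.
* The optimiser is exhaustive by design — transparent and cacheable,
  but exponential in the number of searched parameters; grids beyond
  ~10^5 combinations are better pruned than enumerated.
* Greedy matching is not the optimal assignment; it is the
  field-standard, order-free-up-to-ties procedure the scores are
  defined against, and the sorted-edge oracle test pins its
  behaviour.
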