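---
title: "Methods: image-based phenotyping of Salicornia under salinity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based phenotyping of Salicornia under salinity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosal)
```

## The problem

*Salicornia europaea* is an extreme halophyte whose growth peaks at
moderate NaCl concentrations and declines again at the extremes.  A
non-destructive way to quantify that response is to photograph plants on
a uniform light box, segment the silhouette, and derive a small panel of
traits: projected area `A`, branch count `B`, shoot diameter `S` (a
succulence proxy), height `H`, the box-counting fractal dimension `FD`
of the silhouette, and the CIELab colour difference `deltaE` against the
salt-free controls.  Combined with spectrophotometric assays (proline,
hydrogen peroxide, chlorophylls, carotenoids) the twelve variables feed
a correlation PCA whose factorial scores measure how far two populations
drift apart under each treatment, and a RAPD band panel provides an
independent, marker-based view of the population structure.

Because raw field images are rarely shareable, the package is built
around a seeded synthetic generator that emulates the full
two-population x five-treatment x twelve-replicate factorial with exact
ground truth, so every stage of the measurement chain can be tested for
parameter recovery rather than against a frozen data set.

## The synthetic trial

`plant_config()` bundles the design and all response curves.  Each
plant is a recursive branching silhouette:

* a vertical main stem of sampled height and stroke width, anchored at
  the image base;
* first-order laterals leaving the stem at alternating sides; their
  attachment heights are spread over evenly sized slots per side (with
  jitter) and their angles are tied to height — lower branches flatter,
  upper steeper — so same-side laterals run near-parallel instead of
  crossing;
* per extra level of `branching_depth`, each segment carries a
  near-continuation child at its tip and an outward-turning child
  part-way along, with geometric length decay 0.70 and width decay 0.92.
  Subtrees therefore fan away from the stem rather than folding back
  over it;
* every segment is clipped so tips stay inside the stem's vertical span
  (laterals a few pixels below the apex) and the image frame.  Height
  and branch-count ground truth are exact by construction; an image too
  small for the sampled height is an explicit error, never a silent
  crop.

Foreground pixels are coloured by sampling CIELab values (per-pixel sd
2) around the cell's programmed colour centre and converting to sRGB;
the background is pure white, emulating light-box photography, so the
classical grey-band segmentation (135--240) applies.

The response-curve defaults encode the study conditions: `H`, `A`, `B`
and `branching_depth` are unimodal with their optimum at 400 mM;
`S` rises monotonically with salinity (succulence); the colour centre
drifts lighter (L\* up), less green (a\* toward 0) and more yellow
(b\* up); proline rises with salinity, hydrogen peroxide rises sharply
at the extremes, and the pigment absorbances fall.  The industrial (I)
population is programmed with a multiplicative advantage in the biomass
traits that is smallest near the optimum and largest at 1000 mM, and
with a smaller colour drift than the natural-brine (C) population, so
the populations diverge most under extreme stress.  Those orderings —
not any particular absolute value — are what the downstream statistics
are expected to reproduce.

Two calibration decisions deserve emphasis.  First, the 0 mM lightness
baseline (L\* = 63) was chosen so that every treatment's greyscale
values sit safely inside the 135--240 segmentation band; darker, more
saturated greens would straddle the lower threshold and make
segmentation accuracy a property of the colour model rather than of the
segmenter.  Second, the stroke widths, lateral lengths and the
branching-depth curve were calibrated once so that the measured mean FD
of the default 400 mM cell sits near the moderate-salinity complexity
peak observed for this species (~1.85) while the extremes stay clearly lower; after that
calibration the defaults are frozen.

The biochemical generator draws true concentrations from the response
curves and maps them through the printed standard curves — proline
`y = 0.0467x - 0.0734` (0--40 ug/ml), hydrogen peroxide
`y = 0.0188x + 0.046` (0--40 mM) — plus absorbance noise (sd 0.005).
Negative sampled absorbances are clamped to zero with a warning, which
mimics a reading at the assay's detection limit.  The RAPD generator
emits five monomorphic bands per primer plus the per-primer polymorphic
counts 3/6/6 (K01/M02/OPB11); polymorphic bands are
population-differentiated Bernoulli draws (frequencies 0.8 vs 0.2,
alternating direction), which is what makes individuals cluster by
population without any band being strictly private.

`simulate_trait_records()` is a statistical twin of the image path: it
draws the twelve per-plant variables directly from the same curves
without rasterising.  It shares the programmed effects but not the
imaging noise, and is used where a test needs hundreds of independent
trial repetitions (e.g. the population-distance ordering) that would be
pointlessly expensive through the raster path.

## Measurement operationalisations

**Segmentation.** Deterministic band thresholding (inclusive
135--240 defaults) with optional largest-component and hole-fill
post-processing replaces the manual step a human operator would
perform; all flags are exposed.  The pipeline segments with
`fill_holes = FALSE` and fills holes only where the silhouette itself is
the measurand: projected area ("pixels inside the borderline") and FD.
Colour, diameter and the skeleton operate on the raw strokes, because
filled pockets between overlapping shoots are background-white in the
image and carry no plant colour or topology.

**Diameter.** Rows spanning the middle third of the vertical extent are
probed at the main-stem column (foreground centroid of the middle band,
falling back to the column that crosses the most rows when asymmetric
branch mass pulls the centroid into background).  The reported `S` is
the lower quartile of the per-row run lengths: on heavily branched
shoots many rows cross a lateral at the stem column and report the
merged run, inflating the upper half of the distribution, while the
lower quartile tracks the clean stem rows (uniform bars are unaffected).

**Branch counting.** The mask is thinned (Zhang--Suen), terminal twigs
shorter than `spur_prune_px` (default 5) are pruned, and the main axis
is the base-to-apex skeleton geodesic.  The base-to-apex choice matters:
the longest geodesic through the base frequently exits mid-stem through
a deep lateral chain, absorbing the upper stem and all its laterals into
a single off-axis component.  Laterals are then counted as attachment
sites of off-axis components that reach further than about a stroke
width from the axis (redundant skeleton strands from thick-stroke
thinning stay within that reach), clustering sites closer than 1.5x
that reach; one merged component can therefore still contribute several
laterals through its distinct attachments.  On the default cohort this
recovers the true count with Spearman correlation above 0.9.

**Fractal dimension.** The mask is cropped to its foreground bounding
box and padded to the next power-of-2 square; boxes are powers of 2
from 2 to a quarter of the padded side, counted from a fixed top-left
origin (no origin search), and FD is the OLS slope of `log N` against
`log(1/eps)` in natural logs.  Saturated scales (every box occupied) are
excluded because they flatten the fit for sparse sets — except when
*all* scales are saturated, the plane-filling case, where the counts
follow the slope-2 law exactly and are kept.  Bounding-box cropping
makes whole-pixel translations exact no-ops; at a fixed frame, grid
*aligned* shapes (the block Sierpinski construction) can still move by
more than 0.02 under sub-box translations because perfect alignment is
the worst case for a single-origin counter — one reason the cropping
normalisation is the default.

**Colour.** 8-bit sRGB is linearised with the standard transfer
function, mapped to XYZ with the sRGB/D65 matrix, and to CIELab with
the D65 white point; the per-plant summary is the arithmetic mean over
the mask (median available).  `deltaE` is the CIE76 Euclidean distance
against the per-population mean of the 0 mM controls — per-population
rather than pooled, because the populations differ already at 0 mM and
colour change is reported within population.

## Statistics

The trait matrix holds the population x treatment cell means of the
twelve variables in fixed order (A, B, S, H, P, HP, Cha, Chb, TC,
Carot, FD, deltaE).  PCA is correlation-matrix PCA (the variables have
incommensurate units, and the Kaiser eigenvalue-greater-than-1 retention
rule presumes unit-variance inputs); covariance PCA is available via
`standardise = FALSE`.  Loading signs follow the
largest-magnitude-positive convention so scores are reproducible across
eigensolvers; the population distances are sign-invariant anyway, being
Euclidean distances over the first three factorial scores.

The per-trait two-way ANOVA reports omnibus F tests and the
simple-effect comparisons the field actually reads: treatments within
each population (compact letters) and populations within each treatment
(asterisks), with pooled-error t statistics adjusted by Holm--Sidak
step-down (`1 - (1 - p_i)^(m - i + 1)` with running-maximum
monotonicity) within each comparison family.  Compact letters use the
insert--absorb algorithm with treatments ordered by concentration.

The pigment equations are implemented exactly as printed, including the
`2.81 x A663` term of the chlorophyll-b equation, which differs from the
canonical 80%-acetone coefficient set — the package does not silently
"correct" published arithmetic — and the carotenoid equation consumes
the volume/mass-scaled Cha/Chb values (the typeset formula is ambiguous
on this point; the choice is recorded here and in the function
documentation).  Unit conversion from standard-curve concentration to
per-gram fresh-weight content goes through explicit dilution-factor
parameters whose defaults encode the documented extraction protocol
(5 ul buffer per mg tissue for proline; 5 ml per 0.5 g for peroxide).

RAPD clustering starts from the 0/1 band matrix (band calling from gel
images is out of scope).  Jaccard similarity ignores shared absences —
standard for dominant markers, where a shared missing band is not
evidence of relatedness — and UPGMA is the classic size-weighted
arithmetic-mean agglomeration with merge heights `d/2`
(molecular-clock convention) and deterministic smallest-(row, column)
tie-breaking.  Trees serialise to Newick with branch lengths that
reproduce the cophenetic distances on re-parse.

## Problem sizes and determinism

The default trial is 2 populations x 5 treatments x 12 replicates =
120 plants on 384 x 384 px images; the complexity sweep used for the FD
bounds is 200 silhouettes (5 depths x 2 populations x 20 replicates);
the population-distance ordering is checked over 100 independently
seeded trials through the non-raster twin.  Every random draw derives
its stream from the master seed plus the design labels, so any single
plant can be regenerated in isolation and two runs with the same
configuration are byte-identical.

## What the tests do and do not show

Passing parameter-recovery tests show that the measurement chain
recovers the generator's geometry under the generator's assumptions:
clean white background, in-band plant colour, one connected plant per
image, branches that leave a near-vertical stem at 30--70 degrees.
They do not validate camera calibration, shadow handling, soil or pot
removal, overlapping neighbour plants, or colour constancy on real
photographs — the known weakest link for real images is the assumption
of sRGB primaries for the camera.  The threshold band's orientation
(whether the plant or the background falls inside 135--240) is a
property of the imaging setup; synthetic calibration assumes the plant
is in-band, and real-image use should verify this per dataset rather
than trust the defaults.

## Limitations

* Branch counts above ~15 on a 384 px image begin to saturate as
  laterals crowd; the generator's defaults stay below that regime, and
  larger images relax it.
* The FD estimator uses a single grid origin; origin averaging would
  reduce alignment sensitivity at the cost of determinism of the
  comparison with the closed-form oracles.
* ANOVA assumes a balanced (or near-balanced) factorial with at least
  two replicates per cell and pooled homoscedastic error; mixed models
  and repeated measures are out of scope.
* deltaE is CIE76; perceptually refined variants (deltaE94/2000) are
  deliberately not offered.
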