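---
title: "Methods: from presence records to an offset-sufficiency ledger"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from presence records to an offset-sufficiency ledger}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habfoot)
```

`habfoot` chains five stages — occurrence vetting and thinning, a
presence-background maximum-entropy climate envelope, vegetation-based
refinement, tenure overlay, and offset accounting — into one reproducible
pipeline. This vignette explains the model at each stage, the parameters
that matter, the numerical choices, and what the synthetic landscapes do
and do not demonstrate.

## Occurrence vetting and rounding-based thinning

Opportunistic records carry systematic errors: misattributed subspecies,
ambiguous records beyond the taxon's range limit, and positional errors
(records in the ocean). `vetRecords()` applies these rules in a fixed
order and itemises every removal, so a vetting report can be audited
against a known injection log. Vetting is idempotent.

Spatial thinning mitigates unequal sampling effort: `thinByRounding()`
rounds coordinates to `decimals` places, keeps the **first** record per
rounded pair in input order, and retains the keepers' original
full-precision coordinates for modelling. Two decisions here were
genuinely open and are pinned in tests:

* **Rounding rule.** Decimal rounding is half-away-from-zero, applied to
  the printed decimal representation — the convention of desktop GIS and
  spreadsheet tools, and the one a practitioner rounding coordinate
  columns would get. Banker's rounding would merge a slightly different
  record set.
* **Duplicate retention.** When several records share a rounded key, the
  first in input order is kept. Any stable rule works; first-wins makes
  thinning order-stable and idempotent.
* **Planar coordinates.** On synthetic landscapes coordinates are metres,
  so the pipeline divides by `thin_degree_m` (default 1e5 m) before
  rounding: two and three decimals then merge 1000 m and 100 m blocks, the
  planar analogues of the ~700 m and ~70 m those roundings represent in
  geographic degrees at the study latitudes.

Records with missing year stay available for model fitting but are
excluded from the "recent" (year ≥ 2000) evaluation set: recency is an
evaluation concept, not a fitting one.

## The climate envelope

The envelope is the standard presence-background Maxent, authored in the
package: over the background points the Gibbs density
`q(x) = exp(λ·f(x))/Z` maximises
`mean_pres(λ·f) − log Z − Σ βⱼ|λⱼ|`. Design choices:

* **Target-group background.** Background points are drawn from records of
  co-occurring woodland species collected by the same observers, so the
  urban-proximity sampling bias appears on both sides of the likelihood
  and cancels. Background points are deduplicated by the same rounded key
  as the presences.
* **Features.** Linear + quadratic transforms of the eight bioclimatic
  covariates, min–max scaled to [0, 1] by background statistics and
  clamped. Hinge/product/threshold features are deliberately out: they
  would enlarge the convex problem past the reach of the brute-force
  oracle that certifies the optimiser, and two feature classes already
  capture smooth unimodal responses.
* **Regularization.** `βⱼ = β · max(sd_pres(fⱼ), 0.05)/√m`, the Maxent
  default shape; the 0.05 floor keeps constant features penalized. The
  global multiplier β defaults to 1.
* **Optimiser.** Proximal gradient (ISTA) with backtracking line search on
  the smooth part; convergence is declared when the L1
  subgradient-optimality residual drops below 1e-6 in max norm, capped at
  10 000 iterations (non-convergence is an error carrying the last
  iterate). The objective is convex, so the tests can compare coefficients
  against an independent grid search with refinement to 1e-3 on ≤ 50-cell
  instances.
* **Output transform.** `p = c·q/(1+c·q)` with `c = exp(H)`: the published
  logistic formulation. It is strictly monotone in q (so AUC is unaffected
  by the choice) and calibrated so a featureless model scores exactly 0.5,
  which makes the 0.5 clipping threshold meaningful.
* **AUC** is rank-based (midranks = pairwise enumeration with ½ for ties)
  and computed on the training points: the source analysis reports no
  held-out partitioning, and with presence-only data a test split would
  change the estimand without making it honest.

## Refinement into the habitat model

The thresholded envelope (suitability ≥ 0.5, inclusive) is refined in
three moves, each an exact raster operation on the shared grid:

1. `maskExclusions()` zeroes island and urban cells.
2. `selectFavourableClasses()` counts **full-precision** records per
   vegetation class inside the masked envelope and keeps classes with
   ≥ `min_records` (default 4); water and cleared (non-remnant) classes
   never qualify. A record belongs to the unique cell containing its
   coordinates (half-open intervals), so boundary records are never
   double-counted.
3. `bufferClasses()` / `buildHabitatModel()` buffer the selected classes ∩
   envelope by 1118 m using an exact Euclidean distance transform: a cell
   is habitat iff its centre is within the distance of a selected cell's
   centre. At 250 m cells the 1118 m disc contains 61 cells.

**The buffer is not re-clipped to the envelope.** This was an open
interpretive point; the published area arithmetic (buffered model 15,563
km² against 6,821 km² of suitable classes, which alone lie inside the
envelope) is only consistent with the buffer extending beyond the
envelope, so that is the pinned behaviour — recorded in the model's
provenance string.

Both layers run on the single 250 m analysis grid. Real Regional-Ecosystem
mapping is finer than the climate grid; multi-resolution support was
excluded deliberately, because it would introduce an unspecified
resampling step between every rule, while the single-grid form preserves
each rule exactly and keeps every area reproducible from a mask.

## Evaluation and the two-model comparison

Omission is checked against recent records, commission against the
background points (a proxy: presence-only data has no true absences).
Percentages print at one decimal, half-away — and the two-model
percentage-point difference is computed **from counts before rounding**
(43/2312 → 1.9, where differencing the two rounded rates would give 1.8).
`compareModels()` encodes the adoption reasoning as a configurable
recommendation — flag the compact model when the larger needs ≥ r× the
area (default 3) for < δ percentage points of omission gain (default 2) —
rather than an automatic decision, because the original choice also
weighed map inspection.

## Tenure overlay and offset accounting

All vector layers are rasterized by cell-centre point-in-polygon with
union semantics, so overlapping tenures are counted once; per-type areas
are reported separately and may legitimately sum to more than the union.
Tenures are filtered to those extant at the accounting date (2015-09-07 by
default, `grant ≤ as_of < expiry`), with an explicit whitelist for expired
exploration permits that underpin later detailed mine plans.
`footprintConversion()` pools lease areas within a proponent group against
the group's single measured impact area — proponents sharing one
exploration permit are assessed jointly.

`offsetSufficiency()` finds cleared (non-remnant) cells whose pre-clearing
broad vegetation group is restorable as habitat, inside the climate
envelope; the "available" subset lies within the movement radius (16 km)
of the impact polygon. On synthetic runs the impact polygon is the largest
extant extraction-stage tenure (ML/MDL), and the default required offset
of 5 km² is scaled to the 16 × 16 km synthetic landscape the way a single
mine's federally-conditioned offset (~300 km²) compares to the real
region.

## The synthetic landscape

The generator emulates exactly the structures the pipeline consumes:
eight climate covariates as smooth directional gradients plus low-amplitude
noise; a patchy vegetation mosaic laid out by thresholding smooth random
fields at target areal fractions (realised fractions exact to one cell); a
known logistic true-suitability surface over the standardised covariates
with a wide logit range and a −3 intercept, so clearly suitable climate is
a concentrated minority of the landscape — the regime a range-restricted
species occupies and the one in which a presence-background model is
informative; presences sampled ∝ suitability × bias over favourable-class
cells (with a 2% residual on other land, mimicking use of adjacent cleared
country); a seven-species target-group background sampled ∝ bias alone;
and overlapping, dated tenure rectangles with roughly a fifth expired.
The observation bias is `exp(−strength · d_urban/scale)`, distance to the
nearest urban cell.

Determinism is strict: one root seed feeds named per-stage substreams, so
regenerating occurrences never perturbs tenures, and two runs of
`runPipeline()` produce byte-identical report CSVs.

What passing tests on these landscapes **do not** show: realistic
Australian climate surfaces, real Regional-Ecosystem geometry, spatially
autocorrelated observer effort beyond the single urban-distance kernel,
multi-resolution vegetation mapping, or positional uncertainty in
records. The recovery tests certify the pipeline's arithmetic and
inference under known truth, not the ecological fidelity of any fitted
real-data model.

## Problem sizes and runtime

The default landscape is 64 × 64 cells (16 × 16 km at 250 m) with 500
presences and 2 100 background points; unit tests use 24–48-cell grids and
the Maxent oracle runs on ≤ 50 cells. These sizes were chosen so the full
suite exercises every stage — including two Maxent fits per pipeline run —
in well under a minute, while remaining large enough for the fraction and
recovery tolerances (±0.1 areal fraction on ≥ 64² grids; ≥ 90% recovery of
true favourable-suitable cells) to be meaningful.

## Known limitations

* Cell-centre rasterization has no partial-cell area weighting; areas are
  exact in cell arithmetic but discretize vector boundaries at one
  cell-row.
* Fragmentation, edge effects and linear infrastructure are not modelled
  (the accounting is, if anything, optimistic).
* The AUC of a presence-background model is bounded by the prevalence of
  suitable environment; values are comparable between the two thinning
  levels, not across landscapes.
* Vector-exact (polygon) buffering and geographic-degree grids are out of
  scope; the synthetic world is planar and equal-area by construction.
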