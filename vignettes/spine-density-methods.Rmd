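---
title: "Methods: spine classification, density and cross-stage inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spine classification, density and cross-stage inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinemorph)
```

This vignette documents the scientific and numerical choices behind
`spinemorph`: what is computed, under which assumptions, which knobs
matter, and what the synthetic generator does and does not emulate.

## The measurement model

A dendritic spine is observed as a *protrusion diameter profile*: the
protrusion's diameter sampled along its own arc, from the attachment
point on the dendrite (arc position 0 µm) to the tip. From a profile,
`measure_spine()` extracts the four quantities the classifier uses —
total length, head diameter, maximum neck diameter, neck length — after
deciding whether the protrusion carries a distinguishable head.

Head detection is deliberately simple and parameter-explicit, a
deterministic analogue of the visual "well-formed head" judgement made in
rendering software:

1. find the global diameter minimum (the neck candidate);
2. let `d_head` be the maximum diameter distal to it;
3. declare a head iff `d_head >= head_min_diameter` **and**
   `d_head >= head_prominence_ratio` × the minimum diameter between
   attachment and the position of `d_head` **and** `d_head` exceeds every
   diameter in the neck region.

With a head present, the neck region runs from the attachment to the
thinnest pre-head point; neck length is that point's arc position, and
the neck diameter is the *maximum* over the neck region — the literal
"maximum diameter of the neck" of the classification criteria, not a
mean.

Two numerical details are worth recording. Ties in the pre-head minimum
are resolved *distally*, so a cylindrical neck (constant diameter) is
measured to where the head begins rather than collapsing to length 0.
And condition 3 is not redundant with condition 2: a profile with a
bulbous base and a modest distal bump can pass the prominence test while
its "head" is thinner than the neck's widest point, which would
contradict the definition of a headed spine; such profiles are headless.

Defaults: `head_min_diameter = 0.3` µm (a bulb smaller than that is not a
well-formed head at light-microscopy scale) and
`head_prominence_ratio = 1.2` (the bulb must stand out by 20% from the
thinnest neck point). Both are explicit arguments; analyses of thinner
material (e.g. the SWC round-trip tests, where generated long-thin spines
can carry heads down to 0.13 µm) can lower them.

## The classification rule

Classification is a total, deterministic function of the metrics:

* head present and neck diameter > neck length → **mushroom (M)**;
* head present and neck length ≥ neck diameter → **long thin (LT)**; the
  tie goes to LT because the mushroom criterion demands a *strictly*
  thicker-than-long neck;
* headless and total length < 1 µm → **stubby (S)**;
* headless and total length > 10 µm → **filopodium (F)** (the threshold
  is exposed as `headless_filopodium_min_length`; 10 µm is unusually long
  for filopodia but is applied exactly as published);
* headless and in between — the published criteria are silent. These are
  assigned to S and flagged (`gap_flag`), which keeps the four classes an
  exhaustive partition while making the gap auditable. Both boundary
  lengths (exactly 1 µm and exactly 10 µm) fall in the gap because the
  published inequalities are strict. The synthetic generator never emits
  gap geometries, so recovery tests are unaffected by this choice.

## Densities and summaries

Each traced secondary-trunk segment contributes its own arc length L
(≥ 10 µm; the package refuses shorter segments unless `allow_short =
TRUE`, since the tracing rule is part of the measurement definition).
Class densities are counts normalised to the segment's *actual* length,
`count / L × 10` — "at least 10 µm" implies variable lengths were traced,
so truncating to exactly 10 µm would bias against longer segments. Class
densities therefore sum exactly to the total density on every record, a
property the tests assert.

`stage_summary()` reports mean ± SE (sample SD/√n) with segments as the
unit of analysis — no per-animal or mixed-effects modelling, mirroring
the design being reproduced — plus pooled class means over all segments,
which for a balanced design equal the average of the stage means.

Regressions of density on body size use per-animal mean densities (the
published account does not state whether animal means or pooled segment
densities were used; per-animal means avoid pseudo-replication and are
recorded here as the package's choice), on log₁₀-transformed metrics
(the base is not stated either; base 10 is conventional for body-size
allometry). Significance requires both R² ≥ 0.7 and slope p < 0.05. A
constant response is reported as R² = 0 rather than NaN.

## Inference

The cross-group battery is deliberately nonparametric. Shapiro–Wilk is
computed on the total densities but is *advisory only*: the pipeline
never switches to a parametric branch, because density data — quotients
of small integer counts — are tied and skewed, and the analysis being
reproduced proceeded nonparametrically throughout.

`kruskal_wallis()` always applies the tie correction
1 − Σ(t³ − t)/(N³ − N); with per-segment densities ties are pervasive.
`dunn_posthoc()` uses the pooled-variance mean-rank Z with the matching
tie term. Raw two-sided normal p values are the default (`adjust =
"none"`), matching the raw-Z reporting style of the tables being
mirrored; Bonferroni and Holm are available by flag, and adjusted p
values are never smaller than raw ones. The star-code map is strict at
every threshold, so p = 0.05 exactly prints `ns`.

The asymptotic normal p for Dunn's Z is accurate to about 0.02 against a
200,000-permutation null at six observations per group (the tests verify
this); at three or four observations per group mid-range p values can
deviate by about 0.03 — small-sample inference should use a permutation
approach directly.

## The synthetic generator

The generator exists so the entire pipeline can be exercised and
validated without the original Golgi-Cox material, which was never
deposited. Its defaults *are* the published study conditions: four
stages × 77 segments (308 total), segment lengths uniform on 10–14 µm
("at least 10 µm" with no stated upper bound; a few extra µm of tracing
is what an operator would plausibly do), 19 animals (5/5/5/4 per stage)
with biometrics drawn from truncated-at-zero normals using the published
per-stage means and SDs, and per-class spine counts with mean
`rate × L/10` from the calibrated rate table.

**Rate-table calibration.** Only 8 of the 16 stage × class mean rates
were printed, alongside all four stage totals and the four pooled class
means. `calibrate_rate_table()` completes the matrix exactly as the
printed constraints dictate: missing filopodium cells share the pooled-F
residual `4 × 0.07 − 0.18 = 0.10` in fixed decreasing proportions
(0.6/0.3/0.1 → 0.06, 0.03, 0.01), consistent with the reported
progressive disappearance of filopodia toward the silver stage; each
stage's remaining residual goes to its single missing cell, or is split
equally when both S and LT are missing — which enforces the reported
"no difference between S and LT" equalities. The result is validated:
rows sum to the printed totals, pooled means match within ±0.02 (±0.01
for F), and infeasible inputs (a class mean above its stage total, a
negative residual) raise calibration errors rather than silently
clipping.

**Counts.** The dispersion multiplier φ (variance = φ × mean) defaults
to 1, i.e. Poisson counts. The printed SEs (≈ 0.15 at mean 6.67 with
n ≈ 77) actually imply *sub*-Poisson spread, so φ < 1 (binomial
thinning) and φ > 1 (gamma-mixed Poisson) are exposed; but the real
per-segment count distribution is unknowable from printed summaries, so
no φ is claimed to be "the" study's value, and all calibration-recovery
checks state their tolerances under φ = 1.

**Geometries.** Spine geometries are drawn from class-conditional ranges
that satisfy the classifier by construction (e.g. mushroom necks are
strictly shorter than thick, long-thin necks at least 1.1 × longer than
thick; headed totals are neck length + head diameter, the head modelled
as a terminal bulb), so the generator→classifier round trip is exact —
the tests demand 100% agreement on 10,000 draws per class. Headless
geometries avoid the 1–10 µm gap entirely.

**Biometrics are independent of density.** The published analysis found
no density–body-size correlation; simulating independence reproduces
that null result without inventing a coupling, and the tests confirm all
three regressions stay below the R² = 0.7 criterion in ≥ 95% of 200
replicate studies.

**What the generator does not emulate.** Real confocal material has
operator-dependent tracing error, partially stained neurons (Golgi-Cox
impregnates only a few percent of cells), spatial clustering of spines
along the trunk, within-animal correlation between segments, and an
unknown count dispersion. Passing recovery tests therefore shows the
*pipeline* is correct and the printed summary geometry is internally
consistent — not that the simulated data are statistically
indistinguishable from the original microscopy. In particular the
published H and Z statistics depend on the real dispersion and are not
reproducible from printed means and SEs; the package instead verifies
the recoverable property that, under the calibrated simulation, the
four-stage comparison of total density rejects at p < 0.001 essentially
always and the glass stage exceeds the yellow stage in every replicate.

**Polylines.** Each segment can carry a smooth 3-D random-walk polyline
whose arc length equals the drawn segment length to floating-point
accuracy; SWC export encodes spines as tag-7 child branches. Densities
never depend on the polyline, so `include_polylines = FALSE` skips them;
replicate-heavy analyses (the 200-study regression check, the acceptance
script) use that mode. Problem sizes used by the checks — 2000
segments/stage for mean recovery, 200 replicate studies for the
regression null, 100 for the separation property, 2000 simulations for
the type-I error band [0.035, 0.065] — were chosen as the smallest sizes
at which the Monte-Carlo error is far below the tolerance being
asserted.

## Degenerate inputs and errors

* All-identical observations: rank tests refuse with a degenerate-data
  error (H would be 0/0 after tie correction).
* Stages with fewer than two segments: SE undefined, `stage_summary()`
  errors.
* Spines referencing unknown segments, non-positive biometrics,
  non-positive arc lengths, malformed SWC lines (reported with their
  line number), dangling SWC parents: all hard errors, never silent
  repair.
* `run_pipeline()` in `from_files` mode never touches the generator or
  the RNG (the tests assert the RNG state is untouched), so file-based
  analyses are bit-reproducible by construction; synthetic runs are
  reproducible given (config, seed), which the manifest records along
  with input/output MD5 hashes.

## Known limitations

Segments are the unit of inference, so between-animal variance is not
modelled; the gap rule and the 10 µm filopodium threshold are faithful
to the published criteria but not to the wider spine literature (most of
which uses ~2 µm for filopodia); the head-detection algorithm is an
operationalisation of a visual judgement and its two thresholds should
be reported alongside any new dataset analysed with it.
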