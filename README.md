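# spinemorph

Dendritic spine morphometry and density analysis for olfactory-bulb
granule cells of the European eel (*Anguilla anguilla*).

Granule cells (GCs) are the axonless inhibitory interneurons of the
olfactory bulb; their dendritic spines form the dendro-dendritic synapses
through which odour processing is modulated, and their density and shape
are a morphological index of synaptic plasticity. In the eel, which
migrates by olfactory navigation, GC spine density changes across the
continental life stages (glass eel, elver, yellow eel, silver eel).
`spinemorph` implements the quantitative side of that analysis as a
reusable, tested pipeline:

- **Rule-based spine classification.** Each protrusion is measured
  (total length ℓ, head diameter d<sub>h</sub>, maximum neck diameter
  d<sub>n</sub>, neck length ℓ<sub>n</sub>, all µm) and assigned to one of
  four classes:

  | class | rule |
  |---|---|
  | mushroom (M) | head present (d<sub>h</sub> > d<sub>n</sub>), neck thicker than long (d<sub>n</sub> > ℓ<sub>n</sub>) |
  | long thin (LT) | head present, neck longer than thick (ℓ<sub>n</sub> ≥ d<sub>n</sub>) |
  | stubby (S) | no distinguishable head, ℓ < 1 µm |
  | filopodium (F) | no distinguishable head, ℓ > 10 µm |

  Headless protrusions of 1–10 µm fall outside the published criteria;
  they are assigned to S and flagged (`gap_flag`) so the choice is
  auditable.

- **Spine density.** For each traced secondary-trunk segment (arc length
  L ≥ 10 µm), density per class c is n<sub>c</sub>/L × 10 spines/10 µm;
  summaries are mean ± SE per stage × class.

- **Nonparametric statistics.** Tie-corrected Kruskal–Wallis
  H = [12/(N(N+1)) Σ n<sub>i</sub>(R̄<sub>i</sub> − (N+1)/2)²] / (1 − ΣT/(N³−N)),
  and Dunn's pairwise post hoc
  Z<sub>ab</sub> = (R̄<sub>a</sub> − R̄<sub>b</sub>) / √[(N(N+1)/12 − ΣT/(12(N−1)))(1/n<sub>a</sub> + 1/n<sub>b</sub>)],
  with the star codes `****`/`***`/`**`/`*`/`ns`; plus OLS regressions of
  per-animal mean density on log₁₀ body metrics (a correlation counts as
  significant only when R² ≥ 0.7 and p < 0.05).

- **Morphology I/O.** A 7-column SWC dialect (spine branches carry
  structure tag 7, `# key: value` metadata headers), protrusion diameter
  profiles, and a deterministic head/neck measurement algorithm
  (`measure_spine()`).

- **Calibrated synthetic studies.** `calibrate_rate_table()` completes
  the published stage × class mean-rate matrix from the printed totals and
  pooled means; `generate_study()` simulates full studies (308 segments,
  19 animals with stage-specific biometrics, Poisson spine counts,
  class-conditional geometries) so every downstream step is testable
  without the original Golgi-Cox material.

## Worked example

```r
library(spinemorph)

ds  <- generate_study(study_config(seed = 42), include_polylines = FALSE)
fit <- spine_study(ds)
summary(fit)
```

```
spine_study: 308 segments, 4 stages

Mean total density (spines/10 um):
  glass     6.42 +- 0.27  (n = 77)
  elver     4.46 +- 0.25  (n = 77)
  yellow    3.68 +- 0.20  (n = 77)
  silver    5.48 +- 0.25  (n = 77)
  pooled    5.01 +- 0.13  (n = 308)

Total density across stages: H = 57.39, df = 3, p = 2.12e-12 ****

Stage x class mean densities (spines/10 um):
        measure
stage        M    LT     S     F total
  glass  2.758 2.325 1.124 0.214 6.421
  elver  2.372 0.985 1.021 0.079 4.457
  yellow 1.505 0.949 1.201 0.025 3.681
  silver 2.529 1.398 1.545 0.010 5.482

Shapiro-Wilk on total densities: W = 0.983, p = 0.00084 (non-normal; rank tests used)

Dunn post hoc, total density across stages (adjust = none ):
             pair      Z         p code
1   glass - elver  4.941 7.775e-07 ****
2  glass - yellow  7.065 1.611e-12 ****
3  glass - silver  2.206 2.738e-02    *
4  elver - yellow  2.124 3.370e-02    *
5  elver - silver -2.735 6.240e-03   **
6 yellow - silver -4.859 1.182e-06 ****

Regressions of per-animal mean density on log10 biometrics:
  TL: R^2 = 0.195, p = 0.0584
  TW: R^2 = 0.180, p = 0.0701
  BW: R^2 = 0.140, p = 0.114
```

Reading this output: total spine density is highest in the two migratory
stages (glass ≈ 6.4 and silver ≈ 5.5 spines/10 µm) and lowest in the
resident yellow-eel stage (≈ 3.7), the Kruskal–Wallis test rejects equal
medians across stages, Dunn's test localises the differences to every
pair except the weakest contrasts, and none of the body-size regressions
reaches the R² ≥ 0.7 significance criterion — the density pattern tracks
life stage, not body size.

`run_pipeline()` wraps the same analysis end to end (synthetic or
from TSV/SWC-derived input files) and writes the density, summary,
Kruskal–Wallis, Dunn and regression tables plus a JSON run manifest;
`plot(fit)` draws the stage × class bar chart with SE whiskers.

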