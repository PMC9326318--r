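---
title: "Multiparametric spatial habitat mapping: model, parameters, and validation"
author: "gliohabitats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric spatial habitat mapping: model, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliohabitats)
```

## The model

High-grade gliomas are spatially heterogeneous: perfusion, hypoxia and
cellularity vary across the lesion, and a single whole-tumor summary
hides biologically distinct subregions. Spatial habitat mapping makes
that heterogeneity explicit by clustering voxels of coregistered
parametric maps. `gliohabitats` works with the triple

* **Vp** — plasma volume from DCE-MRI (mL/100 mL), a proxy for
  neoangiogenesis and perfusion;
* **FAZA** — ¹⁸F-fluoroazomycinarabinoside PET uptake (arbitrary or
  SUV-like units), trapped in hypoxic but viable cells;
* **MD** — mean diffusivity from DTI (mm²/s), inversely related to
  cellularity.

Inside a tumor mask, each map $D_i$ is split into a *low* and *high*
cluster, $D_i \to [D_{iL}, D_{iH}]$ with $D_{iL} \cap D_{iH} =
\emptyset$, by a per-subject, per-map Otsu threshold. The intersection
of the three binary volumes yields $2^3 = 8$ **habitats**, labelled in
the fixed column order (perfusion, hypoxia, diffusivity):

| habitat | Vp | FAZA | MD | usual reading |
|---|---|---|---|---|
| 1 | H | H | H | perfused, hypoxic "vital" rim |
| 2 | H | H | L | perfused, hypoxic, high cellularity — the most aggressive core |
| 3 | H | L | H | fragmented, near vessels/cortex |
| 4 | H | L | L | fragmented, near vessels/cortex |
| 5 | L | H | H | necrosis with residual viable tissue |
| 6 | L | H | L | intermediate, inner tumor core |
| 7 | L | L | H | vasogenic edema (largest MD) |
| 8 | L | L | L | infiltrative edema / blood products / cortex |

The pipeline in `compute_habitats()` is:

1. resample all inputs onto a common 1 mm isotropic analysis grid
   (trilinear for maps, nearest neighbour for masks) when they are not
   already aligned — inputs are assumed *coregistered*; only grid
   resampling is provided, not registration;
2. apply the voxel inclusion rule per map: keep in-mask voxels with
   finite values within `mean ± k·SD` of the in-mask distribution
   (`outlier_k = 3` by default);
3. compute the Otsu threshold of the included values of each map;
4. binarize (value `> T` is high, `≤ T` low);
5. intersect the three cluster volumes into labels 1–8; a voxel excluded
   on *any* map gets label 0.

Because thresholds are computed per subject and per map, the habitat map
is invariant to positive rescaling of any input map; that also means no
inter-scanner intensity harmonization is attempted (or needed) for the
clustering itself.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `mask_flavor` | `FLAIR` | — | clustering ROI; the whole FLAIR-hyperintense tumor gives larger, reproducible clusters than the CE core alone |
| `n_bins` | 256 | bins | Otsu histogram resolution; 256 is the conventional grayscale choice |
| `outlier_k` | 3 | SD | inclusion cut; excludes ≈0.27 % of voxels under normality |
| `excluded_policy` | `drop` | — | label-0 voxels stay unassigned; `nearest-cluster` reassigns them to the closer class mean per map |
| `allow_degenerate` | `FALSE` | — | a constant map is an error by default (it indicates an upstream fault); forcing it assigns all-low |
| sphere `diameter` | 5 | mm | biopsy VOI size, matching the reported stereotactic accuracy margin |

## Numerical choices

* **Otsu implementation.** The threshold maximizes
  $\sigma_b^2(t)=\omega_0\omega_1(\mu_0-\mu_1)^2$ over the 255 interior
  bin edges of a 256-bin histogram spanning the included value range;
  class means use bin centres; ties go to the smallest threshold, and
  the reported $T$ is the upper edge of the selected bin. Values exactly
  at $T$ are *low*. When two partitions are nearly tied in
  $\sigma_b^2$ (relative gaps below ~10⁻⁴ occur in practice), the
  histogram optimum and the exact data-level optimum may sit several
  bins apart while being variance-equivalent; the test suite therefore
  checks that the histogram partition attains the exhaustive data-level
  maximum (within 10⁻³ relative) and demands voxel-identical
  classification only when the optimum is unique.
* **Resampling.** World coordinates are mm in RAS+; voxel indices are
  0-based and a voxel is identified with its centre. Only axis-aligned
  grids are supported. Trilinear interpolation is a convex combination,
  so it cannot overshoot the source range; target voxels outside the
  source grid become `NA` and are treated as outside-mask downstream.
* **Fraction denominator.** Habitat fractions are percentages of
  *assigned* voxels (labels 1–8), not of the whole ROI; with the default
  3-SD rule the two denominators differ by well under 1 %.
  Empty habitats contribute 0 % to fractions but are `NA` (never 0) in
  the median tables. MD medians are reported ×10³ (10⁻³ mm²/s), the
  conventional display scale.
* **Multifocal tumors** are treated as one voxel set: thresholds are
  global per subject.

## Nonparametric statistics

Group comparisons mirror standard neuro-oncology cohort practice:
Mann–Whitney U for two groups, Kruskal–Wallis across habitats, Dunn's
post hoc z tests with Bonferroni correction (`p_adj = min(1, m·p)`,
`m = k(k−1)/2`). The Mann–Whitney p-value is the exact two-sided
permutation value whenever both groups have ≤20 observations and there
are no ties; with ties the enumeration null is invalid, so the
tie-corrected normal approximation (no continuity correction) is used
instead.

One note on the bundled cohort: for habitat 7 fractions grouped by
IDH-1 status (14 wild-type vs 3 mutated) the exact two-sided p is
31/340 ≈ 0.091, while the exact one-sided p is 31/680 ≈ 0.046. A
reported significance of 0.05 for this comparison is consistent only
with the one-sided reading; the package always reports the two-sided
value.

Kruskal–Wallis p-values use the χ² approximation with k−1 degrees of
freedom; for very small, extreme samples this approximation is known to
be conservative relative to the exact permutation null (the tests
compare the two only in a regime where the approximation is valid, and
verify the tie-corrected H statistic itself against the textbook rank
formula).

## The synthetic phantom

No patient imaging ships with the package, so validation runs on
phantoms with known ground truth (`generate_phantom()`):

* **Geometry.** Five concentric ellipsoidal shells (default semi-axes
  16/21/24/27/29 mm along x, axis ratios 1/0.85/0.7) carrying habitats
  5, 2, 1, 6, 8 from the inside out, plus a 3 mm halo of habitat 7 —
  an idealization of the roughly concentric arrangement seen in real
  lesions (necrotic centre, aggressive core, edema rim). The CE mask
  covers the shells with habitats 1/2/5/6 plus the core; the FLAIR mask
  covers everything, so CE ⊂ FLAIR. Habitats 3 and 4, which are
  fragmented and scarce in real tumors, are injected as ~2 mm
  peripheral speckle blobs totalling `speckle_fraction` (default 5 %)
  of the tumor volume. The default radii give the six *zone* habitats
  comparable volumes (≈12–26 % each): the phantom is a recovery test
  harness, not a realism claim, and heavily unbalanced zones would make
  per-habitat overlap metrics uninformative for the small ones.
* **Intensities.** Each habitat fixes an H/L state per map; voxel
  values are drawn i.i.d. `Normal(mu_state, sigma)` with default level
  means Vp 1.0/4.9 mL/100 mL, FAZA 0.3/1.4, MD 0.98/1.32 ×10⁻³ mm²/s —
  values typical of edematous vs. actively perfused/hypoxic/cellular
  glioma tissue. The single `separation` parameter
  `(mu_H − mu_L)/sigma` (default 4) tunes recovery difficulty; MD is
  clipped at 0 to stay physically valid.
* **What it does not emulate.** Partial-volume averaging, spatially
  correlated noise, registration error, scanner drift, Rician PET/MR
  noise statistics, and anatomically realistic lesion shapes. Passing
  recovery tests therefore demonstrates correctness of the clustering
  machinery under the stated intensity model, not clinical performance.

## Expected recovery, and an honest limit

With class separation $s$, a voxel's state on one map is misread with
probability $\approx \Phi(-s/2)$ (2.3 % at $s=4$). A habitat collects
false positives from the three habitats whose H/L triple differs in
exactly one map, so its Dice coefficient is governed by the ratio of
its Hamming-1-neighbour volume to its own volume. For the six zone
habitats that ratio is 1–5 and Dice lands at 0.92–0.95 at $s=4$
(exactly 1.0 at zero noise). For the speckle habitats 3 and 4 (≈2.5 %
of the tumor each) the ratio is ≈13–17 and the attainable Dice is
≈0.81–0.84 — a property of voxel-wise thresholding with small classes,
not of this implementation; no geometry with realistically scarce
habitats 3/4 escapes it. The recovery test suite reflects this: zone
habitats are required to exceed 0.9, and the speckle habitats document
the limit.

## Problem sizes

Unit and property tests run on 64³ phantoms (≈15 k tumor voxels,
sub-second per pipeline run); recovery checks use the default 96³
phantom (≈82 k tumor voxels). The cohort statistics are pure arithmetic
on the bundled 17-patient tables and run in milliseconds.

## Known limitations

* Only axis-aligned RAS+ NIfTI grids are read; oblique acquisitions
  must be reformatted upstream.
* Serialized label maps keep labels 0–8 only, so a reloaded map cannot
  distinguish in-ROI-unassigned voxels from background.
* The histology join is descriptive; no inferential statistic links
  habitats to cellularity or necrosis grades.
* Survival handling is descriptive (mean/median/range); no
  time-to-event modelling.
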