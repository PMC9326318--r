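# gliohabitats

Voxel-wise **spatial habitat mapping** of high-grade gliomas from three
coregistered parametric volumes: DCE-MRI plasma volume (**Vp**,
perfusion/neoangiogenesis), ¹⁸F-FAZA PET uptake (**hypoxia**) and DTI
mean diffusivity (**MD**, inversely related to cellularity). It is
aimed at neuroimaging researchers who want a tested, scriptable
implementation of the habitat pipeline — from NIfTI maps and tumor
masks to habitat label maps, cohort statistics, and biopsy-site habitat
profiles — plus a synthetic phantom generator with ground-truth labels
for validating the whole chain.

## Method

Inside a tumor mask (the FLAIR-hyperintense volume by default), each
map `D_i` is binarized at a per-subject **Otsu threshold** `T_i`, the
cut maximizing the between-class variance

```
sigma_b^2(t) = w0(t) * w1(t) * (mu0(t) - mu1(t))^2
```

over a 256-bin histogram of the included voxel values (voxels outside
`mean ± 3 SD` of the in-mask distribution are excluded first). The
three high/low cluster volumes are intersected into **8 habitats**,
labelled in the fixed order (perfusion, hypoxia, diffusivity):
`1 = HHH, 2 = HHL, 3 = HLH, 4 = HLL, 5 = LHH, 6 = LHL, 7 = LLH,
8 = LLL`. Downstream the package computes per-subject habitat volume
fractions and per-habitat map medians, cohort summaries grouped by
IDH-1 status / WHO grade / MGMT status with nonparametric tests
(Mann–Whitney U with exact small-sample p, Kruskal–Wallis,
Dunn–Bonferroni), and prevalence-ordered habitat profiles of 5-mm
spherical VOIs at stereotactic biopsy coordinates.

## Worked example

Generate a default phantom (96³ voxels at 1 mm, six concentric zone
habitats plus habitat-3/4 speckles, 4-sigma class separation), run the
pipeline, and sample a biopsy VOI:

```r
library(gliohabitats)

ph  <- generate_phantom(phantom_spec(), seed = 42)
map <- compute_habitats(ph$vp, ph$faza, ph$md, ph$truth$flair_mask)
map
#> <habitat_map> subject 'phantom', 81602 ROI voxels, 81598 assigned (labels 1-8), 4 unassigned
#>   habitat counts: 1:10644 2:12531 3:2643 4:2486 5:10506 6:13284 7:18716 8:10788

round(unlist(habitat_fractions(map)[paste0("frac_", 1:8)]), 1)
#> frac_1 frac_2 frac_3 frac_4 frac_5 frac_6 frac_7 frac_8
#>   13.0   15.4    3.2    3.0   12.9   16.3   22.9   13.2

round(habitat_dice(map, ph$truth), 3)
#> habitat_1 habitat_2 habitat_3 habitat_4 habitat_5 habitat_6 habitat_7 habitat_8
#>     0.941     0.944     0.813     0.831     0.920     0.939     0.952     0.931

voi_habitat_profile(map, sphere_voxels(map$grid, c(0, 0, 18), diameter = 5))
#> <voi_habitat_profile> habitats [6, 8, 1, 2, 4, 5], dominant fraction 0.48, 0/81 voxels unassigned
```

Reading: 81,602 tumor voxels were clustered (4 fell outside the 3-SD
inclusion band on at least one map); the recovered fractions match the
phantom's zone volumes, and recovery overlap (Dice) is 0.92–0.95 for
the six zone habitats. The small speckle habitats 3/4 sit near 0.82 —
the expected ceiling for voxel-wise thresholding of classes that make
up only ~2.5 % of the tumor each (see the methods vignette in
`vignettes/habitat-mapping.Rmd`). The VOI profile lists habitats by
prevalence inside the 5-mm sphere, the order used to report biopsy
sites.

Cohort statistics work the same way on real fraction tables; the
package bundles a published 17-patient high-grade-glioma cohort as
fixtures:

```r
ct <- cohort_table(load_fixture("table2"))
round(ct$row_average, 1)
#> habitat_1 habitat_2 habitat_3 habitat_4 habitat_5 habitat_6 habitat_7 habitat_8
#>       4.5      12.2       4.5       5.2       4.2       7.1      30.5      31.8
```

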