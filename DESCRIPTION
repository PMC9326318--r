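Package: gliohabitats
Title: Multiparametric PET/MRI Spatial Habitat Mapping of High-Grade Gliomas
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Voxel-wise spatial habitat analysis of high-grade gliomas from
    coregistered perfusion (DCE-MRI plasma volume), hypoxia (18F-FAZA PET)
    and diffusion (DTI mean diffusivity) parametric maps. Each map is
    binarized inside a tumor mask with a per-subject Otsu threshold after a
    mean +/- 3 SD voxel inclusion rule, and the three high/low cluster
    volumes are intersected into eight tumor habitats. The package provides
    NIfTI volume handling and grid resampling, per-subject habitat volume
    fractions and per-habitat map medians, nonparametric cohort statistics
    (Mann-Whitney, Kruskal-Wallis, Dunn-Bonferroni), spherical
    volume-of-interest sampling at stereotactic biopsy coordinates, and a
    synthetic multiparametric phantom generator with ground-truth habitat
    labels for pipeline validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    EBImage
Config/testthat/edition: 3
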