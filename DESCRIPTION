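Package: shrinkvec
Title: Shrinkage Vector Analysis of Dental Composites from Paired Micro-CT Scans
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies polymerization shrinkage of dental resin composites from
    paired micro-CT scans taken before and after light curing. Radiolucent tracer
    spheres (glass beads or air bubbles) embedded in the composite are segmented
    with sub-voxel centroids in both scans; the scans are brought into a common
    frame by rigid registration on static tooth structure; sphere correspondence
    is established by block matching with centroid gating; and per-sphere 3D
    shrinkage vectors (displacement, magnitude, signed axial component) are
    computed, exported as glyph files, and compared across experimental groups
    with Shapiro-Wilk normality checks, one-way ANOVA and Tamhane's T2 post hoc
    test with a compact letter display. A synthetic restoration phantom with
    known ground truth (cylindrical cavity, composite layers, tracer spheres,
    analytic shrinkage fields, rigid pose offset, scanner noise) supports
    validation and parameter-recovery studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    tiff,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
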