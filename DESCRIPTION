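Package: palatasym
Title: Directional and Fluctuating Asymmetry of 3D Palatal Landmark Configurations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Object-symmetry analysis of bilateral 3D landmark configurations,
    built around the human palate during growth. Implements generalized
    Procrustes superimposition with unit centroid-size scaling, thin-plate
    spline bending energy and sliding of curve and surface semilandmarks,
    reflection/relabelling symmetry decomposition into directional (DA) and
    fluctuating (FA) asymmetry at configuration and per-landmark resolution,
    Procrustes ANOVA with residual-randomization permutation, and the
    accompanying between-group test battery (PERMANOVA, dispersion
    homogeneity, Tukey HSD, Kruskal-Wallis with Dunn post-hoc, Spearman rank
    correlation, Mann-Whitney, Bonferroni correction). Includes a synthetic
    generator of bilateral palate-like populations with known asymmetry
    ground truth, readers and writers for common landmark interchange formats
    (CSV, TPS, Morphologika) and ASCII triangle meshes (PLY, OBJ, STL), and a
    config-driven pipeline reproducing the full analysis workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    vegan,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
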