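Package: prostereo
Title: Design-Based Stereology of Glandular Tissue with Phantom Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A design-based stereology toolkit for quantitative histology of
    tubulo-glandular organs such as the rodent ventral prostate. Provides a
    voxelized three-dimensional tissue phantom generator with analytically
    known volume, length, surface and particle densities; isotropic uniform
    random (IUR) sectioning with systematic uniform random field sampling;
    the classical unbiased estimators (Delesse area-fraction volume density,
    tubule length density from profile counts in an unbiased counting frame,
    cycloid-grid surface density, optical-disector numerical density);
    integrated optical density (IOD) nuclear densitometry; and the cohort
    statistics layer (balanced two-way ANOVA, pooled-variance t, exact
    Mann-Whitney) used to compare treated and control groups. Estimators are
    validated against phantom ground truth, and published group summary
    tables from a carbamazepine prostate toxicology study are embedded for
    internal-arithmetic consistency checking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
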