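Package: dcquant
Title: Quantification of Drosophila Dorsal Closure Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify the dynamics of dorsal closure in Drosophila
    embryos from segmented time-lapse label movies: amnioserosa cell pulsation
    amplitude and frequency, a convex-hull cell-shape index, dorsal-hole
    closure kinetics (width and length series, leading-edge convergence
    speed, zipping speed, closure duration, length-to-width ratio),
    filopodia counts and lengths from polyline annotations, and the
    accompanying nonparametric and parametric multi-group statistics
    (Kruskal-Wallis with Dunn's post hoc test, one-way ANOVA with Dunnett's
    test, chi-square on phenotype counts). A synthetic-embryo generator
    renders ground-truthed label movies with parameterized closure-speed
    profiles and sinusoidally pulsing polygonal cell sheets so that every
    analysis stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    mgcv,
    multcomp,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    withr,
    optparse
Config/testthat/edition: 3
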