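Package: aortomorph
Title: Quantitative Histomorphometry of the Aortic Media
Version: 0.1.0
Authors@R: person("Aortomorph", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative histomorphometry of the ascending aortic wall:
    colour segmentation of Movat pentachrome, Verhoeff, Verhoeff-Van Gieson
    and H&E stained medial fields into elastin, cytoplasm, collagen and
    glycosaminoglycan fractions; elastic lamella counting, thickness and
    interlamellar spacing along transects with branch exclusion; medial
    nuclei counting; vessel layer thickness from ring sections; derived
    cross-sectional quantities (media area, component amounts per
    cross-section, smooth muscle cell number) against aortic diameter
    nomograms; an area-conservation model of medial thinning under lumen
    dilatation with pre-aneurysmal reverse-remodeling predictions; and the
    matching nonparametric statistics (exact Mann-Whitney, Freeman-Halton
    r x c exact tests, Kruskal-Wallis with Dunn post hoc, Spearman
    correlation and inter-rater agreement). Includes a seeded synthetic
    stain-image and cohort generator with known ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    grDevices,
    tools,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
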