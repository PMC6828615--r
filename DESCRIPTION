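Package: biofilmscale
Title: Spatial Heterogeneity Analysis of Drinking-Water Biofilms Across Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify spatial heterogeneity of tubing biofilms from
    micrometre to metre scale. Includes a synthetic shower-hose biofilm
    generator with known ground truth (longitudinal thickness field,
    per-section total cell concentrations, multinomial taxa count tables,
    rendered optical-coherence-tomography style B-scan images), B-scan
    thickness extraction by gray-scale gradient analysis with artifact
    masking and manual overrides, per-section heterogeneity statistics
    (adjacent-section variation, fold ranges, longitudinal trends,
    sampling-representativeness curves), community diversity and dominance
    metrics (richness, Shannon, Pielou evenness, Bray-Curtis), and biofilm
    and bacterial-cell volume reconstruction.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
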