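Package: hyperleaf
Title: Hyperspectral Leaf Reflectance and Image-Based Phenotyping of Combined Abiotic Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for combined cold and salt stress phenotyping of
    pepper (Capsicum) leaves. Smooths leaf reflectance spectra with a
    three-point weighted mean, computes first-derivative spectra and locates
    the red-edge peak, evaluates eight vegetation indices (RGI, PRI, NDRE,
    NDVI, green NDVI, ZMI, GM1, FLAV), converts spectrophotometric absorbances
    into chlorophyll and carotenoid concentrations, quantifies phenolics and
    flavonoids via linear calibration curves, derives growth (relative growth
    rate from projected leaf area) and color (excess greenness) phenotypes
    from plant images, and runs a gated statistics layer (ANOVA/Tukey or
    Kruskal-Wallis/Dunn with compact letter displays, wavelength-wise and
    index-trait Pearson correlations). A synthetic leaf-optics generator with
    a logistic red edge and chlorophyll-coupled visible features provides
    ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    png,
    tiff,
    optparse,
    jsonlite
Config/testthat/edition: 3
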