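Package: mangohsi
Title: Hyperspectral Assessment of Impact Damage in Mango Fruit
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Chemometric pipeline for evaluating impact (drop) damage to mango
    from near-infrared hyperspectral images. Provides ENVI-style cube input
    and output with dark/white reflectance calibration and region-of-interest
    mean spectra; Savitzky-Golay, standard normal variate and multiplicative
    scatter correction preprocessing; NIPALS partial least squares regression
    with leave-one-out cross-validation for pulp firmness, total soluble
    solids, titratable acidity and chroma; competitive adaptive reweighted
    sampling (CARS) for key-wavelength selection; Fisher discriminant
    analysis of damage severity classes defined by a ripening index; and a
    synthetic-data generator that emulates the drop-test study design so the
    whole pipeline is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
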