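Package: cryodom
Title: Molecular Dynamics of Dissolved and Particulate Organic Matter in
    Glacier Algal Habitats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for molecular-level analysis of dissolved and particulate
    organic matter (DOM/POM) in glacier ice-algae and snow-algae habitats
    profiled by ultrahigh-resolution mass spectrometry. Implements CHNOSP
    molecular-formula enumeration and assignment from negative-mode peak
    lists (method-detection-limit filtering, mass recalibration,
    homologous-series network validation, carbon-13 isotopologue checks,
    blank subtraction and duplicate merging), van Krevelen molecular
    descriptors and categories (AImod, NOSC, DBE, CRAM, oxy-aromatic
    phytochemicals), classification of light/dark incubation time courses
    into transferred, photoproduced, photo-degraded, heterotrophically
    produced/degraded and refractory pools, and Bray-Curtis NMDS ordination
    of molecular composition. A synthetic-experiment generator with planted
    process classes provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    vegan,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
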