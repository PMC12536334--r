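Package: psdrisk
Title: Multi-Matrix Chemical Risk Assessment with Passive Samplers and
    Invertebrate Biomonitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-matrix monitoring campaigns of
    contaminants of emerging concern in freshwater. Reads and validates
    tidy campaign tables (water grab samples, multi-sorbent passive
    sampler disks, invertebrate tissue); calibrates sampler uptake rates
    from laboratory time series and derives time-weighted-average water
    concentrations; computes risk quotients (MEC/PNEC) with four-band
    classification, internal toxic units and effect units for a benthic
    invertebrate; compares chemical occurrence across matrices with set
    algebra, per-replicate min-max scaling, PCA and hierarchical
    clustering; calibrates sampler-derived against biota-derived effect
    units with k-fold cross-validation, including the sampler-as-organism
    substitution that treats the sorbent disk as a surrogate organism;
    and simulates complete synthetic campaigns with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
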