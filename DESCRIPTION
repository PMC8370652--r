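Package: wsforecast
Title: Forecasting Adaptive Mutations in the Pseudomonas Wrinkly Spreader System
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for forecasting the distribution of adaptive wrinkly spreader
    (WS) mutations in static-microcosm experimental evolution of Pseudomonas.
    Implements a minimal variant-effect annotator for coding and promoter
    mutations, mutational target-size enumeration (stop-gain sites, frameshift
    sites, direct-repeat deletion scanning, region-restricted missense counts),
    a rate-weighted null model over the Wsp, Aws and Mws c-di-GMP signalling
    pathways, a Luria-Delbruck-style simulator of static-well evolution with
    colony screening, selection-coefficient estimation from competition-assay
    CFU counts, and goodness-of-fit scoring of hierarchical evolutionary
    predictions against observed mutant spectra. Synthetic-data generators
    provide every input needed for fully offline testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
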