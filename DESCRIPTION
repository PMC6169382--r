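Package: capensim
Title: Simulation and Classification of Thelytokous and Polyploid
    Reproduction in Honey Bees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward simulator of honey bee (Apis mellifera) meiosis and
    egg formation covering arrhenotoky, fertilization, central-fusion
    thelytoky, fertilized thelytokous fusion nuclei, polyspermic and
    mosaic eggs, androgenesis, and the meiosis of a triploid queen,
    together with the inference tools used to interpret such crosses:
    microsatellite-based ploidy, fertilization and origin classification,
    csd-based sex determination and viability filtering, synthetic
    DAPI flow-cytometry histograms with C1-C4 peak calling, and the
    contingency and proportion summaries used to report cross outcomes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
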