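Package: asfscreen
Title: Aqueous Stability Factor Screening of Iron-Natural Product Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Screens candidate octahedral iron(II/III) coordination shells over
    the oxygen and nitrogen donor atoms of large natural products and ranks the
    resulting complexes by the aqueous stability factor (ASF), a descriptor-based
    score combining complex energy, average metal-ligand bond length, dipole
    moment, and charge. Provides covalency filters on bond lengths, a
    dipole-to-volume polarity ladder calibrated against common solvents,
    trendline fitting for descriptor-score relations, a rank-paired log-log
    correlation against growth-inhibition (GI50) activity data, and a seeded
    synthetic descriptor generator standing in for semi-empirical quantum
    chemistry outputs. Packaged reference tables of previously computed
    discodermolide, kahalalide F, and halichondrin B iron complexes support
    exact replication tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineR,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
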