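Package: ffatrace
Title: Stable-Isotope Tracing Analysis of Free Fatty Acid Biosynthesis and
    Inter-Tissue Crosstalk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for in vivo 13C stable-isotope tracing of free
    fatty acid (FFA) metabolism: natural-abundance correction of isotopologue
    intensities, mass isotopologue distributions (MIDs), labeling extents and
    13C enrichments, quasi-multinomial fitting of de novo synthesis fractions
    g(t) with pool-size-corrected pseudo biosynthesis rates, MID similarity
    scoring and donor-tissue screening against serum, constrained
    deconvolution of synthesis versus serum uptake for palmitate and
    stearate, Monte Carlo permutation tests on MIDs, and a ground-truth
    synthetic-data generator emulating a multi-tissue mouse tracing study.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.2)
Imports:
    dplyr,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
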