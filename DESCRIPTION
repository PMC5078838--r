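Package: popgenscan
Title: Domestication Selection Scans from Population Resequencing Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native toolkit for scanning candidate gene sets for
    signatures of selection across a domestication contrast between an
    ancestral (wild) and a descendant (landrace) population. Implements
    per-gene and per-site nucleotide diversity (theta-pi), Watterson's
    theta, Tajima's D and Hudson's F_ST with pairwise deletion of missing
    data; pairwise Ka/Ks estimation by the NG86 pathway-counting method and
    an approximate MYN-style method with separate purine and pyrimidine
    transition rates; empirical-quantile classification of purifying and
    balancing selection at gene and base-pair level with selective-sweep
    delimitation and codon-effect annotation; classic HKA and a
    likelihood-ratio (mlHKA-style) polymorphism/divergence test; and
    minimum-spanning haplotype networks stratified by sample metadata. A
    forward Wright-Fisher simulator generates two-population bottleneck
    datasets with known selection regimes so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
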