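Package: kinclique
Title: Kin-Structured Social Network Analysis for Bachelor Male Bands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing male social structure in multilevel primate
    societies from behavioural event tables, microsatellite genotypes and GPS
    tracks. Builds half-weight index (HWI) association and directional
    affiliation index (DAI) grooming networks, clusters bachelor males into
    all-male units, fits David's score dominance hierarchies with linearity
    and steepness statistics, estimates pairwise Lynch-Ritland relatedness
    with expectation-maximization null-allele correction, tracks overlapping
    k-clique-percolation communities through time against inter-band
    distance, and attributes dyadic affiliation to kinship, age and rank with
    a higher-order partial Mantel test (HPMT) reporting permutation P values
    and per-factor contribution rates. A seeded synthetic-herd generator with
    known pedigree, behavioural effect sizes and trajectories supports
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ape,
    testthat (>= 3.0.0),
    vegan,
    withr,
    yaml
Config/testthat/edition: 3
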