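Package: clockspacer
Title: Euclidean Clock Spaces and Pacemaker Tests for Phylogenomic Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Places per-branch evolutionary rates from phylogenomic gene trees
    into a Euclidean "clock space" by concordance-based collection of branch
    rates against a species tree followed by principal components analysis.
    Provides permutation tests of pacemaker hypotheses of genome-wide rate
    variation (eigenvalue-dispersion statistics phi and psi, per-component
    significance, and per-branch loading significance), a scale-minimised
    branch-score distance with classical multidimensional scaling, k-medoids
    clustering with gap-statistic selection of the number of rate clusters,
    and a simulation engine (birth-death species trees, multispecies-coalescent
    gene trees, white-noise clocks with locus clusters and branch
    accelerations) for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
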