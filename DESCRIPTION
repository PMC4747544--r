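Package: rhomap
Title: Fine-Scale Population Recombination Rate Maps and Hotspot Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian inference of fine-scale population-scaled recombination
    rate maps (rho = 4*Ne*c) from SNP genotypes of unrelated individuals.
    Implements a coalescent-with-recombination simulator for background-plus-
    hotspot rate maps, a Monte-Carlo two-locus composite likelihood engine,
    reversible-jump MCMC over a background rate with Poisson-process hotspots,
    Bayes-factor classification of 200-bp bins against a prior-only chain,
    hotspot calling as runs of consecutive high-Bayes-factor bins, and GC
    content and repeat-element annotation of hotspot versus neutral bins.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    IRanges,
    Biostrings,
    vcfR,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    optparse
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
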