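Package: tumormix
Title: Tumor Purity and Subclonal Copy Number Inference from Read Depth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers the composition of a bulk tumor sample -- the fraction of
    admixed normal cells and the integer copy numbers of one or two tumor
    subpopulations -- directly from tumor and matched-normal read counts over a
    segmented genome. The sample is modelled as a mixture of genomes whose
    observed read depth vector follows a multinomial distribution; the
    maximum-likelihood interval count matrix and genome mixing vector are found
    by enumerating candidate integer matrices restricted by an ordering
    constraint and solving a convex subproblem for each. Includes
    gamma-modified BIC model selection over the number of subpopulations, a
    simulation generator for benchmark mixtures, and evaluation utilities.
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
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
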