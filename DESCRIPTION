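Package: coalcodon
Title: Joint Estimation of Recombination, Substitution and dN/dS Rates
    from Coding Sequences by Approximate Bayesian Computation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates protein-coding alignments under a neutral
    constant-size coalescent with recombination (including intracodon
    breakpoints) and the Goldman-Yang (GY94) codon substitution model with
    among-site rate variation and invariable sites; summarises alignments
    with a 26-statistic vector combining three recombination tests (PHI,
    NSS, MaxChi), moments of diversity and heterozygosity at the codon and
    amino-acid levels, segregating-site counts and joint codon/amino-acid
    measures; and jointly estimates the population-scaled recombination
    rate rho = 4Nrl, the scaled codon substitution rate theta = 4NmuL and
    the nonsynonymous/synonymous rate ratio omega by approximate Bayesian
    computation, with rejection sampling and Epanechnikov-weighted
    local-linear regression adjustment on optionally log- or
    logit-transformed parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ape,
    Biostrings,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    withr
Config/testthat/edition: 3
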