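Package: coalrate
Title: Speciation-Time Calibration of Phylogenetic Mutation Rates under
    the Multispecies Coalescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to estimate a phylogenetic mutation rate for the great
    apes that is directly comparable to human pedigree (de novo) rates.
    Simulates multi-locus four-taxon alignments under the multispecies
    coalescent, filters loci with a molecular-clock likelihood ratio test,
    computes maximum-likelihood genetic distances (per locus and on a
    concatenated supermatrix), infers the Homo-Pan speciation time tau and
    the ancestral population-mutation parameter theta by Markov chain Monte
    Carlo, and converts tau into yearly and per-generation mutation rates
    over grids of fossil calibration ages and ancestral generation times.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
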