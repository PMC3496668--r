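Package: recmapsel
Title: Fine-Scale Recombination Maps and the Footprint of Linked Selection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Builds fine-scale crossover maps from backcross genotype data
    (double-crossover error filtering, Kosambi centiMorgans per megabase,
    permutation and binomial confidence bounds), compares maps between
    crosses or species with bias-corrected rare-events logistic regression
    and classifies intervals as conserved or divergent, computes nucleotide
    diversity and divergence at 4-fold degenerate sites of unpreferred
    codons together with interval covariates, assembles substitution-centred
    window tables for selective-sweep trough analysis, and fits the
    associated quasibinomial GLMs and Poisson mixed models. A synthetic-data
    generator with known ground truth and a Wright-Fisher simulator for
    fixation probabilities and conditional fixation times support end-to-end
    recovery tests of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
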