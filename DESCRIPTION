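Package: polyphase
Title: Multipoint Linkage Analysis and Haplotype Phasing in Autopolyploid
    Full-Sib Populations
Version: 0.1.0
Authors@R:
    person("polyphase", "developers", email = "polyphase@example.org",
           role = c("aut", "cre"))
Description: Hidden Markov model machinery for genetic linkage analysis in
    full-sib (F1) families of autopolyploids of any even ploidy level.
    Models bivalent pairing and polysomic inheritance, estimates multipoint
    recombination fractions by forward-backward EM over the full genotype
    state space, and reconstructs parental haplotypes (linkage phases) with
    an efficient two-point search-space reduction based on allele-sharing
    partitions and homolog-permutation redundancy elimination.  Includes a
    meiosis simulator for bivalent pairing with optional preferential
    pairing, SNP dosage data input/output with polysomic segregation
    checks, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
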