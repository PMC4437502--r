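Package: mlstpop
Title: Multilocus Sequence Typing and Bacterial Population Structure
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multilocus sequence typing (MLST) of haploid bacterial
    populations: allele and sequence-type (ST) assignment from per-locus
    nucleotide alignments, per-locus diversity statistics (polymorphic sites,
    GC content, nucleotide diversity, Nei-Gojobori dN/dS), linkage
    disequilibrium via the standardized index of association with a
    permutation test, eBURST-style clonal-complex detection with founder
    prediction, minimum spanning trees over allelic profiles, neighbour-joining
    phylogenies with bootstrap support, Bandelt-Dress split decomposition
    networks, and a Wright-Fisher forward simulator of clonal populations with
    tunable mutation and recombination for validation.
License: MIT
Encoding: UTF-8
Imports:
    ape,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    phangorn,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
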