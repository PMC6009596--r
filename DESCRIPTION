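Package: tetrascaf
Title: Assembly Curation and Pseudomolecule Construction for Allotetraploid Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for curating and scaffolding draft assemblies of
    allotetraploid genomes. Implements in-silico nickase digestion and
    restriction-map alignment against optical genome maps, chimeric-junction
    scoring and evidence-based breaking of misassembled sequences, mate-pair
    scaffolding with insert-size validation, hierarchical Hi-C clustering,
    ordering and orientation of scaffolds into pseudomolecules, diagnostic
    k-mer partitioning of sequences into ancestral subgenomes, and assembly
    contiguity and anchoring reports. Ships a seeded simulator for a toy
    allotetraploid truth set (diverged ancestors, fragmented draft with
    planted chimeric joins, optical molecules, mate pairs, long-read
    alignments and Hi-C contacts) so the whole pipeline is testable end to
    end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
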