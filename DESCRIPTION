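Package: olca
Title: Overlap-Layout-Consensus Assembly of Noisy Long Reads at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A small-scale overlap-layout-consensus assembler for noisy
    single-molecule long reads. Implements read database set-up with
    longest-subread-per-ZMW selection, three-tier repeat masking
    (low-complexity, tandem, and coverage-based interspersed repeats),
    k-mer-seeded banded local alignment with alignment chaining, read
    patching with chimera, missed-adapter, strand-jump and low-quality
    artefact correction (including a spanning-chain rule for chimeric
    junctions hidden in repeats), string-graph construction with
    transitive reduction and touring to primary contigs, column-majority
    consensus polishing, and a reference-baited circular mitogenome mode
    with overlap-aware read splitting and self-map circularization. A
    companion read simulator generates genomes with planted repeat
    families and reads with injected artefacts carrying machine-readable
    ground truth, so every stage is testable without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
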