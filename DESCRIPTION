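Package: foldscan
Title: Sliding-Window Thermodynamic Scanning and Weighted Consensus
    Structure Motifs for mRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers locally folded, potentially functional secondary
    structure motifs in mRNAs. A fixed window slides along the transcript and
    each window is folded with a bundled nearest-neighbor thermodynamic engine
    (minimum free energy and McCaskill partition-function metrics); a
    mononucleotide-shuffle null converts the native folding energy into a
    thermodynamic z-score. Per-window structures are combined into
    z-score-weighted consensus base-pair calls, filtered at average-z cutoffs,
    filled in by constrained refolding and grouped into motifs. Companion
    stages classify structural conservation (consistent/compensatory
    mutations) against a multiple sequence alignment, score miRNA target-site
    accessibility as ddG = dG(duplex) - dG(open), and analyse dual-luciferase
    translational-efficiency assays. Seeded synthetic-data generators make
    every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    data.table,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
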