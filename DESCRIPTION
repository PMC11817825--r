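Package: aptamin
Title: Aptamer Minimization by DNA Folding and Constrained Inverse Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for in-silico minimization of single-stranded DNA
    aptamers. Folds DNA with a nearest-neighbor thermodynamic model
    (Zuker-style minimum-free-energy dynamic programming, bundled DNA
    Mathews-2004 parameters), truncates a parent aptamer under a
    sliding-window scan while preserving a designated multiloop
    recognition motif, redesigns the minimized scaffold by repeated
    seeded constrained inverse folding, restores functional loop
    sequences, builds junction composition variants, and screens
    candidates for canonical G-quadruplex motifs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
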