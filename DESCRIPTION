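Package: oligostore
Title: Error-Corrected DNA Data Storage for High-Error Photolithographic
    Synthesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Store arbitrary binary files in pools of short (60 nt),
    primer-free synthetic oligonucleotides and recover them from very noisy
    sequencing reads. Implements a concatenated Reed-Solomon code (a long
    outer code over GF(2^14) across sequences and a short inner code over
    GF(2^6) within each sequence) with errors-and-erasures decoding, payload
    pseudo-randomization, and a mid-sequence 24-bit index. Includes a
    Monte-Carlo channel simulator for the insertion/deletion/substitution
    error structure of light-directed array synthesis (Poisson error counts,
    3' T linker, C-rich library-preparation tail, fixed sequencing window,
    overdispersed per-oligo coverage), read clustering by 16-nt prefix or by
    MinHash locality-sensitive hashing, center-star multiple alignment with
    weighted-majority consensus calling, a full reconstruction pipeline with
    stagewise reporting, and per-position read-profiling analytics (error
    rates, base composition, length and GC summaries).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    withr,
    Biostrings,
    stats,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
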