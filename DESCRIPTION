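Package: paleosrna
Title: Small RNA Profiling and Degradation Analysis for Ancient Plant Tissues
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of small-RNA sequencing libraries from degraded,
    deaminated archaeological plant material alongside modern controls.
    Provides adapter trimming and 18-25 nt size parsing, deamination-aware
    read matching (a single C-to-T mismatch in the frame of the originating
    strand), molecular-class composition and miRNA-family expression
    profiling, depth normalization across libraries, extended-Poisson
    likelihood kernels for differential miRNA assessment, a simplified
    Phylogenetic Intersect Analysis for endogenous-content estimation,
    retroelement activity proportions, RNA half-life estimation from
    per-seed mass, and GC-content survival analysis. A synthetic-data
    generator emulates the statistical structure of degraded archaeological
    libraries so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    Biostrings,
    ape,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
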