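Package: loopmapr
Title: Strand-Specific Nick Mapping and Sanger Trace Decomposition for
    Repeat-Loop Substrates
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstituted-biochemistry studies of trinucleotide
    repeat instability on circular heteroduplex plasmids carrying an
    extrahelical loop. Builds looped substrates and their expansion and
    contraction products; simulates 3'-OH-capture (GLOE-seq-style)
    single-end reads from planted per-strand nick profiles; maps reads
    against a triply concatenated circular reference to call
    strand-specific cut positions at single-nucleotide resolution, with a
    loop-aware rescue pass for reads spanning the loop; and quantifies
    repeat expansion and contraction from Sanger chromatograms by
    decomposing mutant traces into simulated indel references with
    non-negative least squares and covariance-derived t statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    data.table,
    ggplot2,
    jsonlite,
    pracma,
    stats,
    tools,
    utils,
    grDevices,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
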