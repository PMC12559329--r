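#!/usr/bin/env Rscript
# Run both bundled end-to-end scenarios (substrate -> nick profile ->
# reads -> cut map -> trace mixture -> decomposition) and write complete
# report bundles, each with a machine-readable run summary and file
# checksums, under results/demo/.

suppressMessages(library(loopmapr))

run_expansion_demo("results/demo/expansion", list(seed = 1L))
run_contraction_demo("results/demo/contraction", list(seed = 1L))
message("wrote results/demo/{expansion,contraction}")
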