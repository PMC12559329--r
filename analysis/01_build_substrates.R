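#!/usr/bin/env Rscript
# Build the study's two heteroduplex substrates: a 3.2 kb circular
# plasmid with a 12-nt (CAG)4 extrahelical loop in the top strand, and
# the (T)4 variant. Writes FASTA, substrate JSON and the predicted
# expansion/contraction product sequences under results/substrates/.

suppressMessages(library(loopmapr))
out <- "results/substrates"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

plasmid <- generate_plasmid(3200L, 0.5, seed = 7L, name = "pSyn")
write_plasmid(plasmid, file.path(out, "pSyn.fasta"))

cag4 <- make_heteroduplex(plasmid, loop_spec("top", 1600L, "CAGCAGCAGCAG"))
t4 <- make_heteroduplex(plasmid, loop_spec("top", 1600L, "TTTT"))
write_substrate(cag4, file.path(out, "pSyn_CAG4.json"))
write_substrate(t4, file.path(out, "pSyn_T4.json"))

exp_prod <- expansion_product(cag4)
con_prod <- contraction_product(cag4)
writeLines(c(">pSyn_CAG4_expansion_opposite_strand", exp_prod$opposite_strand,
             ">pSyn_CAG4_contraction_looped_strand", con_prod$looped_strand),
           file.path(out, "pSyn_CAG4_products.fasta"))

message(sprintf("substrate: %d nt plasmid; looped strand %d nt (loop %d..%d)",
                plasmid$length_nt, nchar(cag4$looped_strand_seq),
                cag4$loop5_boundary, cag4$loop3_boundary))
message(sprintf("expansion writes %s opposite the loop; contraction returns both strands to %d nt",
                substr(exp_prod$opposite_strand, 3200 - 1600 + 1,
                       3200 - 1600 + 12),
                nchar(con_prod$looped_strand)))
message("wrote ", out)
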