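#!/usr/bin/env Rscript
# Simulate 3'-OH-capture read sets for the two incision scenarios on the
# (CAG)4 substrate: loop-recognition nicking of the strand opposite the
# loop (decaying peaks 5' of the loop) and FAN1-like nicking of the
# looped strand one nucleotide 3' of the loop. Writes FASTQ plus the
# ground-truth nick table under results/reads/.

suppressMessages(library(loopmapr))
out <- "results/reads"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sub <- read_substrate("results/substrates/pSyn_CAG4.json")

for (scn in c("mutl_opposite_5prime", "fan1_loop3prime")) {
  prof <- preset_profile(scn, sub)
  rs <- simulate_reads(prof, n_reads = 50000L, read_length = 75L,
                       error_rate = 0, seed = 42L)
  tag <- if (scn == "fan1_loop3prime") "fan1" else "mutl"
  write_fastq(rs, file.path(out, paste0(tag, ".fastq")))
  write_truth(rs, file.path(out, paste0(tag, "_truth.tsv")))
  by_strand <- table(rs$truth$strand)
  message(sprintf("%s: %d reads (nicks: %s)", tag, nrow(rs$reads),
                  paste(names(by_strand), by_strand, collapse = ", ")))
}
message("wrote ", out)
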