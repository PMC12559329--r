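# Shared fixtures and independent oracles. Everything is generated in
# code; no stored data.

std_substrate <- function(n = 3200L, seed = 7L, loop = "CAGCAGCAGCAG",
                          insertion_point = n %/% 2L, carrier = "top") {
  p <- generate_plasmid(n, 0.5, seed = seed)
  suppressWarnings(
    make_heteroduplex(p, loop_spec(carrier, insertion_point, loop)))
}

# Ten-peak planted nick profile spread over both strands, avoiding the
# loop interior; peak set is deterministic.
ten_peak_profile <- function(substrate) {
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  i <- substrate$loop$insertion_point
  top <- numeric(n + l)
  bottom <- numeric(n)
  bpos <- round(n * c(0.05, 0.18, 0.33, 0.47, 0.62, 0.81))
  bw <- c(5, 3, 8, 2, 6, 4)
  bottom[bpos + 1L] <- bw
  tpos_lm <- c((i - 200L) %% (n + l), (i + l + 37L) %% (n + l),
               round(0.9 * n), 3L)
  tw <- c(4, 7, 2, 5)
  top[tpos_lm + 1L] <- tw
  nick_profile(substrate, top, bottom)
}

# Empirical vs expected total-variation distance over (strand, position)
truth_tv <- function(truth, profile) {
  sub <- profile$substrate
  lab <- loopmapr:::strand_labels(sub)
  ic <- loopmapr:::carrier_intensity(profile)
  io <- loopmapr:::opposite_intensity(profile)
  expected <- c(ic, io) / (sum(ic) + sum(io))
  n_c <- length(ic)
  idx <- ifelse(truth$strand == lab$carrier,
                truth$nick_position + 1L,
                n_c + truth$nick_position + 1L)
  emp <- tabulate(idx, nbins = n_c + length(io)) / nrow(truth)
  sum(abs(emp - expected)) / 2
}

# TV distance between an inferred cut profile and the truth table, over
# (strand, plasmid position); loop-internal truth rows are excluded on
# both sides.
cut_tv <- function(cuts, truth) {
  n <- cuts$substrate$plasmid$length_nt
  emp_t <- tabulate(truth$plasmid_position[truth$strand == "top"] + 1L, n)
  emp_b <- tabulate(truth$plasmid_position[truth$strand == "bottom"] + 1L, n)
  emp <- c(emp_t, emp_b) / nrow(truth)
  placed <- sum(cuts$counts_top) + sum(cuts$counts_bottom)
  inf <- c(cuts$counts_top, cuts$counts_bottom) / placed
  sum(abs(emp - inf)) / 2
}

# Brute-force exhaustive aligner over all 2 x (3N - len + 1) ungapped
# offsets of the concatenated reference; independent of the k-mer path.
oracle_align <- function(read, ref, max_mm = 2L) {
  len <- nchar(read)
  r3 <- nchar(ref)
  ref_raw <- charToRaw(ref)
  hits <- list()
  for (strand in c("top", "bottom")) {
    rr <- charToRaw(if (strand == "top") read else
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(read))))
    for (s in 0:(r3 - len)) {
      mm <- sum(ref_raw[(s + 1):(s + len)] != rr)
      if (mm <= max_mm)
        hits[[length(hits) + 1L]] <- data.frame(strand = strand, start = s,
                                                mm = mm)
    }
  }
  if (length(hits) == 0) return(NULL)
  do.call(rbind, hits)
}

# Per-read identity of inferred cuts against the simulation truth.
roundtrip_identity <- function(cuts, truth) {
  m <- merge(truth, cuts$per_read, by = "read_id")
  m <- m[is.na(m$loop_offset), , drop = FALSE]
  mean(m$strand.x == m$strand.y & m$plasmid_position == m$position)
}
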