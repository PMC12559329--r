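test_that("build_reference concatenates both strands exactly three times", {
  sub <- std_substrate(3200, seed = 7)
  b <- build_reference(sub)
  expect_equal(nchar(b$duplex_ref), 9600)
  expect_equal(nchar(b$loop_ref), 3 * 3212)
  expect_identical(b$duplex_ref, strrep(sub$plasmid$sequence, 3))
  expect_identical(b$loop_ref, strrep(sub$looped_strand_seq, 3))

  none <- std_substrate(400, seed = 7, loop = "", insertion_point = 100)
  b0 <- build_reference(none)
  expect_identical(b0$loop_ref, b0$duplex_ref)
})

test_that("the aligner recovers planted substrings on both strands", {
  sub <- std_substrate(600, seed = 11, insertion_point = 300)
  b <- build_reference(sub)
  n <- 600
  fwd <- substr(sub$plasmid$sequence, 101, 175)            # plain top
  rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substr(sub$plasmid$sequence, 401, 475))))
  origin <- circ_substr(sub$plasmid$sequence, n - 30, 75)  # spans the origin
  reads <- data.frame(id = c("fwd", "rev", "ori"),
                      seq = c(fwd, rev, origin))
  aln <- align_reads(reads, b)
  expect_equal(aln$status, rep("unique", 3))
  expect_equal(aln$ref_strand, c("top", "bottom", "top"))
  # middle-copy representatives
  expect_equal(aln$start, c(100 + n, 400 + n, (n - 30) + n))
  expect_equal(aln$mismatches, c(0L, 0L, 0L))

  # brute-force oracle agreement for the origin-spanning read (it cannot
  # map within a single copy)
  oracle <- oracle_align(origin, b$duplex_ref, 0)
  expect_true(all(oracle$start %% n == (n - 30)))
  # a 75-nt window starting in the third copy would run off the 3N end,
  # so exactly two concatenation representatives exist
  expect_setequal(oracle$start, c(n - 30, 2 * n - 30))
})

test_that("mismatched, ambiguous and unmappable reads are classified", {
  sub <- std_substrate(600, seed = 12, insertion_point = 300)
  b <- build_reference(sub)
  base <- substr(sub$plasmid$sequence, 201, 275)
  two_mm <- base
  substr(two_mm, 5, 5) <- if (substr(base, 5, 5) == "A") "C" else "A"
  substr(two_mm, 70, 70) <- if (substr(base, 70, 70) == "G") "T" else "G"
  three_mm <- two_mm
  substr(three_mm, 40, 40) <- if (substr(two_mm, 40, 40) == "A") "C" else "A"
  random <- strrep("ACGT", 19)  # periodic, will multimap or unmap
  reads <- data.frame(id = c("ok", "two", "three"),
                      seq = c(base, two_mm, three_mm))
  aln <- align_reads(reads, b, list(max_mismatches = 2))
  expect_equal(aln$status[1:2], c("unique", "unique"))
  expect_equal(aln$mismatches[1:2], c(0L, 2L))
  expect_equal(aln$status[3], "unmapped")
  expect_true(is.na(aln$start[3]))

  # a read planted at two distinct loci is ambiguous
  dup_plasmid <- paste0(base, substr(sub$plasmid$sequence, 276, 500),
                        base, substr(sub$plasmid$sequence, 276, 350))
  p2 <- suppressWarnings(make_heteroduplex(
    loopmapr:::new_circular_plasmid("dup", dup_plasmid),
    loop_spec("top", 10, "")))
  b2 <- build_reference(p2)
  aln2 <- align_reads(data.frame(id = "amb", seq = base), b2)
  expect_equal(aln2$status, "ambiguous")
  expect_true(is.na(aln2$start))

  expect_error(align_reads(data.frame(id = "x", seq = "ACGT-ACGT"), b),
               class = "loopmapr_format_error")
})

test_that("cuts land on the strand opposite the read, adjacent to the 5' end", {
  sub <- std_substrate(800, seed = 13, insertion_point = 400)
  # single planted nick on the bottom strand: reads map to top, cuts
  # must come back on bottom at the planted position
  bottom <- numeric(800); bottom[101] <- 1   # position 100
  prof <- nick_profile(sub, numeric(812), bottom)
  rs <- simulate_reads(prof, 1000, 75, 0, seed = 21)
  cuts <- map_nicks(sub, rs)
  expect_equal(sum(cuts$counts_bottom), 1000)
  expect_equal(cuts$counts_bottom[101], 1000L)
  expect_equal(sum(cuts$counts_top), 0)
  aln <- align_reads(rs$reads, build_reference(sub))
  expect_true(all(aln$ref_strand == "top"))

  # and the mirror case: nick on the looped (top) strand
  top <- numeric(812); top[(sub$loop3_boundary + 1L) + 1L] <- 1
  rs2 <- simulate_reads(nick_profile(sub, top, numeric(800)), 500, 75, 0,
                        seed = 22)
  cuts2 <- map_nicks(sub, rs2)
  expect_equal(sum(cuts2$counts_top), 500)
  expect_equal(which.max(cuts2$counts_top) - 1L, 400L)  # plasmid coord of loop3'+1
  aln2 <- align_reads(rs2$reads, build_reference(sub))
  expect_true(all(aln2$ref_strand == "bottom"))
})

test_that("loop-spanning reads are rescued at their true positions", {
  sub <- std_substrate(1000, seed = 14, insertion_point = 500)
  bottom <- numeric(1000)
  bottom[(500 - 40):(500 - 10) + 1L] <- 1  # reads traverse the loop
  prof <- nick_profile(sub, numeric(1012), bottom)
  rs <- simulate_reads(prof, 400, 75, 0, seed = 23)
  b <- build_reference(sub)
  primary_aln <- align_reads(rs$reads, b)
  expect_gt(sum(primary_aln$status == "unmapped"), 0)

  cuts <- map_nicks(sub, rs)
  expect_gt(cuts$totals$n_rescued, 0)
  expect_equal(cuts$totals$n_unmapped_final, 0)
  expect_equal(roundtrip_identity(cuts, rs$truth), 1)

  # rescue adds nothing for an empty pool or a loop-free substrate
  empty <- rescue_loop_reads(rs$reads[0, ], sub)
  expect_equal(nrow(empty$calls), 0)
  none <- std_substrate(600, seed = 14, loop = "", insertion_point = 100)
  prof0 <- nick_profile(none, numeric(600), c(1, numeric(599)))
  rs0 <- simulate_reads(prof0, 50, 60, 0, seed = 24)
  cuts0 <- map_nicks(none, rs0)
  expect_equal(cuts0$totals$n_rescued, 0)
  expect_equal(cuts0$totals$n_unique_primary, 50)
})

test_that("read-count conservation holds and finalize catches violations", {
  sub <- std_substrate(900, seed = 15, insertion_point = 450)
  prof <- preset_profile("mutl_opposite_5prime", sub,
                         list(background = 0.2))
  for (s in c(31, 32)) {
    rs <- simulate_reads(prof, 500, 75, 0.01, seed = s)
    cuts <- map_nicks(sub, rs)
    t <- cuts$totals
    expect_identical(t$n_input, t$n_unique_primary + t$n_rescued +
                       t$n_ambiguous + t$n_unmapped_final)
    expect_identical(sum(cuts$counts_top) + sum(cuts$counts_bottom) +
                       sum(cuts$loop_local_counts),
                     t$n_unique_primary + t$n_rescued)
  }
  rs <- simulate_reads(prof, 100, 75, 0, seed = 33)
  aln <- align_reads(rs$reads, build_reference(sub))
  primary <- call_cuts(aln, sub)
  rescue <- rescue_loop_reads(rs$reads[0, ], sub)
  expect_error(finalize_profile(primary, rescue, sub, n_input = 10),
               class = "loopmapr_internal_inconsistency")
})

test_that("zero mapped reads produce a clean all-zero profile", {
  sub <- std_substrate(300, seed = 16, insertion_point = 150)
  junk <- data.frame(id = "j1", seq = strrep("A", 75),
                     qual = strrep("I", 75))
  cuts <- map_nicks(sub, junk)
  expect_equal(sum(cuts$counts_top) + sum(cuts$counts_bottom), 0)
  expect_true(all(cuts$cpm_top == 0))
  expect_equal(cuts$totals$n_unmapped_final +
                 cuts$totals$n_ambiguous, 1L)
})

test_that("rotating the plasmid origin rotates the cut profile", {
  n <- 800; k <- 137
  p <- generate_plasmid(n, 0.5, seed = 17)
  rot_seq <- circ_substr(p$sequence, k, n)
  sub <- suppressWarnings(make_heteroduplex(
    p, loop_spec("top", 400, "CAGCAGCAGCAG")))
  sub_rot <- suppressWarnings(make_heteroduplex(
    loopmapr:::new_circular_plasmid("rot", rot_seq),
    loop_spec("top", 400 - k, "CAGCAGCAGCAG")))
  prof <- ten_peak_profile(sub)
  rs <- simulate_reads(prof, 1500, 75, 0, seed = 25)
  cuts <- map_nicks(sub, rs)
  # identical molecules, rotated frame: feed the same reads to the
  # rotated substrate
  cuts_rot <- map_nicks(sub_rot, rs$reads)
  roll <- function(x, k) c(x[(k + 1):length(x)], x[seq_len(k)])
  expect_equal(cuts_rot$counts_top, roll(cuts$counts_top, k))
  expect_equal(cuts_rot$counts_bottom, roll(cuts$counts_bottom, k))
})

test_that("swapping the nicked strands swaps the called profile", {
  n <- 700
  p <- generate_plasmid(n, 0.5, seed = 18)
  sub <- suppressWarnings(make_heteroduplex(
    p, loop_spec("top", 350, "TTTT")))
  top <- numeric(n + 4); top[(100) + 1L] <- 2; top[(600 + 4) + 1L] <- 1
  bottom <- numeric(n); bottom[201] <- 3
  prof <- nick_profile(sub, top, bottom)
  rs <- simulate_reads(prof, 800, 60, 0, seed = 26)
  cuts <- map_nicks(sub, rs)

  # mirror substrate: the same physical picture with strand labels
  # exchanged (loop on the bottom strand of the reverse-complement
  # plasmid at the mirrored coordinate)
  p_rc <- loopmapr:::new_circular_plasmid("mirror", revcomp(p$sequence))
  sub_m <- suppressWarnings(make_heteroduplex(
    p_rc, loop_spec("bottom", 350, "TTTT")))
  expect_identical(sub_m$looped_strand_seq, sub$looped_strand_seq)
  cuts_m <- map_nicks(sub_m, rs$reads)
  # plasmid coordinate x in `sub` corresponds to n-1-x in the mirror
  expect_equal(cuts_m$counts_bottom, rev(cuts$counts_top))
  expect_equal(cuts_m$counts_top, rev(cuts$counts_bottom))
})

test_that("all-copies mode agrees with middle-copy mode on clean reads", {
  sub <- std_substrate(600, seed = 19, insertion_point = 300)
  prof <- preset_profile("mutl_opposite_5prime", sub)
  rs <- simulate_reads(prof, 400, 75, 0, seed = 27)
  a <- map_nicks(sub, rs, copies = "middle")
  b <- map_nicks(sub, rs, copies = "all")
  expect_equal(a$counts_top, b$counts_top)
  expect_equal(a$counts_bottom, b$counts_bottom)
})

test_that("the loopless rescue reference also recovers loop-spanning reads", {
  sub <- std_substrate(1000, seed = 20, insertion_point = 500)
  bottom <- numeric(1000); bottom[(500 - 30):(500 - 20) + 1L] <- 1
  prof <- nick_profile(sub, numeric(1012), bottom)
  rs <- simulate_reads(prof, 100, 75, 0, seed = 28)
  cuts <- map_nicks(sub, rs, rescue_reference = "loopless")
  # under the loopless reading the loop bases are absent from the
  # second-pass reference, so loop-spanning reads carry the loop as
  # mismatches/insertions and only reads with small loop overlap return;
  # the mode must still run cleanly and keep conservation
  t <- cuts$totals
  expect_identical(t$n_input, t$n_unique_primary + t$n_rescued +
                     t$n_ambiguous + t$n_unmapped_final)
})

test_that("exported profiles round-trip and exports are complete", {
  sub <- std_substrate(400, seed = 21, insertion_point = 200)
  prof <- preset_profile("fan1_loop3prime", sub)
  rs <- simulate_reads(prof, 300, 75, 0, seed = 29)
  cuts <- map_nicks(sub, rs)
  pre <- file.path(tempdir(), "prof_test")
  files <- export_profile(cuts, pre)
  expect_true(file.exists(files["tsv"]))
  expect_true(file.exists(files["bed"]))
  expect_true(file.exists(files["json"]))

  tsv <- utils::read.table(files[["tsv"]], header = TRUE, sep = "\t")
  expect_equal(nrow(tsv), 2 * 400 + 12)
  back <- read_profile_tsv(files[["tsv"]])
  expect_identical(back$counts_top, cuts$counts_top)
  expect_identical(back$counts_bottom, cuts$counts_bottom)
  expect_identical(back$loop_local_counts, cuts$loop_local_counts)
  expect_equal(back$cpm_top, cuts$cpm_top)

  bed <- utils::read.table(files[["bed"]], sep = "\t")
  expect_equal(sum(bed$V5), cuts$totals$n_unique_primary +
                 cuts$totals$n_rescued - sum(cuts$loop_local_counts))

  p <- plot_cut_profile(cuts)
  expect_s3_class(p, "ggplot")
  # looped and opposite strands are styled as distinct series
  expect_setequal(unique(p$data$series)[order(unique(p$data$series))],
                  c("looped strand", "opposite strand"))
})

test_that("external SAM alignments reproduce internal downstream results", {
  sub <- std_substrate(500, seed = 22, insertion_point = 250)
  prof <- preset_profile("mutl_opposite_5prime", sub)
  rs <- simulate_reads(prof, 150, 75, 0, seed = 30)
  b <- build_reference(sub)
  aln <- align_reads(rs$reads, b)

  # write the internal alignments as a minimal SAM against the 3x ref
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s_3x_duplex\tLN:%d",
                   sub$plasmid$name, nchar(b$duplex_ref)))
  seqs <- setNames(rs$reads$seq, rs$reads$id)
  body <- vapply(seq_len(nrow(aln)), function(j) {
    a <- aln[j, ]
    if (a$status != "unique") {
      sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t*", a$read_id,
              seqs[[a$read_id]])
    } else {
      flag <- if (a$ref_strand == "bottom") 16L else 0L
      s <- seqs[[a$read_id]]
      if (flag == 16L)
        s <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(s)))
      sprintf("%s\t%d\t%s_3x_duplex\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
              a$read_id, flag, sub$plasmid$name, a$start + 1L,
              nchar(s), s)
    }
  }, character(1))
  writeLines(c(hdr, body), sam)

  cuts_int <- map_nicks(sub, rs)
  cuts_sam <- map_nicks(sub, rs$reads, sam = sam)
  expect_equal(cuts_sam$counts_top, cuts_int$counts_top)
  expect_equal(cuts_sam$counts_bottom, cuts_int$counts_bottom)
  expect_equal(cuts_sam$totals$n_input, cuts_int$totals$n_input)
})
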