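#' Circular-reference alignment by k-mer seed and ungapped extension
#'
#' Desk-scale plasmid references need no index structures: the reference
#' strand is duplicated and concatenated three times so that reads
#' spanning the circular origin map contiguously, exact k-mer seeds
#' (taken at several offsets along the read) propose candidate loci on
#' both strands, and ungapped extension counts mismatches. The best
#' alignment by mismatch count wins; best-score ties at distinct loci
#' modulo the circle length are reported as ambiguous, never silently
#' dropped.
#'
#' @name align
NULL

#' Build the triply concatenated reference bundle for a substrate
#'
#' `duplex_ref` is the plasmid top strand repeated exactly three times
#' (length `3N`); `loop_ref` is the looped strand repeated three times
#' (length `3(N + L)`), used by the loop-rescue pass.
#'
#' @param substrate a `heteroduplex`.
#' @return a `reference_bundle` with `duplex_ref`, `loop_ref`, their
#'   circle periods, and the substrate as provenance.
#' @export
build_reference <- function(substrate) {
  stopifnot(inherits(substrate, "heteroduplex"))
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  structure(list(
    duplex_ref = strrep(substrate$plasmid$sequence, 3L),
    loop_ref = strrep(substrate$looped_strand_seq, 3L),
    duplex_period = n,
    loop_period = n + l,
    substrate = substrate), class = "reference_bundle")
}

#' Write the 3x reference FASTA used for external alignment
#'
#' External aligner output (SAM) is interpreted against this exact
#' sequence, giving parity between the internal aligner and an external
#' run.
#'
#' @param bundle a `reference_bundle`.
#' @param path output FASTA path.
#' @param which `"duplex"` or `"loop"`.
#' @export
write_reference_fasta <- function(bundle, path, which = c("duplex", "loop")) {
  which <- match.arg(which)
  seq <- if (which == "duplex") bundle$duplex_ref else bundle$loop_ref
  x <- Biostrings::DNAStringSet(seq)
  names(x) <- paste0(bundle$substrate$plasmid$name, "_3x_", which)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# Count mismatches between a read (raw bytes) and the reference window
# starting at 0-based `start`. Vectorised over nothing; called per
# candidate locus.
mm_count <- function(ref_raw, start, read_raw) {
  sum(ref_raw[(start + 1L):(start + length(read_raw))] != read_raw)
}

#' Align reads to a concatenated circular reference
#'
#' Seeds of length `seed_k` are looked up at offsets `0, k, 2k, ...` and
#' the final `len - k` window, for the read and its reverse complement;
#' every candidate locus is extended without gaps and scored by mismatch
#' count. With this offset set, any alignment with at most two
#' mismatches in a 75-nt read is guaranteed to be proposed by at least
#' one error-free seed window.
#'
#' @param reads data.frame with columns `id`, `seq` (as produced by
#'   [simulate_reads()] or [read_fastq()]).
#' @param bundle a `reference_bundle`.
#' @param params list: `seed_k` (default 20) and `max_mismatches`
#'   (default 2).
#' @param reference `"duplex"` (primary pass) or `"loop"` (rescue pass).
#' @return data.frame of alignment records: `read_id`, `ref_strand`
#'   (`"top"` = the given reference sense), `start` (0-based leftmost
#'   coordinate in the concatenated reference, middle-copy
#'   representative), `mapped_length`, `mismatches`, `status`
#'   (`unique` / `ambiguous` / `unmapped`). Ambiguous and unmapped rows
#'   carry `NA` coordinates.
#' @export
align_reads <- function(reads, bundle, params = list(),
                        reference = c("duplex", "loop")) {
  reference <- match.arg(reference)
  if (inherits(reads, "simulated_reads")) reads <- reads$reads
  if (!is.data.frame(reads) || !all(c("id", "seq") %in% names(reads)))
    abort_format("reads must be a data.frame with columns 'id' and 'seq'")
  k <- as.integer(params$seed_k %||% 20L)
  max_mm <- as.integer(params$max_mismatches %||% 2L)
  ref <- if (reference == "duplex") bundle$duplex_ref else bundle$loop_ref
  period <- if (reference == "duplex") bundle$duplex_period else bundle$loop_period
  r3 <- nchar(ref)

  empty <- data.frame(read_id = character(0), ref_strand = character(0),
                      start = integer(0), mapped_length = integer(0),
                      mismatches = integer(0), status = character(0))
  if (nrow(reads) == 0) return(empty)
  if (any(!grepl("^[ACGTN]+$", reads$seq)))
    abort_format("read sequences contain characters outside A/C/G/T/N")
  lens <- nchar(reads$seq)
  if (any(lens < k))
    abort_invalid(sprintf("seed_k = %d exceeds the shortest read (%d nt)",
                          k, min(lens)))

  # k-mer index of the concatenated reference
  kmer_dt <- data.table::data.table(
    kmer = substring(ref, 1:(r3 - k + 1L), k:r3),
    ref_pos = 0:(r3 - k))

  rc_seq <- revcomp(reads$seq)
  read_raw <- lapply(reads$seq, charToRaw)
  rc_raw <- lapply(rc_seq, charToRaw)
  ref_raw <- charToRaw(ref)

  seed_offsets <- function(len) unique(c(seq(0L, len - k, by = k), len - k))
  off_list <- lapply(lens, seed_offsets)
  n_off <- lengths(off_list)

  seeds <- data.table::data.table(
    read_idx = rep(rep(seq_len(nrow(reads)), n_off), 2L),
    off = rep(unlist(off_list), 2L),
    strand = rep(c("fwd", "rev"), each = sum(n_off)))
  seeds[, kmer := ifelse(strand == "fwd",
                         substring(reads$seq[read_idx], off + 1L, off + k),
                         substring(rc_seq[read_idx], off + 1L, off + k))]

  cand <- merge(seeds, kmer_dt, by = "kmer", allow.cartesian = TRUE)
  results <- empty
  if (nrow(cand) > 0) {
    cand[, start := ref_pos - off]
    cand[, len := lens[read_idx]]
    cand <- cand[start >= 0L & start + len <= r3]
    cand <- unique(cand[, .(read_idx, strand, start, len)])
    cand[, mm := vapply(seq_len(.N), function(j) {
      rr <- if (strand[j] == "fwd") read_raw[[read_idx[j]]] else
        rc_raw[[read_idx[j]]]
      mm_count(ref_raw, start[j], rr)
    }, numeric(1))]
    cand <- cand[mm <= max_mm]
    if (nrow(cand) > 0) {
      cand[, best := mm == min(mm), by = read_idx]
      best <- cand[best == TRUE]
      best[, locus := paste0(strand, ":", start %% period)]
      per_read <- best[, {
        loci <- unique(locus)
        if (length(loci) > 1L) {
          # best-score ties at distinct circular loci: ambiguous
          list(ref_strand = NA_character_, start = NA_integer_,
               mapped_length = NA_integer_, mismatches = NA_integer_,
               status = "ambiguous")
        } else {
          # middle-copy representative of the unique circular locus; the
          # reference is exactly periodic, so this window always exists
          st <- (start[1L] %% period) + period
          list(ref_strand = if (strand[1L] == "fwd") "top" else "bottom",
               start = as.integer(st),
               mapped_length = as.integer(len[1L]),
               mismatches = as.integer(mm[1L]),
               status = "unique")
        }
      }, by = read_idx]
      results <- data.frame(read_id = reads$id[per_read$read_idx],
                            ref_strand = per_read$ref_strand,
                            start = per_read$start,
                            mapped_length = per_read$mapped_length,
                            mismatches = per_read$mismatches,
                            status = per_read$status)
    }
  }
  missing <- setdiff(reads$id, results$read_id)
  if (length(missing) > 0) {
    results <- rbind(results, data.frame(
      read_id = missing, ref_strand = NA_character_, start = NA_integer_,
      mapped_length = NA_integer_, mismatches = NA_integer_,
      status = "unmapped"))
  }
  results[match(reads$id, results$read_id), , drop = FALSE]
}

#' Import external-aligner SAM records as alignment records
#'
#' The SAM must have been produced against the exported 3x reference
#' FASTA (see [write_reference_fasta()]); coordinates are taken as-is
#' and the FLAG strand bit is translated to the package's strand labels.
#' Reads absent from the SAM or flagged unmapped are reported as
#' `unmapped`; secondary/supplementary records are ignored.
#'
#' @param sam_path path to a SAM file.
#' @param bundle a `reference_bundle` (used only for provenance checks).
#' @return alignment records in the same shape as [align_reads()].
#' @export
read_sam_alignments <- function(sam_path, bundle) {
  bam <- Rsamtools::asBam(sam_path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  flags <- Rsamtools::scanBamFlag(isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "pos", "qwidth"),
                               flag = flags)
  rec <- Rsamtools::scanBam(bam, param = p)[[1]]
  unmapped <- bitwAnd(rec$flag, 4L) != 0L
  data.frame(
    read_id = rec$qname,
    ref_strand = ifelse(unmapped, NA_character_,
                        ifelse(bitwAnd(rec$flag, 16L) != 0L, "bottom", "top")),
    start = ifelse(unmapped, NA_integer_, rec$pos - 1L),
    mapped_length = ifelse(unmapped, NA_integer_, rec$qwidth),
    mismatches = NA_integer_,
    status = ifelse(unmapped, "unmapped", "unique"))
}
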