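#' Strand-specific cut calling from circular-reference alignments
#'
#' Reads aligned to the top strand report cuts on the bottom strand, and
#' vice versa: a 3'-OH-capture read is the intact strand opposite the
#' break, so the nick is assigned to the strand opposite the read's
#' mapping strand, at the coordinate base-paired with the read's 5'-most
#' mapped base. Alignments are restricted by default to the middle copy
#' of the triply concatenated reference (window `[N, 2N)`, then shifted
#' by `-N`), which counts each circular locus exactly once and avoids
#' concatenation-edge artifacts; an all-copies-mod-N mode is provided
#' for comparison.
#'
#' @name cutcall
NULL

#' Call cuts from primary-pass (duplex reference) alignments
#'
#' @param alignments alignment records from [align_reads()] (or
#'   [read_sam_alignments()]) against the duplex reference.
#' @param substrate the `heteroduplex` the reference was built from.
#' @param copies `"middle"` keeps alignments starting in `[N, 2N)`;
#'   `"all"` collapses every copy modulo `N`.
#' @return list with `calls` (data.frame `read_id`, `strand`, `position`
#'   in plasmid coordinates), and `leftover` (read ids that did not
#'   yield a unique middle-copy call, with their primary status).
#' @export
call_cuts <- function(alignments, substrate, copies = c("middle", "all")) {
  copies <- match.arg(copies)
  n <- substrate$plasmid$length_nt
  uniq <- alignments[!is.na(alignments$status) &
                       alignments$status == "unique", , drop = FALSE]
  if (copies == "middle") {
    keep <- uniq$start >= n & uniq$start < 2L * n
    dropped <- uniq[!keep, , drop = FALSE]
    uniq <- uniq[keep, , drop = FALSE]
    pos0 <- uniq$start - n
  } else {
    dropped <- uniq[0, , drop = FALSE]
    pos0 <- uniq$start %% n
  }
  # top-strand read: 5'-most base at `pos0`, cut on bottom at pos0;
  # bottom-strand read: 5'-most base at the right end, cut on top there
  cut_pos <- ifelse(uniq$ref_strand == "top",
                    pos0,
                    (pos0 + uniq$mapped_length - 1L) %% n)
  cut_strand <- ifelse(uniq$ref_strand == "top", "bottom", "top")
  calls <- data.frame(read_id = uniq$read_id,
                      strand = as.character(cut_strand),
                      position = as.integer(cut_pos),
                      loop_offset = rep(NA_integer_, nrow(uniq)))
  not_called <- alignments[is.na(alignments$status) |
                             alignments$status != "unique", , drop = FALSE]
  leftover <- rbind(
    data.frame(read_id = not_called$read_id, status = not_called$status),
    data.frame(read_id = dropped$read_id,
               status = rep("unmapped", nrow(dropped))))
  list(calls = calls, leftover = leftover)
}

#' Rescue loop-spanning reads with a second, loop-aware mapping pass
#'
#' Reads that fail the duplex pass (typically because they traverse the
#' extrahelical loop) are aligned against the looped strand of the
#' substrate, concatenated three times. Unique middle-copy hits are
#' converted to cuts with the same geometry convention, in looped-strand
#' coordinates, then projected onto plasmid coordinates; cuts whose
#' coordinate falls inside the loop are segregated into loop-local
#' counts rather than forced onto the duplex frame.
#'
#' @param unmapped_reads data.frame (`id`, `seq`) of reads that were not
#'   uniquely placed in the primary pass.
#' @param substrate a `heteroduplex`.
#' @param params aligner parameters, as in [align_reads()].
#' @param rescue_reference `"looped"` aligns to the full looped strand
#'   (default); `"loopless"` aligns to the carrier strand with the loop
#'   deleted, the alternative reading of a loop-excluding second pass.
#' @return list with `calls` (data.frame `read_id`, `strand`, `position`
#'   in plasmid coordinates, `loop_offset` non-`NA` for loop-internal
#'   cuts) and `leftover` as in [call_cuts()].
#' @export
rescue_loop_reads <- function(unmapped_reads, substrate, params = list(),
                              rescue_reference = c("looped", "loopless")) {
  rescue_reference <- match.arg(rescue_reference)
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  i <- substrate$loop$insertion_point
  lab <- strand_labels(substrate)
  empty_calls <- data.frame(read_id = character(0), strand = character(0),
                            position = integer(0), loop_offset = integer(0))
  if (is.null(unmapped_reads) || nrow(unmapped_reads) == 0)
    return(list(calls = empty_calls,
                leftover = data.frame(read_id = character(0),
                                      status = character(0))))
  bundle <- build_reference(substrate)
  if (rescue_reference == "loopless") {
    bundle$loop_ref <- strrep(substrate$carrier_duplex_seq, 3L)
    bundle$loop_period <- n
  }
  aln <- align_reads(unmapped_reads, bundle, params, reference = "loop")
  period <- bundle$loop_period
  uniq <- aln[aln$status == "unique" & aln$start >= period &
                aln$start < 2L * period, , drop = FALSE]
  calls <- empty_calls
  if (nrow(uniq) > 0) {
    pos0 <- uniq$start - period
    on_looped_sense <- uniq$ref_strand == "top"  # read matches looped strand
    # read on the looped-strand sense: nick on the opposite strand at the
    # read's 5'-most (leftmost) looped coordinate; read on the reverse
    # sense: nick on the looped strand at its 5'-most (rightmost) coord
    cut_coord <- ifelse(on_looped_sense, pos0,
                        (pos0 + uniq$mapped_length - 1L) %% period)
    cut_strand <- ifelse(on_looped_sense, lab$opposite, lab$carrier)
    if (rescue_reference == "loopless") {
      plasmid_pos <- carrier_to_plasmid(substrate, cut_coord)
      calls <- data.frame(read_id = uniq$read_id,
                          strand = as.character(cut_strand),
                          position = as.integer(plasmid_pos),
                          loop_offset = rep(NA_integer_, nrow(uniq)))
    } else {
      in_loop <- l > 0 & cut_coord >= i & cut_coord < i + l
      cd <- ifelse(cut_coord < i, cut_coord, cut_coord - l)
      plasmid_pos <- ifelse(in_loop, NA_integer_,
                            carrier_to_plasmid(substrate, cd))
      calls <- data.frame(read_id = uniq$read_id, strand = cut_strand,
                          position = as.integer(plasmid_pos),
                          loop_offset = ifelse(in_loop,
                                               as.integer(cut_coord - i),
                                               NA_integer_))
    }
  }
  rest <- aln[!aln$read_id %in% calls$read_id, , drop = FALSE]
  list(calls = calls,
       leftover = data.frame(read_id = rest$read_id, status = rest$status))
}

#' Combine primary and rescue calls into a finalized cut profile
#'
#' @param primary result of [call_cuts()].
#' @param rescue result of [rescue_loop_reads()] (may be an empty call
#'   set).
#' @param substrate the `heteroduplex`.
#' @param n_input total number of input reads, for the conservation
#'   identity `n_input == unique + rescued + ambiguous + unmapped`.
#' @return a `cut_profile`: per-position cut counts for both strands in
#'   plasmid coordinates, loop-local counts, CPM normalisation and
#'   bookkeeping totals.
#' @export
finalize_profile <- function(primary, rescue, substrate, n_input) {
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  all_calls <- rbind(primary$calls, rescue$calls)
  counts_top <- counts_bottom <- integer(n)
  loop_local <- integer(l)
  placed <- all_calls[is.na(all_calls$loop_offset), , drop = FALSE]
  tt <- placed[placed$strand == "top", "position"]
  bb <- placed[placed$strand == "bottom", "position"]
  counts_top <- tabulate(tt + 1L, nbins = n)
  counts_bottom <- tabulate(bb + 1L, nbins = n)
  if (l > 0) {
    inloop <- all_calls[!is.na(all_calls$loop_offset), , drop = FALSE]
    loop_local <- tabulate(inloop$loop_offset + 1L, nbins = l)
  }
  # final classification: a read placed in either pass is counted there;
  # an unplaced read is ambiguous if any pass found tied loci for it
  called_ids <- c(primary$calls$read_id, rescue$calls$read_id)
  amb_ids <- union(
    primary$leftover$read_id[primary$leftover$status == "ambiguous"],
    rescue$leftover$read_id[rescue$leftover$status == "ambiguous"])
  n_ambiguous <- length(setdiff(amb_ids, called_ids))
  n_unique_primary <- nrow(primary$calls)
  n_rescued <- nrow(rescue$calls)
  n_unmapped_final <- n_input - n_unique_primary - n_rescued - n_ambiguous
  totals <- list(n_input = n_input,
                 n_unique_primary = n_unique_primary,
                 n_rescued = n_rescued,
                 n_ambiguous = n_ambiguous,
                 n_unmapped_final = n_unmapped_final)
  if (n_unmapped_final < 0 ||
      totals$n_input != n_unique_primary + n_rescued + n_ambiguous +
        n_unmapped_final)
    abort_inconsistent("read-count conservation violated in finalize_profile")
  if (sum(counts_top) + sum(counts_bottom) + sum(loop_local) !=
      n_unique_primary + n_rescued)
    abort_inconsistent("cut counts do not sum to the number of placed reads")
  mapped <- n_unique_primary + n_rescued
  cpm <- function(x) if (mapped > 0) x / mapped * 1e6 else x * 0
  structure(list(substrate = substrate,
                 counts_top = counts_top, counts_bottom = counts_bottom,
                 loop_local_counts = loop_local,
                 cpm_top = cpm(counts_top), cpm_bottom = cpm(counts_bottom),
                 cpm_loop_local = cpm(loop_local),
                 totals = totals, per_read = all_calls),
            class = "cut_profile")
}

#' @export
print.cut_profile <- function(x, ...) {
  t <- x$totals
  cat(sprintf(
    "cut profile over %d-nt plasmid: %d reads in, %d unique, %d rescued, %d ambiguous, %d unmapped\n",
    x$substrate$plasmid$length_nt, t$n_input, t$n_unique_primary,
    t$n_rescued, t$n_ambiguous, t$n_unmapped_final))
  invisible(x)
}

#' Run the full nick-mapping pipeline on a read set
#'
#' Convenience orchestration: build the 3x reference, run the primary
#' duplex-reference pass (internal aligner or imported SAM), rescue
#' loop-spanning reads against the looped strand, and finalize the cut
#' profile.
#'
#' @param substrate a `heteroduplex`.
#' @param reads data.frame (`id`, `seq`) or `simulated_reads`.
#' @param params aligner parameters (`seed_k`, `max_mismatches`).
#' @param copies copy-selection mode, see [call_cuts()].
#' @param rescue_reference see [rescue_loop_reads()].
#' @param sam optional path to an external-aligner SAM against the
#'   exported duplex 3x reference; replaces the internal primary pass.
#' @return a `cut_profile`.
#' @export
map_nicks <- function(substrate, reads, params = list(),
                      copies = c("middle", "all"),
                      rescue_reference = c("looped", "loopless"),
                      sam = NULL) {
  copies <- match.arg(copies)
  rescue_reference <- match.arg(rescue_reference)
  if (inherits(reads, "simulated_reads")) reads <- reads$reads
  bundle <- build_reference(substrate)
  aln <- if (is.null(sam)) align_reads(reads, bundle, params, "duplex")
         else read_sam_alignments(sam, bundle)
  primary <- call_cuts(aln, substrate, copies)
  pool <- reads[reads$id %in% primary$leftover$read_id, , drop = FALSE]
  rescue <- rescue_loop_reads(pool, substrate, params, rescue_reference)
  finalize_profile(primary, rescue, substrate, nrow(reads))
}

#' Export a cut profile: per-position TSV, BED intervals, polar plot,
#' JSON run summary
#'
#' The TSV holds one row per position and strand (`2N` rows, plus `L`
#' loop-local rows) with raw counts and CPM; re-importing it with
#' [read_profile_tsv()] reproduces the profile vectors exactly. The BED
#' file lists single-base half-open intervals for positions with at
#' least one cut. The polar plot draws the looped and opposite strands
#' as distinct series around the circular plasmid with the loop position
#' marked.
#'
#' @param profile a `cut_profile`.
#' @param out_prefix path prefix for the output files.
#' @return invisibly, the named vector of files written.
#' @export
export_profile <- function(profile, out_prefix) {
  sub <- profile$substrate
  n <- sub$plasmid$length_nt
  l <- sub$loop$loop_length
  tsv <- paste0(out_prefix, ".profile.tsv")
  bed <- paste0(out_prefix, ".cuts.bed")
  json <- paste0(out_prefix, ".summary.json")
  df <- data.frame(
    position = c(0:(n - 1L), 0:(n - 1L),
                 if (l > 0) 0:(l - 1L) else integer(0)),
    strand = c(rep("top", n), rep("bottom", n), rep("loop_local", l)),
    count = c(profile$counts_top, profile$counts_bottom,
              profile$loop_local_counts),
    cpm = c(profile$cpm_top, profile$cpm_bottom, profile$cpm_loop_local))
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  hit <- df[df$count > 0 & df$strand != "loop_local", , drop = FALSE]
  bed_df <- data.frame(chrom = rep(sub$plasmid$name, nrow(hit)),
                       start = hit$position,
                       end = hit$position + 1L,
                       name = rep("cut", nrow(hit)),
                       score = hit$count,
                       strand = ifelse(hit$strand == "top", "+", "-"))
  utils::write.table(bed_df, bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(plasmid = sub$plasmid$name, length_nt = n,
         loop = sub$loop$loop_sequence,
         carrier_strand = sub$loop$carrier_strand,
         insertion_point = sub$loop$insertion_point,
         totals = profile$totals),
    json, auto_unbox = TRUE)
  plot_file <- tryCatch(
    save_polar_plot(profile, out_prefix),
    error = function(e) NA_character_)
  invisible(c(tsv = tsv, bed = bed, json = json, plot = plot_file))
}

#' Re-import an exported per-position profile TSV
#'
#' @param path path to a `.profile.tsv` written by [export_profile()].
#' @return list with `counts_top`, `counts_bottom`, `loop_local_counts`,
#'   `cpm_top`, `cpm_bottom`.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  top <- df[df$strand == "top", ]
  bottom <- df[df$strand == "bottom", ]
  loc <- df[df$strand == "loop_local", ]
  list(counts_top = top$count[order(top$position)],
       counts_bottom = bottom$count[order(bottom$position)],
       loop_local_counts = loc$count[order(loc$position)],
       cpm_top = top$cpm[order(top$position)],
       cpm_bottom = bottom$cpm[order(bottom$position)])
}

#' Polar plot of a cut profile
#'
#' Counts for the looped strand and the strand opposite the loop are
#' drawn as radial segments around the circular plasmid, styled as
#' distinct series, with the loop position marked.
#'
#' @param profile a `cut_profile`.
#' @return a ggplot object.
#' @export
plot_cut_profile <- function(profile) {
  sub <- profile$substrate
  n <- sub$plasmid$length_nt
  lab <- strand_labels(sub)
  series <- function(counts, strand_label) {
    role <- if (strand_label == lab$carrier) "looped strand"
            else "opposite strand"
    data.frame(position = 0:(n - 1L), count = counts, series = role)
  }
  df <- rbind(series(profile$counts_top, "top"),
              series(profile$counts_bottom, "bottom"))
  df <- df[df$count > 0, , drop = FALSE]
  loop_pos <- sub$loop$insertion_point
  if (sub$loop$carrier_strand == "bottom")
    loop_pos <- carrier_to_plasmid(sub, loop_pos)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$position,
                                        xend = .data$position,
                                        y = 0, yend = .data$count,
                                        colour = .data$series)) +
    ggplot2::geom_vline(xintercept = loop_pos, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_segment(linewidth = 0.5) +
    ggplot2::scale_colour_manual(
      values = c("looped strand" = "#c0392b", "opposite strand" = "black"),
      limits = c("looped strand", "opposite strand")) +
    ggplot2::scale_x_continuous(limits = c(0, n)) +
    ggplot2::coord_polar(theta = "x") +
    ggplot2::labs(x = NULL, y = "cut count", colour = NULL,
                  title = sprintf("strand-specific cuts on %s",
                                  sub$plasmid$name)) +
    ggplot2::theme_minimal()
  p
}

save_polar_plot <- function(profile, out_prefix) {
  p <- plot_cut_profile(profile)
  file <- if (isTRUE(unname(capabilities("cairo"))))
    paste0(out_prefix, ".polar.svg") else paste0(out_prefix, ".polar.png")
  if (grepl("svg$", file)) {
    grDevices::svg(file, width = 7, height = 7)
  } else {
    grDevices::png(file, width = 1400, height = 1400, res = 200)
  }
  on.exit(grDevices::dev.off(), add = TRUE)
  print(p)
  file
}
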