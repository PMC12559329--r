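#' Synthetic Sanger chromatograms and simulated indel references
#'
#' The peak model is deliberately minimal and exactly linear in the
#' mixture: one scan per called base, with the four channel intensities
#' at scan `t` equal to `exp(-decay_rate * t)` times the mixture-weighted
#' indicator of each sequence's base at `t`, plus optional Gaussian noise
#' (clipped at zero). There is no inter-scan peak spreading, so a
#' noiseless mixture trace is exactly the weighted sum of the component
#' traces -- the representation that peak-height decomposition methods
#' operate on.
#'
#' @name tracesim
NULL

channel_matrix <- function(sequence, n_scans, decay_rate) {
  bases <- strsplit(substr(sequence, 1, n_scans), "", fixed = TRUE)[[1]]
  amp <- exp(-decay_rate * (seq_len(n_scans) - 1))
  m <- matrix(0, nrow = n_scans, ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_len(n_scans), match(bases, DNA_BASES))] <- amp
  m
}

#' Simulate a Sanger chromatogram from a sequence mixture
#'
#' @param mixture data.frame with columns `sequence` and `fraction`
#'   (fractions non-negative, summing to 1 within 1e-6), or a list of
#'   `list(sequence=, fraction=)`. Sequences may differ in length
#'   downstream of a shared prefix; the trace covers the shortest one.
#' @param decay_rate exponential amplitude decay per scan (default
#'   0.001, i.e. ~10% signal loss over 100 scans).
#' @param noise_sd Gaussian channel noise, as a fraction of the initial
#'   amplitude (default 0).
#' @param seed RNG seed for the noise; fixed seed gives an identical
#'   trace.
#' @return a `chromatogram`: `scans` (matrix n x 4, columns A,C,G,T),
#'   `called_sequence` (argmax channel per scan), `meta`.
#' @export
simulate_trace <- function(mixture, decay_rate = 0.001, noise_sd = 0,
                           seed = NULL) {
  if (is.list(mixture) && !is.data.frame(mixture))
    mixture <- data.frame(
      sequence = vapply(mixture, `[[`, character(1), "sequence"),
      fraction = vapply(mixture, `[[`, numeric(1), "fraction"))
  if (any(mixture$fraction < 0))
    abort_invalid("mixture fractions must be non-negative")
  if (abs(sum(mixture$fraction) - 1) > 1e-6)
    abort_invalid("mixture fractions must sum to 1 (tolerance 1e-6)")
  n_scans <- min(nchar(mixture$sequence))
  m <- matrix(0, nrow = n_scans, ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  for (j in seq_len(nrow(mixture)))
    m <- m + mixture$fraction[j] *
      channel_matrix(mixture$sequence[j], n_scans, decay_rate)
  if (noise_sd > 0)
    m <- with_seed(seed, m + matrix(stats::rnorm(4 * n_scans, 0, noise_sd),
                                    nrow = n_scans))
  m <- pmax(m, 0)
  structure(list(
    scans = m,
    called_sequence = paste(DNA_BASES[max.col(m, ties.method = "first")],
                            collapse = ""),
    meta = list(decay_rate = decay_rate, noise_sd = noise_sd, seed = seed)),
    class = "chromatogram")
}

#' Chromatogram I/O as per-scan 4-channel TSV
#'
#' Columns: `scan_index` (0-based), `A`, `C`, `G`, `T`, `called_base`.
#'
#' @param chrom a `chromatogram`.
#' @param path file path.
#' @export
write_chromatogram <- function(chrom, path) {
  df <- data.frame(scan_index = seq_len(nrow(chrom$scans)) - 1L,
                   chrom$scans,
                   called_base = strsplit(chrom$called_sequence, "")[[1]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chromatogram
#' @export
read_chromatogram <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("scan_index", "A", "C", "G", "T")
  if (!all(need %in% names(df)))
    abort_format("chromatogram TSV must have columns scan_index, A, C, G, T")
  m <- as.matrix(df[order(df$scan_index), c("A", "C", "G", "T")])
  dimnames(m) <- list(NULL, DNA_BASES)
  structure(list(scans = m,
                 called_sequence = paste(
                   DNA_BASES[max.col(m, ties.method = "first")],
                   collapse = ""),
                 meta = list()), class = "chromatogram")
}

#' Fabricate a simulated indel reference from the control sequence
#'
#' Rather than requiring a sequenced reference for each product, the
#' reference is simulated by modifying the control sequence itself:
#' inserting or removing bases at the target site mimics the expected
#' indel, and its noiseless trace serves as the reference chromatogram.
#'
#' @param control_sequence the control (unmodified) sequence.
#' @param indel list with `size` (signed integer; > 0 insertion, < 0
#'   deletion, 0 identity) and, for insertions, `bases` of length
#'   `size`.
#' @param target_site 0-based coordinate where the indel is introduced.
#' @param decay_rate passed to [simulate_trace()].
#' @return list with `sequence` (the modified sequence) and `trace`
#'   (its noiseless chromatogram).
#' @export
build_simulated_reference <- function(control_sequence, indel, target_site,
                                      decay_rate = 0.001) {
  s <- as.integer(indel$size)
  n <- nchar(control_sequence)
  if (target_site < 0 || target_site > n)
    abort_invalid("target_site outside the control sequence")
  if (s > 0) {
    bases <- toupper(indel$bases %||% "")
    if (nchar(bases) != s)
      abort_invalid("insertion requires `bases` of length `size`")
    seq <- paste0(substr(control_sequence, 1, target_site), bases,
                  substr(control_sequence, target_site + 1, n))
  } else if (s < 0) {
    if (target_site - s > n)
      abort_invalid("deletion runs past the end of the control sequence")
    seq <- paste0(substr(control_sequence, 1, target_site),
                  substr(control_sequence, target_site - s + 1, n))
  } else {
    seq <- control_sequence
  }
  list(sequence = seq,
       trace = simulate_trace(data.frame(sequence = seq, fraction = 1),
                              decay_rate = decay_rate))
}

phased_insert <- function(unit, size) {
  if (size == 0) return("")
  substr(strrep(unit, ceiling(size / nchar(unit))), 1, size)
}

#' Build the per-shift template set for trace decomposition
#'
#' One noiseless channel matrix per indel shift over the fitting window.
#' Positive shifts insert repeat-unit-phased bases of
#' `expected_insert_bases` at the target site (so the shift equal to the
#' loop length reproduces the expansion product exactly); negative
#' shifts delete bases starting at the target site.
#'
#' @param control_sequence control sequence covering the window for the
#'   most negative shift.
#' @param target_site 0-based indel site.
#' @param shift_range integer vector of shifts, e.g. `-15:15`.
#' @param window list with `start` (0-based scan index) and `width`;
#'   `NULL` uses [default_window()].
#' @param expected_insert_bases repeat unit used to phase positive-shift
#'   inserts (for a CAG-loop opposite-strand trace, `"CTG"` or the full
#'   12-nt insert).
#' @param decay_rate exponential amplitude decay per scan.
#' @return a `template_set`.
#' @export
build_templates <- function(control_sequence, target_site,
                            shift_range = -15:15, window = NULL,
                            expected_insert_bases, decay_rate = 0.001) {
  shift_range <- sort(unique(as.integer(shift_range)))
  if (is.null(window))
    window <- default_window(target_site, max(shift_range))
  w0 <- window$start
  ww <- window$width
  min_len <- nchar(control_sequence) + min(shift_range)
  if (w0 < 0 || w0 + ww > min_len)
    abort_invalid(sprintf(
      "fitting window [%d, %d) exceeds the shortest shifted sequence (%d scans)",
      w0, w0 + ww, min_len))
  if (w0 < target_site)
    abort_invalid("fitting window must start downstream of the target site")
  templates <- lapply(shift_range, function(s) {
    ref <- build_simulated_reference(
      control_sequence,
      list(size = s, bases = phased_insert(expected_insert_bases, max(s, 0))),
      target_site, decay_rate)
    ref$trace$scans[(w0 + 1L):(w0 + ww), , drop = FALSE]
  })
  names(templates) <- as.character(shift_range)
  structure(list(control_sequence = control_sequence,
                 target_site = as.integer(target_site),
                 shifts = shift_range, window = list(start = w0, width = ww),
                 expected_insert_bases = toupper(expected_insert_bases),
                 decay_rate = decay_rate,
                 templates = templates),
            class = "template_set")
}

#' Default fitting window
#'
#' Starts 5 scans downstream of `target_site + max_insert` (so every
#' template's insert is fully upstream of the window) and spans 80
#' scans.
#'
#' @param target_site 0-based indel site.
#' @param max_insert largest positive shift considered.
#' @param width window width in scans.
#' @param offset gap between the largest insert and the window start.
#' @return list with `start` and `width`.
#' @export
default_window <- function(target_site, max_insert, width = 80L,
                           offset = 5L) {
  list(start = as.integer(target_site + max_insert + offset),
       width = as.integer(width))
}

#' Extract the Sanger sequencing context of a substrate's loop site
#'
#' Returns the linear control sequence a primer-extension read-out of
#' one strand would produce around the loop, together with the matched
#' product sequence, the indel target site in window coordinates, and
#' the repeat unit used for insert templates. The opposite strand is
#' where expansion writes the loop's reverse complement; the looped
#' strand is where contraction deletes the loop.
#'
#' @param substrate a `heteroduplex` with a non-empty loop.
#' @param event `"expansion"` (opposite-strand read-out) or
#'   `"contraction"` (looped-strand read-out).
#' @param upstream,downstream nucleotides of context kept on each side
#'   of the loop site.
#' @return list with `control`, `product`, `target_site`, `insert_unit`
#'   and `indel_size`.
#' @export
sanger_context <- function(substrate, event = c("expansion", "contraction"),
                           upstream = 150L, downstream = 240L) {
  event <- match.arg(event)
  stopifnot(inherits(substrate, "heteroduplex"))
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  i <- substrate$loop$insertion_point
  if (l == 0) abort_invalid("sanger_context requires a substrate with a loop")
  if (event == "expansion") {
    # read the strand opposite the loop; its insertion point (own 5'->3')
    oi <- n - i
    start0 <- (oi - upstream) %% n
    control <- circ_substr(substrate$opposite_strand_seq, start0,
                           upstream + downstream)
    prod_full <- expansion_product(substrate)$opposite_strand
    product <- circ_substr(prod_full, start0 %% (n + l),
                           upstream + downstream + l)
    # wrap-free only if the window does not cross the origin relative to
    # the insertion; enforced by construction below
    if (start0 > oi)
      abort_invalid("upstream context crosses the plasmid origin; rotate the substrate or reduce `upstream`")
    list(control = control, product = product,
         target_site = as.integer(upstream),
         insert_unit = revcomp(substrate$loop$loop_sequence),
         indel_size = l)
  } else {
    nl <- n + l
    start0 <- (i - upstream) %% nl
    control <- circ_substr(substrate$looped_strand_seq, start0,
                           upstream + l + downstream)
    if (start0 > i)
      abort_invalid("upstream context crosses the plasmid origin; rotate the substrate or reduce `upstream`")
    product <- circ_substr(contraction_product(substrate)$looped_strand,
                           start0, upstream + downstream)
    list(control = control, product = product,
         target_site = as.integer(upstream),
         insert_unit = substrate$loop$loop_sequence,
         indel_size = -l)
  }
}
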