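#' Circular heteroduplex substrates with extrahelical loops
#'
#' A reconstituted repeat-instability reaction acts on a covalently closed
#' circular plasmid whose two strands are identical except for a short
#' extrahelical loop (for example (T)4 or (CAG)4) carried by one strand.
#' This file builds those substrates, predicts the fully double-stranded
#' products of repeat expansion (the loop's complement copied into the
#' opposite strand) and contraction (the loop excised), and converts
#' coordinates between the loop-free duplex frame and the looped-strand
#' frame.
#'
#' Conventions used throughout the package:
#' * coordinates are 0-based and interpreted modulo the relevant strand
#'   length; the "duplex" frame is the top strand of the plasmid as given
#'   in the FASTA, 5'->3';
#' * bottom-strand features are reported in top-strand coordinates with a
#'   strand flag;
#' * the loop of length L sits between duplex positions `insertion_point -
#'   1` and `insertion_point` of the carrier strand, measured in that
#'   strand's own 5'->3' sense.
#'
#' @name substrates
NULL

new_circular_plasmid <- function(name, sequence) {
  sequence <- toupper(sequence)
  if (!is_dna_string(sequence) || nchar(sequence) == 0)
    abort_format("plasmid sequence must be a non-empty A/C/G/T string")
  structure(
    list(name = name, sequence = sequence, length_nt = nchar(sequence)),
    class = "circular_plasmid"
  )
}

#' Generate a random circular plasmid
#'
#' Draws an i.i.d. random sequence at a target GC content, as a synthetic
#' stand-in for a real ~3.2 kb assay plasmid. Deterministic for a fixed
#' seed.
#'
#' @param length_nt plasmid length in nucleotides (>= 100).
#' @param gc_fraction expected fraction of G+C bases, in `[0, 1]`.
#' @param seed integer RNG seed.
#' @param name label stored with the plasmid.
#' @return a `circular_plasmid` object.
#' @examples
#' p <- generate_plasmid(3200, 0.5, seed = 7)
#' p$length_nt
#' @export
generate_plasmid <- function(length_nt, gc_fraction = 0.5, seed,
                             name = "synthetic_plasmid") {
  if (!is.numeric(length_nt) || length(length_nt) != 1 || length_nt < 100)
    abort_invalid("length_nt must be a single integer >= 100")
  if (!is.numeric(gc_fraction) || gc_fraction < 0 || gc_fraction > 1)
    abort_invalid("gc_fraction must lie in [0, 1]")
  probs <- c((1 - gc_fraction) / 2, gc_fraction / 2,
             gc_fraction / 2, (1 - gc_fraction) / 2)
  bases <- with_seed(seed, sample(DNA_BASES, length_nt, replace = TRUE,
                                  prob = probs))
  new_circular_plasmid(name, paste(bases, collapse = ""))
}

#' Load a circular plasmid from a single-record FASTA file
#'
#' @param fasta_source path to a FASTA file containing exactly one record
#'   of A/C/G/T bases (case-insensitive).
#' @return a `circular_plasmid` with the sequence uppercased and circular
#'   semantics attached.
#' @export
load_plasmid <- function(fasta_source) {
  recs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_source),
    error = function(e) abort_format(paste0("cannot read FASTA: ",
                                            conditionMessage(e)))
  )
  if (length(recs) != 1)
    abort_format(sprintf("expected exactly one FASTA record, found %d",
                         length(recs)))
  seq <- toupper(as.character(recs[[1]]))
  if (!is_dna_string(seq) || nchar(seq) == 0)
    abort_format("FASTA record contains non-A/C/G/T characters or is empty")
  new_circular_plasmid(sub("\\s.*$", "", names(recs)[1]), seq)
}

#' Write a plasmid to FASTA with a circular flag in the header
#' @param plasmid a `circular_plasmid`.
#' @param path output file path.
#' @export
write_plasmid <- function(plasmid, path) {
  x <- Biostrings::DNAStringSet(plasmid$sequence)
  names(x) <- paste0(plasmid$name, " circular=true")
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Specify an extrahelical loop
#'
#' @param carrier_strand which strand carries the loop, `"top"` or
#'   `"bottom"`.
#' @param insertion_point 0-based duplex coordinate `i` in the carrier
#'   strand's 5'->3' sense; the loop sits between positions `i - 1` and
#'   `i`.
#' @param loop_sequence loop bases, 5'->3' on the carrier strand (may be
#'   empty).
#' @return a `loop_spec` object.
#' @export
loop_spec <- function(carrier_strand = c("top", "bottom"),
                      insertion_point, loop_sequence) {
  carrier_strand <- match.arg(carrier_strand)
  loop_sequence <- toupper(loop_sequence)
  if (!is_dna_string(loop_sequence))
    abort_invalid("loop_sequence must be an A/C/G/T string (possibly empty)")
  if (!is.numeric(insertion_point) || length(insertion_point) != 1 ||
      insertion_point < 0)
    abort_invalid("insertion_point must be a single non-negative integer")
  structure(
    list(carrier_strand = carrier_strand,
         insertion_point = as.integer(insertion_point),
         loop_sequence = loop_sequence,
         loop_length = nchar(loop_sequence)),
    class = "loop_spec"
  )
}

#' Build a circular heteroduplex substrate
#'
#' Inserts the loop into the carrier strand of the duplex. The looped
#' strand has length `N + L`; the opposite strand is the loop-free
#' complement of length `N`. Warns when the loop sequence also occurs
#' elsewhere in the plasmid, since repeated context causes multi-mapping
#' of simulated reads.
#'
#' @param plasmid a `circular_plasmid` of length `N`.
#' @param loop a `loop_spec` with loop length `L`.
#' @return a `heteroduplex` object with fields `plasmid`, `loop`,
#'   `looped_strand_seq` (length `N + L`, carrier-strand 5'->3'),
#'   `opposite_strand_seq` (length `N`, its own 5'->3'), and the
#'   looped-strand coordinates `loop5_boundary` / `loop3_boundary` of the
#'   first and last loop nucleotide (`NA` for an empty loop).
#' @examples
#' p <- generate_plasmid(500, 0.5, seed = 1)
#' sub <- make_heteroduplex(p, loop_spec("top", 250, "CAGCAGCAGCAG"))
#' nchar(sub$looped_strand_seq) - p$length_nt
#' @export
make_heteroduplex <- function(plasmid, loop) {
  stopifnot(inherits(plasmid, "circular_plasmid"), inherits(loop, "loop_spec"))
  n <- plasmid$length_nt
  i <- loop$insertion_point
  l <- loop$loop_length
  if (i < 0 || i >= n)
    abort_invalid(sprintf("insertion_point %d out of range [0, %d)", i, n))
  carrier_seq <- if (loop$carrier_strand == "top") plasmid$sequence
                 else revcomp(plasmid$sequence)
  looped <- paste0(substr(carrier_seq, 1, i), loop$loop_sequence,
                   substr(carrier_seq, i + 1, n))
  opposite <- revcomp(carrier_seq)
  if (l > 0) {
    # repeated loop context elsewhere on the plasmid breaks unique mapping
    hits <- Biostrings::countPattern(loop$loop_sequence,
                                     paste0(plasmid$sequence,
                                            substr(plasmid$sequence, 1, l))) +
      Biostrings::countPattern(loop$loop_sequence,
                               paste0(revcomp(plasmid$sequence),
                                      substr(revcomp(plasmid$sequence), 1, l)))
    if (hits > 0)
      warning(sprintf(
        "loop sequence '%s' also occurs %d time(s) in the duplex; ",
        loop$loop_sequence, hits),
        "loop-spanning reads may become ambiguous", call. = FALSE)
  }
  structure(
    list(plasmid = plasmid, loop = loop,
         carrier_duplex_seq = carrier_seq,
         looped_strand_seq = looped,
         opposite_strand_seq = opposite,
         loop5_boundary = if (l > 0) i else NA_integer_,
         loop3_boundary = if (l > 0) i + l - 1L else NA_integer_),
    class = "heteroduplex"
  )
}

#' @export
print.heteroduplex <- function(x, ...) {
  cat(sprintf(
    "heteroduplex substrate: plasmid '%s' (%d nt), %d-nt loop '%s' on %s strand at duplex position %d\n",
    x$plasmid$name, x$plasmid$length_nt, x$loop$loop_length,
    x$loop$loop_sequence, x$loop$carrier_strand, x$loop$insertion_point))
  invisible(x)
}

# Carrier-frame duplex coordinate of a plasmid (top-strand) coordinate.
# For a top-strand carrier the two frames coincide; for a bottom-strand
# carrier position p pairs with bottom coordinate N - 1 - p.
plasmid_to_carrier <- function(substrate, p) {
  n <- substrate$plasmid$length_nt
  if (substrate$loop$carrier_strand == "top") p %% n else (n - 1L - (p %% n)) %% n
}

carrier_to_plasmid <- plasmid_to_carrier  # involution

#' Map positions between the duplex and looped-strand frames
#'
#' The duplex frame is the plasmid top strand (0..N-1); the looped-strand
#' frame is the carrier strand with the loop inserted (0..N+L-1, in the
#' carrier strand's 5'->3' sense). Outside the loop the map is a
#' bijection. Looped-strand positions inside the loop have no duplex
#' partner: they are returned as `NA` with the loop-local offset (0-based
#' from the 5' loop boundary) recorded in the `"loop_offset"` attribute.
#'
#' @param substrate a `heteroduplex`.
#' @param position integer vector of positions, valid in `from_frame`.
#' @param from_frame,to_frame `"duplex"` or `"looped_strand"`.
#' @return integer vector of mapped positions (`NA` for loop-internal
#'   inputs), with attribute `loop_offset`.
#' @export
coord_map <- function(substrate, position,
                      from_frame = c("duplex", "looped_strand"),
                      to_frame = c("looped_strand", "duplex")) {
  from_frame <- match.arg(from_frame)
  to_frame <- match.arg(to_frame)
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  i <- substrate$loop$insertion_point
  position <- as.integer(position)
  lim <- if (from_frame == "duplex") n else n + l
  if (any(is.na(position)) || any(position < 0 | position >= lim))
    abort_invalid(sprintf("position out of range [0, %d) in frame '%s'",
                          lim, from_frame))
  if (from_frame == to_frame) {
    out <- position
    attr(out, "loop_offset") <- rep(NA_integer_, length(out))
    return(out)
  }
  if (from_frame == "duplex") {
    cd <- plasmid_to_carrier(substrate, position)
    out <- ifelse(cd < i, cd, cd + l)
    off <- rep(NA_integer_, length(out))
  } else {
    in_loop <- l > 0 & position >= i & position < i + l
    cd <- ifelse(position < i, position, position - l)
    out <- ifelse(in_loop, NA_integer_,
                  carrier_to_plasmid(substrate, cd))
    off <- ifelse(in_loop, position - i, NA_integer_)
  }
  out <- as.integer(out)
  attr(out, "loop_offset") <- as.integer(off)
  out
}

#' Predict the repeat-expansion product
#'
#' Expansion copies the loop into the opposite strand: displacement
#' synthesis across the loop templates the loop's reverse complement into
#' the strand opposite the loop, giving a fully paired circle of length
#' `N + L` on both strands. The looped strand itself is unchanged.
#'
#' @param substrate a `heteroduplex`.
#' @return list with `looped_strand` and `opposite_strand` sequences,
#'   each of length `N + L` in its own 5'->3' sense.
#' @export
expansion_product <- function(substrate) {
  stopifnot(inherits(substrate, "heteroduplex"))
  n <- substrate$plasmid$length_nt
  i <- substrate$loop$insertion_point
  opp <- substrate$opposite_strand_seq
  # insertion lands between opposite-strand coordinates N-i-1 and N-i
  oi <- n - i
  opp_exp <- paste0(substr(opp, 1, oi),
                    revcomp(substrate$loop$loop_sequence),
                    substr(opp, oi + 1, n))
  list(looped_strand = substrate$looped_strand_seq,
       opposite_strand = opp_exp)
}

#' Predict the repeat-contraction product
#'
#' Contraction excises the loop: both strands collapse to the loop-free
#' duplex of length `N`.
#'
#' @param substrate a `heteroduplex`.
#' @return list with `looped_strand` (now loop-free carrier strand) and
#'   `opposite_strand`, both of length `N`.
#' @export
contraction_product <- function(substrate) {
  stopifnot(inherits(substrate, "heteroduplex"))
  list(looped_strand = substrate$carrier_duplex_seq,
       opposite_strand = substrate$opposite_strand_seq)
}

#' Serialize / restore a substrate description as JSON
#'
#' The JSON carries the plasmid name and sequence plus the loop
#' specification, so a substrate file is self-contained.
#'
#' @param substrate a `heteroduplex`.
#' @param path output (input) file path.
#' @export
write_substrate <- function(substrate, path) {
  jsonlite::write_json(
    list(plasmid_name = substrate$plasmid$name,
         plasmid_sequence = substrate$plasmid$sequence,
         carrier_strand = substrate$loop$carrier_strand,
         insertion_point = substrate$loop$insertion_point,
         loop_sequence = substrate$loop$loop_sequence,
         loop5_boundary = substrate$loop5_boundary,
         loop3_boundary = substrate$loop3_boundary),
    path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_substrate
#' @export
read_substrate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  suppressWarnings(make_heteroduplex(
    new_circular_plasmid(x$plasmid_name, x$plasmid_sequence),
    loop_spec(x$carrier_strand, x$insertion_point, x$loop_sequence)))
}
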