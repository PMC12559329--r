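#' Nick profiles and 3'-OH-capture read simulation
#'
#' A nick at index `p` on strand `s` is a broken backbone between the
#' nucleotide at `p` and its 3' neighbour on that strand, leaving a free
#' 3'-OH at `p`. 3'-OH-capture sequencing reads the *intact complementary
#' strand*: each simulated read maps to the strand opposite the nicked
#' one, and its 5'-most reference coordinate sits base-paired immediately
#' across from the free 3'-OH nucleotide. The cut caller in this package
#' uses the identical convention, so simulator/caller round-trip identity
#' defines correctness of the geometry.
#'
#' Profile indexing: the intensity vector of the loop-carrying strand is
#' indexed by looped-strand coordinates (length `N + L`); the loop-free
#' strand is indexed by plasmid top-strand coordinates (length `N`).
#'
#' @name gloesim
NULL

strand_labels <- function(substrate) {
  carrier <- substrate$loop$carrier_strand
  list(carrier = carrier, opposite = if (carrier == "top") "bottom" else "top")
}

#' Construct a per-position, per-strand nick intensity profile
#'
#' @param substrate a `heteroduplex`.
#' @param intensity_top,intensity_bottom non-negative intensity vectors.
#'   The vector of the loop-carrying strand must have length `N + L`
#'   (looped-strand coordinates); the other strand has length `N`
#'   (plasmid coordinates).
#' @return a `nick_profile` object.
#' @export
nick_profile <- function(substrate, intensity_top, intensity_bottom) {
  stopifnot(inherits(substrate, "heteroduplex"))
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  len_top <- if (substrate$loop$carrier_strand == "top") n + l else n
  len_bottom <- if (substrate$loop$carrier_strand == "bottom") n + l else n
  if (length(intensity_top) != len_top)
    abort_invalid(sprintf("intensity_top must have length %d", len_top))
  if (length(intensity_bottom) != len_bottom)
    abort_invalid(sprintf("intensity_bottom must have length %d", len_bottom))
  if (any(intensity_top < 0) || any(intensity_bottom < 0))
    abort_invalid("nick intensities must be non-negative")
  structure(list(substrate = substrate,
                 intensity_top = as.numeric(intensity_top),
                 intensity_bottom = as.numeric(intensity_bottom)),
            class = "nick_profile")
}

# Plasmid coordinate `offset` nucleotides 5' of the loop along the
# *opposite* strand (offset >= 1). The 5' direction of the opposite
# strand runs against the carrier strand's 5'->3' sense.
opposite_flank_position <- function(substrate, offset) {
  n <- substrate$plasmid$length_nt
  i <- substrate$loop$insertion_point
  cd <- (i - 1L + offset) %% n        # carrier-frame duplex coordinate
  carrier_to_plasmid(substrate, cd)
}

#' Preset nick-intensity scenarios
#'
#' Three planted incision geometries:
#' * `mutl_opposite_5prime` — loop-recognition (MutSbeta-MutLgamma-like)
#'   incision: a decaying multi-peak distribution on the strand opposite
#'   the loop, extending 5' from the loop along that strand;
#' * `fan1_loop3prime` — FAN1-like incision: one dominant peak on the
#'   looped strand exactly one nucleotide 3' of the loop
#'   (`loop3_boundary + 1`), plus low uniform background;
#' * `uniform` — equal intensity at every position of one strand.
#'
#' @param scenario one of `"mutl_opposite_5prime"`, `"fan1_loop3prime"`,
#'   `"uniform"`.
#' @param substrate a `heteroduplex`.
#' @param params named list of scenario parameters. For
#'   `mutl_opposite_5prime`: `n_peaks` (8), `first_offset` (20 nt),
#'   `spacing` (30 nt), `decay_length` (100 nt), `background` (0.05).
#'   For `fan1_loop3prime`: `background` (0.05). For `uniform`: `strand`
#'   (`"top"`).
#' @return a `nick_profile`; intensities sum to 1.
#' @export
preset_profile <- function(scenario, substrate, params = list()) {
  stopifnot(inherits(substrate, "heteroduplex"))
  n <- substrate$plasmid$length_nt
  l <- substrate$loop$loop_length
  lab <- strand_labels(substrate)
  carrier_len <- n + l
  int_carrier <- numeric(carrier_len)
  int_opposite <- numeric(n)
  loop_idx <- if (l > 0)
    (substrate$loop5_boundary:substrate$loop3_boundary) + 1L else integer(0)

  add_background <- function(frac) {
    if (frac <= 0) return()
    paired <- carrier_len - l
    per_pos <- frac / (paired + n)
    int_carrier[] <<- int_carrier + per_pos
    if (l > 0) int_carrier[loop_idx] <<- int_carrier[loop_idx] - per_pos
    int_opposite[] <<- int_opposite + per_pos
  }

  if (scenario == "mutl_opposite_5prime") {
    n_peaks <- params$n_peaks %||% 8L
    first_offset <- params$first_offset %||% 20L
    spacing <- params$spacing %||% 30L
    decay_length <- params$decay_length %||% 100
    background <- params$background %||% 0.05
    offsets <- first_offset + spacing * (seq_len(n_peaks) - 1L)
    heights <- exp(-offsets / decay_length)
    heights <- heights / sum(heights) * (1 - background)
    pos <- opposite_flank_position(substrate, offsets)
    for (j in seq_along(pos))
      int_opposite[pos[j] + 1L] <- int_opposite[pos[j] + 1L] + heights[j]
    add_background(background)
  } else if (scenario == "fan1_loop3prime") {
    if (l == 0)
      abort_invalid("fan1_loop3prime requires a substrate with a loop")
    background <- params$background %||% 0.05
    peak <- (substrate$loop3_boundary + 1L) %% carrier_len
    int_carrier[peak + 1L] <- 1 - background
    add_background(background)
  } else if (scenario == "uniform") {
    strand <- params$strand %||% "top"
    if (!strand %in% c("top", "bottom"))
      abort_invalid("uniform scenario: params$strand must be 'top' or 'bottom'")
    if (strand == lab$carrier) {
      int_carrier[] <- 1 / (carrier_len - l)
      if (l > 0) int_carrier[loop_idx] <- 0
    } else {
      int_opposite[] <- 1 / n
    }
  } else {
    abort_invalid(sprintf("unknown scenario '%s'", scenario))
  }

  if (lab$carrier == "top")
    nick_profile(substrate, int_carrier, int_opposite)
  else
    nick_profile(substrate, int_opposite, int_carrier)
}

carrier_intensity <- function(profile) {
  if (profile$substrate$loop$carrier_strand == "top")
    profile$intensity_top else profile$intensity_bottom
}

opposite_intensity <- function(profile) {
  if (profile$substrate$loop$carrier_strand == "top")
    profile$intensity_bottom else profile$intensity_top
}

draw_read_lengths <- function(read_length, n) {
  if (is.numeric(read_length) && length(read_length) == 1) {
    return(rep(as.integer(read_length), n))
  }
  if (is.list(read_length) && identical(read_length$dist, "tgeom")) {
    # truncated-geometric fragment lengths, crude sonication mimic
    min_l <- as.integer(read_length$min %||% 40L)
    max_l <- as.integer(read_length$max %||% 150L)
    mean_l <- read_length$mean %||% 75
    p <- 1 / max(mean_l - min_l, 1)
    len <- min_l + stats::rgeom(n, p)
    return(pmin(len, max_l))
  }
  abort_invalid("read_length must be a single integer or list(dist='tgeom', ...)")
}

#' Simulate 3'-OH-capture single-end reads from a nick profile
#'
#' Nick positions are drawn from the normalised profile; each read is the
#' sequence of the intact strand opposite the nick, starting base-paired
#' across from the free 3'-OH and extending 5'->3' along that strand,
#' with circular wrap-around. Substitution errors are injected uniformly
#' at `error_rate` per base. Reads from loop-proximal nicks on the
#' opposite strand therefore traverse the loop and contain the loop
#' sequence; such reads fail duplex mapping and exercise the loop-rescue
#' pass of the cut caller.
#'
#' @param profile a `nick_profile` with at least one positive entry.
#' @param n_reads number of reads to emit (>= 0).
#' @param read_length fixed read length in nt (default 75), or
#'   `list(dist = "tgeom", min, mean, max)` for a truncated-geometric
#'   length distribution.
#' @param error_rate per-base substitution probability.
#' @param seed integer RNG seed; fixed seed gives byte-identical FASTQ.
#' @return a `simulated_reads` object: `reads` (data.frame `id`, `seq`,
#'   `qual`) and `truth` (data.frame `read_id`, `strand` of the nicked
#'   strand, `nick_position` in the strand's native frame,
#'   `plasmid_position`, `read_length`).
#' @export
simulate_reads <- function(profile, n_reads, read_length = 75L,
                           error_rate = 0, seed = 1L) {
  stopifnot(inherits(profile, "nick_profile"))
  sub <- profile$substrate
  n <- sub$plasmid$length_nt
  l <- sub$loop$loop_length
  i <- sub$loop$insertion_point
  lab <- strand_labels(sub)
  if (n_reads < 0) abort_invalid("n_reads must be >= 0")
  if (n_reads == 0) {
    return(structure(list(
      reads = data.frame(id = character(0), seq = character(0),
                         qual = character(0)),
      truth = data.frame(read_id = character(0), strand = character(0),
                         nick_position = integer(0),
                         plasmid_position = integer(0),
                         read_length = integer(0)),
      substrate = sub), class = "simulated_reads"))
  }
  ic <- carrier_intensity(profile)
  io <- opposite_intensity(profile)
  if (sum(ic) + sum(io) <= 0)
    abort_invalid("all-zero nick profile with n_reads > 0")
  if (l > 0 && any(ic[(sub$loop5_boundary:sub$loop3_boundary) + 1L] > 0))
    abort_invalid(paste0(
      "positive nick intensity inside the extrahelical loop: loop-internal ",
      "3'-OH ends have no base-paired partner and no defined read geometry"))

  frame <- data.frame(
    strand = c(rep("carrier", n + l), rep("opposite", n)),
    pos = c(0:(n + l - 1L), 0:(n - 1L)),
    w = c(ic, io))
  frame <- frame[frame$w > 0, ]

  with_seed(seed, {
    pick <- sample.int(nrow(frame), n_reads, replace = TRUE, prob = frame$w)
    lens <- draw_read_lengths(read_length, n_reads)
    if (any(lens > n))
      abort_invalid("read_length exceeds plasmid length")
    strand_k <- frame$strand[pick]
    pos_k <- frame$pos[pick]

    seqs <- character(n_reads)
    is_car <- strand_k == "carrier"
    if (any(is_car)) {
      # nick on the looped (carrier) strand at looped coordinate q:
      # read is the opposite strand, 5'-most across from q
      q <- pos_k[is_car]
      d <- ifelse(q < i, q, q - l)              # carrier-frame duplex coord
      st <- (d - lens[is_car] + 1L) %% n
      seqs[is_car] <- revcomp(circ_substr(sub$carrier_duplex_seq, st,
                                          lens[is_car]))
    }
    if (any(!is_car)) {
      # nick on the opposite strand at plasmid coordinate p: read is the
      # looped strand, 5'-most across from p, so it can traverse the loop
      p <- pos_k[!is_car]
      cd <- plasmid_to_carrier(sub, p)
      lm <- ifelse(cd < i, cd, cd + l)
      seqs[!is_car] <- circ_substr(sub$looped_strand_seq, lm, lens[!is_car])
    }

    if (error_rate > 0) {
      chars <- strsplit(seqs, "", fixed = TRUE)
      flat <- unlist(chars)
      hit <- which(stats::runif(length(flat)) < error_rate)
      if (length(hit)) {
        # substitute with one of the three other bases
        repl <- vapply(flat[hit], function(b)
          sample(setdiff(DNA_BASES, b), 1L), character(1))
        flat[hit] <- repl
        grp <- factor(rep(seq_along(chars), lens), levels = seq_along(chars))
        seqs <- vapply(split(flat, grp), paste, character(1), collapse = "")
        names(seqs) <- NULL
      }
    }

    ids <- sprintf("read%07d", seq_len(n_reads))
    nick_strand <- ifelse(strand_k == "carrier", lab$carrier, lab$opposite)
    plasmid_pos <- integer(n_reads)
    if (any(is_car)) {
      q <- pos_k[is_car]
      plasmid_pos[is_car] <- carrier_to_plasmid(sub, ifelse(q < i, q, q - l))
    }
    plasmid_pos[!is_car] <- pos_k[!is_car]

    structure(list(
      reads = data.frame(id = ids, seq = seqs,
                         qual = strrep("I", lens)),
      truth = data.frame(read_id = ids, strand = nick_strand,
                         nick_position = pos_k,
                         plasmid_position = plasmid_pos,
                         read_length = lens),
      substrate = sub), class = "simulated_reads")
  })
}

#' Write simulated reads as FASTQ and the truth table as TSV
#'
#' @param readset a `simulated_reads` object (or a data.frame with `id`,
#'   `seq`, `qual` for `write_fastq`).
#' @param path output path.
#' @export
write_fastq <- function(readset, path) {
  reads <- if (inherits(readset, "simulated_reads")) readset$reads else readset
  lines <- character(4L * nrow(reads))
  if (nrow(reads) > 0) {
    idx <- seq_len(nrow(reads))
    lines[4 * idx - 3] <- paste0("@", reads$id)
    lines[4 * idx - 2] <- reads$seq
    lines[4 * idx - 1] <- "+"
    lines[4 * idx] <- reads$qual
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_truth <- function(readset, path) {
  stopifnot(inherits(readset, "simulated_reads"))
  utils::write.table(readset$truth, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read single-end FASTQ into the data.frame currency used by the aligner
#' @param path FASTQ file path.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path)),
    error = function(e) abort_format(paste0("malformed FASTQ: ",
                                            conditionMessage(e))))
  data.frame(id = names(x) %||% sprintf("read%07d", seq_along(x)),
             seq = as.character(x),
             qual = as.character(Biostrings::quality(x)))
}
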