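# Shared low-level helpers: circular string arithmetic, reverse
# complementation, classed error conditions and seeded evaluation.

DNA_BASES <- c("A", "C", "G", "T")

# let data.table's `[` semantics work inside this package
.datatable.aware <- TRUE

abort <- function(msg, class) {
  stop(structure(
    class = c(class, "loopmapr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

abort_invalid <- function(msg) abort(msg, "loopmapr_invalid_argument")
abort_format  <- function(msg) abort(msg, "loopmapr_format_error")
abort_degenerate <- function(msg) abort(msg, "loopmapr_numerical_degeneracy")
abort_inconsistent <- function(msg) abort(msg, "loopmapr_internal_inconsistency")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character DNA sequences
#'
#' Thin vectorised wrapper over [Biostrings::reverseComplement()] that keeps
#' plain character vectors as the working currency of the package.
#'
#' @param x character vector of A/C/G/T sequences.
#' @return character vector of the same length.
#' @keywords internal
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Circular substring: 0-based start, wraps around the end of `seq`.
# Requires len <= nchar(seq); doubling the string covers every window.
circ_substr <- function(seq, start0, len) {
  n <- nchar(seq)
  stopifnot(all(len <= n))
  start0 <- start0 %% n
  substring(paste0(seq, seq), start0 + 1L, start0 + len)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic operations in the package funnel through this.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  seed <- as.integer(seed)
  withr::with_seed(seed, expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

is_dna_string <- function(x) {
  length(x) == 1 && is.character(x) && !is.na(x) &&
    grepl("^[ACGT]*$", x)
}
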