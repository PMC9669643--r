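# Core sequence records and circular-sequence arithmetic.
#
# Internal coordinates are 0-based half-open everywhere; conversion to the
# 1-based inclusive convention happens only in file readers/writers.

IUPAC_CHARS <- "ACGTRYSWKMBDHVN"
IUPAC_COMP  <- "TGCAYRSWMKVHDBN"

#' Create a sequence record
#'
#' A lightweight container for one nucleotide sequence: an identifier (no
#' whitespace), an optional free-text description, and an uppercase IUPAC
#' base string.
#'
#' @param id Record identifier; must be non-empty and contain no whitespace.
#' @param bases Nucleotide string over the IUPAC alphabet (case-insensitive;
#'   stored uppercase).
#' @param description Optional description (the remainder of a FASTA header).
#' @return An object of class `seq_record` with elements `id`, `description`
#'   and `bases`.
#' @export
seq_record <- function(id, bases, description = "") {
  if (!is.character(id) || length(id) != 1L || !nzchar(id) || grepl("\\s", id)) {
    abort("`id` must be a single non-empty string without whitespace",
          class = "plastr_bad_record")
  }
  bases <- toupper(bases)
  if (!is.character(bases) || length(bases) != 1L || !nzchar(bases)) {
    abort(sprintf("record '%s' has an empty sequence", id),
          class = "plastr_bad_record")
  }
  check_iupac(bases, what = sprintf("record '%s'", id))
  structure(list(id = id, description = description, bases = bases),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d bp)\n", x$id, nchar(x$bases)))
  invisible(x)
}

#' Create a circular sequence
#'
#' Plastomes are circular molecules; this wraps a base string with an id and
#' marks it circular so coordinate arithmetic wraps the origin.
#'
#' @param id Sequence identifier.
#' @param bases IUPAC nucleotide string.
#' @return An object of class `circular_sequence` (also a `seq_record`).
#' @export
circular_sequence <- function(id, bases) {
  rec <- seq_record(id, bases)
  rec$circular <- TRUE
  class(rec) <- c("circular_sequence", "seq_record")
  rec
}

# Accept a circular_sequence, seq_record, or bare string; return the bases.
as_bases <- function(x) {
  if (inherits(x, "seq_record")) return(x$bases)
  if (is.character(x) && length(x) == 1L) return(toupper(x))
  abort("expected a sequence record or a single string")
}

seq_id <- function(x, default = "seq") {
  if (inherits(x, "seq_record")) x$id else default
}

check_iupac <- function(bases, what = "sequence") {
  bad <- regexpr(sprintf("[^%s]", IUPAC_CHARS), bases)
  if (bad > 0L) {
    abort(sprintf("%s contains a non-IUPAC character '%s' at position %d",
                  what, substr(bases, bad, bad), bad),
          class = "plastr_bad_alphabet")
  }
  invisible(bases)
}

#' Reverse complement of an IUPAC nucleotide string
#'
#' Complements every IUPAC code (including ambiguity codes: N->N, R<->Y,
#' K<->M, B<->V, D<->H; S and W are self-complementary) and reverses the
#' string.  The operation is an involution.
#'
#' @param bases Character vector of IUPAC nucleotide strings.
#' @return Character vector of reverse-complemented strings.
#' @examples
#' reverse_complement("AACCGG")  # "CCGGTT"
#' @export
reverse_complement <- function(bases) {
  vapply(bases, function(b) {
    b <- toupper(b)
    check_iupac(b)
    comp <- chartr(IUPAC_CHARS, IUPAC_COMP, b)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

# Circular substring: `len` bases starting at 0-based `start0`, wrapping the
# origin.  len may equal the sequence length (a rotation).
circ_substr <- function(bases, start0, len) {
  n <- nchar(bases)
  if (len > n) abort("circular substring longer than the sequence")
  if (len == 0L) return("")
  s <- ((start0 %% n) + n) %% n
  substr(paste0(bases, bases), s + 1L, s + len)
}

# Rotate left by `k`: the base at position k becomes position 0.
rotate_bases <- function(bases, k) circ_substr(bases, k, nchar(bases))

# Reverse-complement the circular interval [start0, start0 + len) in place,
# leaving the rest of the molecule untouched.  Handles origin wrap.
splice_revcomp <- function(bases, start0, len) {
  n <- nchar(bases)
  s <- ((start0 %% n) + n) %% n
  if (s + len <= n) {
    paste0(substr(bases, 1L, s),
           reverse_complement(substr(bases, s + 1L, s + len)),
           substr(bases, s + len + 1L, n))
  } else {
    rot <- rotate_bases(bases, s)
    rot <- paste0(reverse_complement(substr(rot, 1L, len)),
                  substr(rot, len + 1L, n))
    rotate_bases(rot, (n - s) %% n)
  }
}

# Split a string into a character vector of single bases.
base_chars <- function(bases) strsplit(bases, "", fixed = TRUE)[[1L]]
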