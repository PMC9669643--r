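# Quadripartite structure resolution: given the inverted-repeat pairs of a
# circular plastome, locate LSC, IRb, SSC and IRa.

#' Plastome structure object
#'
#' Holds the four region intervals on the circular coordinate system, in
#' circular order LSC -> IRb -> SSC -> IRa.  Intervals are 0-based
#' half-open; an end beyond the genome length marks an origin-wrapping
#' region.  The four intervals tile the whole circle.
#'
#' @param lsc,irb,ssc,ira Integer vectors `c(start, end)`.
#' @param genome_length Total genome length in bp.
#' @return An object of class `plastome_structure` with a `regions` tibble
#'   (`region`, `start`, `end`, `length`) and `genome_length`.
#' @export
plastome_structure <- function(lsc, irb, ssc, ira, genome_length) {
  regions <- tibble(
    region = c("lsc", "irb", "ssc", "ira"),
    start = as.integer(c(lsc[1L], irb[1L], ssc[1L], ira[1L])),
    end = as.integer(c(lsc[2L], irb[2L], ssc[2L], ira[2L])))
  regions$length <- regions$end - regions$start
  if (sum(regions$length) != genome_length) {
    abort("region lengths do not tile the genome",
          class = "plastr_bad_structure")
  }
  structure(list(regions = regions,
                 genome_length = as.integer(genome_length)),
            class = "plastome_structure")
}

#' @export
print.plastome_structure <- function(x, ...) {
  cat(sprintf("<plastome_structure> %d bp\n", x$genome_length))
  r <- x$regions
  for (i in seq_len(nrow(r))) {
    cat(sprintf("  %-4s %7d..%-7d (%d bp)\n", toupper(r$region[i]),
                r$start[i] %% x$genome_length + 1L,
                (r$end[i] - 1L) %% x$genome_length + 1L, r$length[i]))
  }
  invisible(x)
}

#' @export
as_tibble.plastome_structure <- function(x, ...) x$regions

region_interval <- function(structure, region) {
  r <- structure$regions[structure$regions$region == region, ]
  c(r$start, r$end)
}

#' Extract one region's sequence
#'
#' @param seq The circular sequence the structure was resolved on.
#' @param structure A [plastome_structure()].
#' @param region One of `"lsc"`, `"irb"`, `"ssc"`, `"ira"`.
#' @return The region's nucleotide string (wrapping the origin if needed).
#' @export
region_sequence <- function(seq, structure, region) {
  iv <- region_interval(structure, region)
  circ_substr(as_bases(seq), iv[1L], iv[2L] - iv[1L])
}

#' Resolve the quadripartite structure from inverted repeats
#'
#' The longest inverted pair is taken as the IRs; the two arcs between its
#' copies are the single-copy regions, the longer arc being the LSC.  IRb
#' is the IR copy immediately clockwise of the LSC, so the four intervals
#' come back in circular order LSC -> IRb -> SSC -> IRa.
#'
#' @param seq The circular sequence the repeats were found on.
#' @param repeats Repeat pairs from [find_inverted_repeats()] on `seq`.
#' @param reference Optional `reference_annotation`; used only to break the
#'   tie when the two arcs have equal length (the arc with the higher
#'   alignment identity to the reference LSC becomes the LSC).
#' @param ref_structure Optional pre-resolved [plastome_structure()] of the
#'   reference (resolved on demand otherwise).
#' @param params [structure_params()] used to resolve the reference when
#'   needed.
#' @return A [plastome_structure()].
#' @export
resolve_quadripartite <- function(seq, repeats, reference = NULL,
                                  ref_structure = NULL,
                                  params = structure_params()) {
  b <- as_bases(seq)
  n <- nchar(b)
  min_length <- attr(repeats, "min_length") %||% params$min_length
  if (is.null(repeats) || nrow(repeats) == 0L ||
      max(repeats$length) < min_length) {
    abort("no inverted repeat of the required length: quadripartite structure not found",
          class = "plastr_no_quadripartite")
  }
  top <- repeats[1L, ]
  sa <- top$copy_a_start; ea <- top$copy_a_end
  sb <- top$copy_b_start; eb <- top$copy_b_end
  L <- top$length
  gap_ab <- (sb - ea) %% n  # arc clockwise from copy A end to copy B start
  gap_ba <- (sa - eb) %% n  # arc clockwise from copy B end to copy A start

  build <- function(lsc_start, lsc_len, irb_start, ssc_len) {
    lsc_start <- lsc_start %% n
    irb_start <- irb_start %% n
    ssc_start <- (irb_start + L) %% n
    ira_start <- (ssc_start + ssc_len) %% n
    plastome_structure(c(lsc_start, lsc_start + lsc_len),
                       c(irb_start, irb_start + L),
                       c(ssc_start, ssc_start + ssc_len),
                       c(ira_start, ira_start + L), n)
  }

  pick_a_first <- function() build(eb, gap_ba, sa, gap_ab)   # LSC then copy A
  pick_b_first <- function() build(ea, gap_ab, sb, gap_ba)   # LSC then copy B

  if (gap_ab > gap_ba) return(pick_b_first())
  if (gap_ba > gap_ab) return(pick_a_first())

  # equal arcs: need the reference to decide which arc is the LSC
  if (is.null(reference)) {
    abort("the two single-copy arcs have equal length and no reference was supplied",
          class = "plastr_ambiguous_structure")
  }
  if (is.null(ref_structure)) {
    ref_structure <- resolve_reference_structure(reference, params)
  }
  ref_lsc <- region_sequence(reference$sequence, ref_structure, "lsc")
  arc_ab <- circ_substr(b, ea %% n, gap_ab)
  arc_ba <- circ_substr(b, eb %% n, gap_ba)
  if (alignment_identity(arc_ab, ref_lsc) >=
      alignment_identity(arc_ba, ref_lsc)) pick_b_first() else pick_a_first()
}

#' Resolve and cache a reference's structure
#'
#' @param reference A `reference_annotation` from [read_genbank()].
#' @param params [structure_params()].
#' @return A [plastome_structure()] (also memoized inside `reference`'s
#'   environment when possible).
#' @export
resolve_reference_structure <- function(reference, params = structure_params()) {
  reps <- find_inverted_repeats(reference$sequence,
                                min_length = params$min_length,
                                min_identity = params$min_identity,
                                k = params$k)
  resolve_quadripartite(reference$sequence, reps)
}

#' Maximum circular boundary deviation between two structures
#'
#' Compares two structures on the same circular coordinate system and
#' returns the largest circular distance between corresponding region
#' boundaries, so a boundary represented as `n - 1` in one structure and
#' `-1` (wrapped) in the other counts as a 2 bp deviation, not `n`.
#'
#' @param a,b Two [plastome_structure()] objects of equal genome length.
#' @return The maximum boundary distance in bp.
#' @export
max_boundary_deviation <- function(a, b) {
  stopifnot(a$genome_length == b$genome_length)
  n <- a$genome_length
  d <- c(circ_dist(a$regions$start, b$regions$start, n),
         circ_dist(a$regions$end, b$regions$end, n))
  max(d)
}

#' Resolve structure directly from a sequence
#'
#' Convenience wrapper: repeat search plus quadripartite resolution.
#'
#' @inheritParams resolve_quadripartite
#' @inheritParams find_inverted_repeats
#' @param params [structure_params()].
#' @return A [plastome_structure()].
#' @export
resolve_structure <- function(seq, params = structure_params(),
                              reference = NULL, ref_structure = NULL) {
  reps <- find_inverted_repeats(seq, min_length = params$min_length,
                                min_identity = params$min_identity,
                                k = params$k)
  resolve_quadripartite(seq, reps, reference = reference,
                        ref_structure = ref_structure, params = params)
}
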