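# Standardization: canonical LSC-IRb-SSC-IRa representation oriented
# against a reference, and selection among flip-flop isomer candidates.

mirror_interval <- function(iv, n) {
  s <- iv[1L]; e <- iv[2L]; l <- e - s
  ns <- ((n - (e %% n)) %% n + n) %% n
  c(ns, ns + l)
}

# Structure of the reverse-complemented molecule, derived arithmetically:
# LSC and SSC map to themselves, IRb and IRa swap roles.
mirror_structure <- function(structure) {
  n <- structure$genome_length
  plastome_structure(mirror_interval(region_interval(structure, "lsc"), n),
                     mirror_interval(region_interval(structure, "ira"), n),
                     mirror_interval(region_interval(structure, "ssc"), n),
                     mirror_interval(region_interval(structure, "irb"), n), n)
}

canonical_structure <- function(structure) {
  r <- structure$regions
  l <- r$length
  plastome_structure(c(0L, l[1L]), c(l[1L], l[1L] + l[2L]),
                     c(l[1L] + l[2L], l[1L] + l[2L] + l[3L]),
                     c(l[1L] + l[2L] + l[3L], sum(l)),
                     structure$genome_length)
}

#' Canonicalize a circular assembly
#'
#' Rotates and/or reverse-complements the molecule so that the linear
#' string begins at LSC base 1 with region order LSC-IRb-SSC-IRa.  Between
#' the two strand choices the one whose LSC aligns to the reference LSC
#' with higher identity wins; the SSC is then independently flipped in
#' place if its reverse complement matches the reference SSC better
#' (flip-flop isomer resolution).  Provenance records every transformation
#' applied.
#'
#' @param seq The candidate [circular_sequence()] (or [seq_record()]).
#' @param structure Its resolved [plastome_structure()] (resolved on demand
#'   when `NULL`).
#' @param reference A `reference_annotation` from [read_genbank()].
#' @param ref_structure Optional pre-resolved reference structure.
#' @param params [structure_params()] for any on-demand resolution.
#' @return An object of class `standardized_assembly`: `sequence`
#'   (linearized [seq_record()] starting at LSC base 1), `structure`
#'   (recomputed on the standardized string) and `provenance` (chosen
#'   rotation offset, whole-molecule flip flag, SSC flip flag, corrected
#'   positions).
#' @export
canonicalize <- function(seq, structure = NULL, reference,
                         ref_structure = NULL, params = structure_params()) {
  b <- as_bases(seq)
  n <- nchar(b)
  if (is.null(structure)) structure <- resolve_structure(seq, params)
  if (is.null(ref_structure)) {
    ref_structure <- tryCatch(resolve_reference_structure(reference, params),
                              error = function(e) NULL)
  }
  if (is.null(ref_structure)) {
    warn("reference structure unresolvable; falling back to whole-molecule orientation")
    return(orient_to_reference(seq, reference))
  }
  ref_lsc <- region_sequence(reference$sequence, ref_structure, "lsc")
  ref_ssc <- region_sequence(reference$sequence, ref_structure, "ssc")

  rb <- reverse_complement(b)
  rstructure <- mirror_structure(structure)

  lsc_f <- region_interval(structure, "lsc")
  lsc_r <- region_interval(rstructure, "lsc")
  cand_f <- rotate_bases(b, lsc_f[1L] %% n)
  cand_r <- rotate_bases(rb, lsc_r[1L] %% n)
  id_f <- alignment_identity(substr(cand_f, 1L, lsc_f[2L] - lsc_f[1L]), ref_lsc)
  # a perfect forward LSC cannot be beaten (ties keep the forward strand)
  id_r <- if (id_f == 1) 0 else
    alignment_identity(substr(cand_r, 1L, lsc_r[2L] - lsc_r[1L]), ref_lsc)

  flipped <- id_r > id_f
  if (flipped) {
    canon <- cand_r
    rotation <- lsc_r[1L] %% n
    cstruct <- canonical_structure(rstructure)
  } else {
    canon <- cand_f
    rotation <- lsc_f[1L] %% n
    cstruct <- canonical_structure(structure)
  }

  ssc_iv <- region_interval(cstruct, "ssc")
  ssc_seq <- substr(canon, ssc_iv[1L] + 1L, ssc_iv[2L])
  ssc_flipped <- FALSE
  if (nzchar(ssc_seq)) {
    id_keep <- alignment_identity(ssc_seq, ref_ssc)
    id_flip <- if (id_keep == 1) 0 else
      alignment_identity(reverse_complement(ssc_seq), ref_ssc)
    if (id_flip > id_keep) {
      canon <- splice_revcomp(canon, ssc_iv[1L], ssc_iv[2L] - ssc_iv[1L])
      ssc_flipped <- TRUE
    }
  }

  structure(list(
    sequence = seq_record(seq_id(seq), canon),
    structure = cstruct,
    provenance = list(candidate_index = attr(seq, "candidate_index") %||% NA_integer_,
                      rotation = as.integer(rotation),
                      flipped = flipped,
                      ssc_flipped = ssc_flipped,
                      corrected_positions = integer(0),
                      fallback = FALSE)),
    class = "standardized_assembly")
}

#' @export
print.standardized_assembly <- function(x, ...) {
  p <- x$provenance
  cat(sprintf("<standardized_assembly> %s (%d bp)\n", x$sequence$id,
              nchar(x$sequence$bases)))
  cat(sprintf("  rotation %d, flipped %s, SSC flipped %s\n",
              p$rotation, p$flipped, p$ssc_flipped))
  invisible(x)
}

# Fallback when the reference (or target) has no resolvable quadripartite
# structure: orient the whole molecule by the best-matching rotation/strand
# of the reference's leading sequence.
orient_to_reference <- function(seq, reference, probe_len = 200L) {
  b <- as_bases(seq)
  n <- nchar(b)
  probe <- substr(as_bases(reference$sequence), 1L,
                  min(probe_len, nchar(as_bases(reference$sequence))))
  D <- Biostrings::DNAString(paste0(b, b))
  find_hit <- function(pat) {
    for (mm in unique(c(0L, ceiling(0.05 * nchar(pat)),
                        ceiling(0.15 * nchar(pat))))) {
      m <- Biostrings::matchPattern(pat, D, max.mismatch = mm,
                                    with.indels = mm > 0L)
      if (length(m)) return(Biostrings::start(m)[1L] - 1L)
    }
    NULL
  }
  hit_f <- find_hit(probe)
  if (!is.null(hit_f)) {
    canon <- rotate_bases(b, hit_f %% n)
    flipped <- FALSE; rotation <- hit_f %% n
  } else {
    rb <- reverse_complement(b)
    D <- Biostrings::DNAString(paste0(rb, rb))
    hit_r <- find_hit(probe)
    if (is.null(hit_r)) {
      abort("could not orient the assembly against the reference",
            class = "plastr_orientation_failed")
    }
    canon <- rotate_bases(rb, hit_r %% n)
    flipped <- TRUE; rotation <- hit_r %% n
  }
  structure(list(
    sequence = seq_record(seq_id(seq), canon),
    structure = NULL,
    provenance = list(candidate_index = NA_integer_,
                      rotation = as.integer(rotation), flipped = flipped,
                      ssc_flipped = FALSE, corrected_positions = integer(0),
                      fallback = TRUE)),
    class = "standardized_assembly")
}

#' Select among assembler candidate isomers
#'
#' A single candidate is returned unchanged.  With two candidates (the
#' assembler's Option 1/Option 2, differing in SSC orientation), each is
#' structure-resolved, its SSC compared with the reference SSC, and the
#' candidate whose native SSC orientation matches the reference (higher
#' forward identity) is returned.  The choice is order-independent.
#'
#' @param candidates A list of 1 or 2 [seq_record()]/[circular_sequence()]
#'   objects.
#' @param reference A `reference_annotation`.
#' @param ref_structure Optional pre-resolved reference structure.
#' @param params [structure_params()].
#' @return The selected candidate, with attribute `candidate_index`.
#' @export
select_candidate <- function(candidates, reference, ref_structure = NULL,
                             params = structure_params()) {
  if (inherits(candidates, "seq_record")) candidates <- list(candidates)
  nc <- length(candidates)
  if (nc < 1L || nc > 2L) {
    abort(sprintf("expected 1 or 2 candidates, got %d", nc),
          class = "plastr_candidate_overflow")
  }
  if (nc == 1L) {
    out <- candidates[[1L]]
    attr(out, "candidate_index") <- 1L
    return(out)
  }
  if (is.null(ref_structure)) {
    ref_structure <- resolve_reference_structure(reference, params)
  }
  ref_ssc <- region_sequence(reference$sequence, ref_structure, "ssc")
  scores <- vapply(candidates, function(cand) {
    st <- tryCatch(resolve_structure(cand, params), error = function(e) NULL)
    if (is.null(st)) return(NA_real_)
    alignment_identity(region_sequence(cand, st, "ssc"), ref_ssc)
  }, numeric(1L))
  if (all(is.na(scores))) {
    abort(sprintf("no candidate has a resolvable structure: %s",
                  paste(vapply(candidates, seq_id, character(1L)),
                        collapse = ", ")),
          class = "plastr_no_quadripartite")
  }
  idx <- which.max(scores)
  out <- candidates[[idx]]
  attr(out, "candidate_index") <- idx
  out
}
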