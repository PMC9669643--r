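# Pairwise identity used by every orientation decision: fraction of
# matching columns in a gap-tolerant global alignment (unit match/mismatch
# costs, linear gaps).  Ambiguity codes match only themselves, so Ns never
# inflate identity.

unit_submat <- function() {
  if (is.null(.plastr_env$submat)) {
    .plastr_env$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  }
  .plastr_env$submat
}

.plastr_env <- new.env(parent = emptyenv())

#' Global alignment identity of two segments
#'
#' @param x,y Nucleotide strings (or sequence records).
#' @return Matching columns / total alignment columns, in `[0, 1]`.
#' @export
alignment_identity <- function(x, y) {
  x <- as_bases(x); y <- as_bases(y)
  if (x == y) return(1)
  if (!nzchar(x) || !nzchar(y)) return(0)
  aln <- Biostrings::pairwiseAlignment(
    x, y, type = "global", substitutionMatrix = unit_submat(),
    gapOpening = 0, gapExtension = 1)
  pa <- base_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- base_chars(as.character(Biostrings::alignedSubject(aln)))
  mean(pa == sa & pa != "-")
}
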