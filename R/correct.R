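# Read-based correction of ambiguous (non-ACGT) bases.  Reads are anchored
# by exact k-mer flank matches on either side of the ambiguous position
# (both strands considered), votes from both flanks are pooled, and the
# base is replaced only under sufficient depth and a clear majority.

#' Correct ambiguous bases from reads
#'
#' For every non-ACGT position, reads are anchored by an exact match of the
#' k-mer immediately left or right of the position (each read is searched
#' on both strands), the anchored reads vote on the base, and the position
#' is rewritten when at least `min_depth` votes were collected and the
#' modal base reaches `min_majority` of them; otherwise the base is left
#' unchanged and a warning is recorded in the report.  Positions already in
#' ACGT are never touched.
#'
#' @param seq A [seq_record()] (possibly containing Ns or other IUPAC
#'   ambiguity codes); treated as circular for flank extraction.
#' @param reads Read sequences: a character vector, a tibble from
#'   [read_fastq()], or a list of such tibbles (e.g. both mates).
#' @param k Anchor flank length (default 21).
#' @param min_depth Minimum number of votes to act (default 5).
#' @param min_majority Minimum modal-base fraction to act (default 0.7).
#' @return A list with `sequence` (corrected [seq_record()]) and `report`,
#'   a tibble with one row per ambiguous position: `position` (1-based),
#'   `original`, `depth`, `votes` (e.g. `"A:6 G:4"`), `action`
#'   (`"corrected"`/`"unchanged"`), `new_base`.
#' @export
correct_ambiguous <- function(seq, reads, k = 21L, min_depth = 5L,
                              min_majority = 0.7) {
  b <- as_bases(seq)
  n <- nchar(b)
  reads <- normalize_reads(reads)
  amb <- gregexpr("[^ACGT]", b)[[1L]]
  report <- tibble(position = integer(0), original = character(0),
                   depth = integer(0), votes = character(0),
                   action = character(0), new_base = character(0))
  if (amb[1L] == -1L) {
    return(list(sequence = seq_record(seq_id(seq), b,
                                      if (inherits(seq, "seq_record")) seq$description else ""),
                report = report))
  }
  pool <- c(reads, reverse_complement(reads))
  chars <- base_chars(b)
  rows <- vector("list", length(amb))
  for (ix in seq_along(amb)) {
    p1 <- amb[ix]                 # 1-based ambiguous position
    p0 <- p1 - 1L
    left <- circ_substr(b, p0 - k, k)
    right <- circ_substr(b, p1, k)
    votes <- character(0)
    if (!grepl("[^ACGT]", left)) {
      m <- regexpr(left, pool, fixed = TRUE)
      hit <- which(m > 0L)
      vp <- m[hit] + k
      v <- substring(pool[hit], vp, vp)
      votes <- c(votes, v[v %in% c("A", "C", "G", "T")])
    }
    if (!grepl("[^ACGT]", right)) {
      m <- regexpr(right, pool, fixed = TRUE)
      hit <- which(m > 0L)
      vp <- m[hit] - 1L
      keep <- vp >= 1L
      v <- substring(pool[hit][keep], vp[keep], vp[keep])
      votes <- c(votes, v[v %in% c("A", "C", "G", "T")])
    }
    tab <- sort(table(votes), decreasing = TRUE)
    depth <- length(votes)
    vote_str <- if (depth) paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                                 collapse = " ") else ""
    if (depth >= min_depth && length(tab) &&
        tab[1L] / depth >= min_majority) {
      chars[p1] <- names(tab)[1L]
      act <- "corrected"; newb <- names(tab)[1L]
    } else {
      warn(sprintf("position %d: ambiguous base '%s' left unchanged (depth %d%s)",
                   p1, substr(b, p1, p1), depth,
                   if (depth) sprintf(", votes %s", vote_str) else ""))
      act <- "unchanged"; newb <- substr(b, p1, p1)
    }
    rows[[ix]] <- tibble(position = p1, original = substr(b, p1, p1),
                         depth = depth, votes = vote_str,
                         action = act, new_base = newb)
  }
  report <- do.call(rbind, rows)
  corrected <- paste(chars, collapse = "")
  list(sequence = seq_record(seq_id(seq), corrected,
                             if (inherits(seq, "seq_record")) seq$description else ""),
       report = report)
}

normalize_reads <- function(reads) {
  if (is.data.frame(reads)) return(toupper(reads$seq))
  if (is.list(reads)) {
    return(unlist(lapply(reads, normalize_reads), use.names = FALSE))
  }
  if (is.character(reads)) return(toupper(reads))
  abort("`reads` must be a character vector, a read tibble, or a list of them")
}
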