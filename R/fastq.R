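# FASTQ reading and writing (plain or gzip, 4-line records).
#
# Qualities are carried through but not interpreted: ambiguous-base
# correction uses base votes, not quality scores.

open_text <- function(path, mode = "rt") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a FASTQ file
#'
#' Transparent to gzip compression.  Each record must have matching sequence
#' and quality lengths.
#'
#' @param path Path to a `.fastq` or `.fastq.gz` file.
#' @return A tibble with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4L != 0L) {
    abort(sprintf("%s: truncated FASTQ (line count not a multiple of 4)", path),
          class = "plastr_format_error")
  }
  idx <- seq(1L, length(lines), by = 4L)
  ids <- sub("^@", "", lines[idx])
  ids <- sub("\\s.*$", "", ids)
  seqs <- toupper(lines[idx + 1L])
  quals <- lines[idx + 3L]
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    abort(sprintf("%s: line %d: sequence and quality lengths differ",
                  path, idx[bad[1L]] + 1L),
          class = "plastr_format_error")
  }
  tibble(id = ids, seq = seqs, qual = quals)
}

#' Write a FASTQ file
#'
#' @param reads Tibble with columns `id`, `seq`, `qual` (as from
#'   [read_fastq()] or [simulate_reads()]).
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  con <- open_text(path, "wt")
  on.exit(close(con))
  out <- rbind(paste0("@", reads$id), reads$seq,
               rep("+", nrow(reads)), reads$qual)
  writeLines(as.vector(out), con)
  invisible(path)
}
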