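# FASTA reading and writing.
#
# The reader gives line-numbered diagnostics and uppercases bases; the writer
# wraps at a fixed width so that read_fasta(write_fasta(x)) reproduces ids
# and bases exactly and a second write is byte-identical.

#' Read a FASTA file
#'
#' @param path Path to a FASTA file.
#' @return A list of [seq_record()] objects, one per header, with bases
#'   uppercased and line wrapping removed.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*$", lines) | cumsum(grepl("^>", lines)) > 0]
  hdr <- grep("^>", lines)
  if (length(hdr) == 0L || length(lines) == 0L) {
    abort(sprintf("%s: not a FASTA file (no '>' header found)", path),
          class = "plastr_format_error")
  }
  if (hdr[1L] != 1L) {
    abort(sprintf("%s: line 1: sequence data before the first header", path),
          class = "plastr_format_error")
  }
  ends <- c(hdr[-1L] - 1L, length(lines))
  records <- vector("list", length(hdr))
  for (i in seq_along(hdr)) {
    header <- sub("^>", "", lines[hdr[i]])
    id <- sub("\\s.*$", "", header)
    desc <- if (grepl("\\s", header)) sub("^\\S+\\s+", "", header) else ""
    body <- lines[seq(hdr[i] + 1L, length.out = ends[i] - hdr[i])]
    body <- gsub("\\s", "", body)
    bases <- toupper(paste(body, collapse = ""))
    if (!nzchar(bases)) {
      abort(sprintf("%s: line %d: record '%s' has an empty sequence",
                    path, hdr[i], id),
            class = "plastr_format_error")
    }
    bad <- regexpr(sprintf("[^%s]", IUPAC_CHARS), bases)
    if (bad > 0L) {
      # recover the offending line for the diagnostic
      off <- cumsum(nchar(body))
      line_in_body <- which(off >= bad)[1L]
      abort(sprintf("%s: line %d: non-IUPAC character in record '%s'",
                    path, hdr[i] + line_in_body, id),
            class = "plastr_format_error")
    }
    records[[i]] <- seq_record(id, bases, desc)
  }
  records
}

#' Write a FASTA file
#'
#' @param records A [seq_record()] or a list of them.
#' @param path Output path.
#' @param width Line-wrap width for the sequence (default 70).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  if (inherits(records, "seq_record")) records <- list(records)
  if (length(records) == 0L) abort("no records to write")
  out <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description %||% "")) {
      paste0(">", r$id, " ", r$description)
    } else {
      paste0(">", r$id)
    }
    n <- nchar(r$bases)
    starts <- seq(1L, n, by = width)
    c(header, substring(r$bases, starts, pmin(starts + width - 1L, n)))
  }))
  writeLines(out, path)
  invisible(path)
}
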