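# NCBI 5-column feature table (.tbl) output, the format consumed by
# BankIt/table2asn for GenBank submission.  Only gene-level feature keys
# (gene, CDS, tRNA, rRNA) are emitted; introns are implicit in submission
# tables, so derived exon/intron features are skipped.

TBL_KEYS <- c("gene", "CDS", "tRNA", "rRNA")

#' Write an NCBI feature table (.tbl)
#'
#' The first line is `>Feature <seqid>`; each feature contributes one
#' tab-separated `start<TAB>end<TAB>key` line for its first interval,
#' `start<TAB>end` continuation lines for further intervals, and
#' `<TAB><TAB><TAB>name<TAB>value` qualifier lines.  Coordinates are
#' 1-based inclusive; minus-strand intervals are written with start > end.
#'
#' @param x An [annotation_set][build_annotation()] or `reference_annotation`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  p <- gb_parts(x)
  if (is.null(p$rec$id) || !nzchar(p$rec$id)) {
    abort("annotation has no sequence id")
  }
  out <- sprintf(">Feature %s", p$rec$id)
  for (f in p$features) {
    if (!f$key %in% TBL_KEYS) next
    seg <- f$segments
    if (nrow(seg) == 0L) {
      abort(sprintf("feature '%s' has zero segments", feature_name(f)))
    }
    ivals <- vapply(seq_len(nrow(seg)), function(i) {
      s1 <- seg$start[i] + 1L; e1 <- seg$end[i]
      if (seg$strand[i] == "-") sprintf("%d\t%d", e1, s1)
      else sprintf("%d\t%d", s1, e1)
    }, character(1L))
    out <- c(out, paste0(ivals[1L], "\t", f$key))
    if (length(ivals) > 1L) out <- c(out, ivals[-1L])
    for (i in seq_along(f$qualifiers)) {
      v <- f$qualifiers[[i]]
      out <- c(out, sprintf("\t\t\t%s\t%s", names(f$qualifiers)[i],
                            if (is.na(v)) "" else v))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Read back an NCBI feature table
#'
#' Inverse of [write_feature_table()]; used for round-trip checks.
#'
#' @param path Path to a `.tbl` file.
#' @return A list with `seqid` and a list of features (key, segments,
#'   qualifiers) in 0-based half-open coordinates.
#' @export
read_feature_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !startsWith(lines[1L], ">Feature ")) {
    abort(sprintf("%s: missing '>Feature' header", path),
          class = "plastr_format_error")
  }
  seqid <- sub("^>Feature ", "", lines[1L])
  features <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) features[[length(features) + 1L]] <<- cur
  for (ln in lines[-1L]) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) >= 3L && nzchar(f[1L])) {            # new feature
      flush()
      s <- as.integer(f[1L]); e <- as.integer(f[2L])
      seg <- if (s <= e) data.frame(start = s - 1L, end = e, strand = "+")
      else data.frame(start = e - 1L, end = s, strand = "-")
      cur <- list(key = f[3L], segments = seg, qualifiers = character(0))
    } else if (length(f) == 2L && nzchar(f[1L])) {      # continuation interval
      s <- as.integer(f[1L]); e <- as.integer(f[2L])
      seg <- if (s <= e) data.frame(start = s - 1L, end = e, strand = "+")
      else data.frame(start = e - 1L, end = s, strand = "-")
      cur$segments <- rbind(cur$segments, seg)
    } else if (length(f) >= 4L) {                       # qualifier
      v <- if (length(f) >= 5L) f[5L] else ""
      cur$qualifiers <- c(cur$qualifiers, setNames(v, f[4L]))
    }
  }
  flush()
  list(seqid = seqid, features = features)
}
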