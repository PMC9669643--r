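# GenBank flat-file parsing and writing.
#
# A feature is a list(key, qualifiers, segments, operator) where `segments`
# is a data.frame(start, end, strand) in 0-based half-open coordinates, in
# the order listed in the file, and `operator` is NA, "join" or "order".
# Conversion to/from the 1-based inclusive GenBank convention happens only
# here.  Qualifier values are stored unquoted; purely numeric values are
# re-emitted unquoted, flags (no value) as bare /name.

new_feature <- function(key, segments, qualifiers = character(0),
                        operator = NA_character_) {
  stopifnot(is.data.frame(segments),
            all(c("start", "end", "strand") %in% names(segments)))
  list(key = key, qualifiers = qualifiers,
       segments = segments, operator = operator)
}

qual_get <- function(quals, name) {
  if (!is.null(quals) && name %in% names(quals)) unname(quals[[name]]) else NULL
}

feature_name <- function(f) {
  qual_get(f$qualifiers, "gene") %||% qual_get(f$qualifiers, "product") %||% f$key
}

feature_span <- function(f) c(min(f$segments$start), max(f$segments$end))

# Segments in biological (transcription) order.  GenBank writes a
# minus-strand multi-exon gene as complement(join(...)) with ascending
# coordinates, i.e. the listed order is the reverse of the reading order;
# order() locations (trans-spliced genes) are already in reading order.
segments_bio <- function(f) {
  seg <- f$segments
  if (!is.na(f$operator) && f$operator == "join" &&
      nrow(seg) > 1L && all(seg$strand == "-")) {
    seg <- seg[rev(seq_len(nrow(seg))), , drop = FALSE]
    rownames(seg) <- NULL
  }
  seg
}

is_trans_spliced <- function(f) {
  (!is.na(f$operator) && f$operator == "order") ||
    length(unique(f$segments$strand)) > 1L
}

## ---- location grammar -----------------------------------------------------

# Split "a,b,c" at top-level commas (not inside parentheses).
split_top_commas <- function(txt) {
  chars <- strsplit(txt, "", fixed = TRUE)[[1L]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0L)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  vapply(seq_along(starts), function(i)
    paste(chars[starts[i]:ends[i]], collapse = ""), character(1L))
}

parse_location <- function(txt, strand = "+") {
  txt <- gsub("\\s", "", txt)
  flip <- function(s) if (s == "+") "-" else "+"
  if (grepl("^complement\\(.*\\)$", txt)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", txt)
    return(parse_location(inner, flip(strand)))
  }
  if (grepl("^(join|order)\\(.*\\)$", txt)) {
    op <- sub("^(join|order)\\(.*", "\\1", txt)
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", txt)
    parts <- lapply(split_top_commas(inner), parse_location, strand = strand)
    segs <- do.call(rbind, lapply(parts, `[[`, "segments"))
    rownames(segs) <- NULL
    return(list(segments = segs, operator = op))
  }
  plain <- gsub("[<>]", "", txt)
  if (grepl("^[0-9]+\\.\\.[0-9]+$", plain)) {
    se <- as.integer(strsplit(plain, "..", fixed = TRUE)[[1L]])
    return(list(segments = data.frame(start = se[1L] - 1L, end = se[2L],
                                      strand = strand),
                operator = NA_character_))
  }
  if (grepl("^[0-9]+$", plain)) {
    p <- as.integer(plain)
    return(list(segments = data.frame(start = p - 1L, end = p, strand = strand),
                operator = NA_character_))
  }
  abort(sprintf("unparseable location '%s'", txt),
        class = "plastr_format_error")
}

format_location <- function(f) {
  seg <- f$segments
  one <- function(i) sprintf("%d..%d", seg$start[i] + 1L, seg$end[i])
  if (nrow(seg) == 1L) {
    loc <- one(1L)
    if (seg$strand[1L] == "-") loc <- sprintf("complement(%s)", loc)
    return(loc)
  }
  op <- if (!is.na(f$operator)) f$operator else "join"
  if (op == "join" && all(seg$strand == "-")) {
    return(sprintf("complement(join(%s))",
                   paste(vapply(seq_len(nrow(seg)), one, character(1L)),
                         collapse = ",")))
  }
  parts <- vapply(seq_len(nrow(seg)), function(i) {
    if (seg$strand[i] == "-") sprintf("complement(%s)", one(i)) else one(i)
  }, character(1L))
  sprintf("%s(%s)", op, paste(parts, collapse = ","))
}

## ---- reader ----------------------------------------------------------------

#' Read a GenBank flat file
#'
#' Parses LOCUS, the FEATURES table (location grammar: `n..m`, `join(...)`,
#' `order(...)`, `complement(...)` with nesting) and ORIGIN.  Coordinates
#' are converted to the internal 0-based half-open convention; the listed
#' segment order of compound locations is preserved.
#'
#' @param path Path to a GenBank flat file.
#' @return An object of class `reference_annotation`: a list with elements
#'   `sequence` (a [seq_record()]), `features` (list of features), and
#'   `source_metadata` (locus name, topology, organism).
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  lines <- readLines(path, warn = FALSE)
  locus_i <- grep("^LOCUS", lines)
  origin_i <- grep("^ORIGIN", lines)
  feat_i <- grep("^FEATURES", lines)
  if (length(origin_i) == 0L) {
    abort(sprintf("%s: missing ORIGIN section", path),
          class = "plastr_format_error")
  }
  locus_name <- "unknown"
  topology <- "linear"
  if (length(locus_i)) {
    toks <- strsplit(trimws(lines[locus_i[1L]]), "\\s+")[[1L]]
    if (length(toks) >= 2L) locus_name <- toks[2L]
    if (any(toks == "circular")) topology <- "circular"
  }

  # sequence
  seq_lines <- lines[seq(origin_i[1L] + 1L, length(lines))]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  bases <- toupper(gsub("[0-9 ]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(bases)) {
    abort(sprintf("%s: empty ORIGIN sequence", path),
          class = "plastr_format_error")
  }

  # features
  features <- list()
  organism <- ""
  if (length(feat_i)) {
    flines <- lines[seq(feat_i[1L] + 1L, origin_i[1L] - 1L)]
    cur_key <- NULL; cur_loc <- NULL; cur_quals <- list()
    open_qual <- NULL; open_val <- NULL; open_quoted <- FALSE
    flush_qual <- function() {
      if (!is.null(open_qual)) {
        cur_quals[[length(cur_quals) + 1L]] <<- c(open_qual, open_val)
        open_qual <<- NULL; open_val <<- NULL; open_quoted <<- FALSE
      }
    }
    flush_feature <- function(line_no) {
      flush_qual()
      if (is.null(cur_key)) return()
      loc <- tryCatch(parse_location(cur_loc), error = function(e) {
        abort(sprintf("%s: feature '%s': %s", path, cur_key,
                      conditionMessage(e)), class = "plastr_format_error")
      })
      q <- setNames(vapply(cur_quals, function(x)
        if (length(x) > 1L) x[2L] else NA_character_, character(1L)),
        vapply(cur_quals, `[[`, character(1L), 1L))
      features[[length(features) + 1L]] <<-
        new_feature(cur_key, loc$segments, q, loc$operator)
      cur_key <<- NULL; cur_loc <<- NULL; cur_quals <<- list()
    }
    for (ln in flines) {
      if (!nzchar(trimws(ln))) next
      key <- trimws(substr(ln, 1L, 20L))
      rest <- trimws(substr(ln, 21L, nchar(ln)))
      if (nzchar(key)) {
        flush_feature()
        cur_key <- key
        cur_loc <- rest
      } else if (startsWith(rest, "/") && !open_quoted) {
        flush_qual()
        m <- regmatches(rest, regexec("^/([^=]+)(=(.*))?$", rest))[[1L]]
        open_qual <- m[2L]
        val <- m[4L]
        if (is.na(val) || !nzchar(m[3L])) {
          open_val <- NULL; flush_qual()
        } else if (startsWith(val, "\"")) {
          body <- sub("^\"", "", val)
          if (grepl("\"$", body) && nchar(val) > 1L) {
            open_val <- sub("\"$", "", body); flush_qual()
          } else {
            open_val <- body; open_quoted <- TRUE
          }
        } else {
          open_val <- val; flush_qual()
        }
      } else if (open_quoted) {
        if (grepl("\"$", rest)) {
          open_val <- paste(open_val, sub("\"$", "", rest))
          flush_qual()
        } else {
          open_val <- paste(open_val, rest)
        }
      } else if (!is.null(cur_key) && is.null(open_qual) &&
                 length(cur_quals) == 0L) {
        cur_loc <- paste0(cur_loc, rest)  # wrapped location
      }
    }
    flush_feature()
    src <- Filter(function(f) f$key == "source", features)
    if (length(src)) organism <- qual_get(src[[1L]]$qualifiers, "organism") %||% ""
    features <- Filter(function(f) f$key != "source", features)
  }

  rec <- seq_record(locus_name, bases)
  for (f in features) {
    if (any(f$segments$start < 0L | f$segments$end > nchar(bases))) {
      abort(sprintf("%s: feature '%s' (%s) outside [1, %d]",
                    path, f$key, feature_name(f), nchar(bases)),
            class = "plastr_format_error")
    }
  }
  structure(list(sequence = rec, features = features,
                 source_metadata = list(locus = locus_name,
                                        topology = topology,
                                        organism = organism)),
            class = "reference_annotation")
}

#' @export
print.reference_annotation <- function(x, ...) {
  cat(sprintf("<reference_annotation> %s: %d bp (%s), %d features\n",
              x$sequence$id, nchar(x$sequence$bases),
              x$source_metadata$topology, length(x$features)))
  invisible(x)
}

## ---- writer ----------------------------------------------------------------

# Normalize a reference_annotation or annotation_set to (record, features,
# metadata) for writing.
gb_parts <- function(x) {
  if (inherits(x, "reference_annotation")) {
    list(rec = x$sequence, features = x$features, meta = x$source_metadata)
  } else if (inherits(x, "annotation_set")) {
    list(rec = x$sequence, features = x$features,
         meta = list(locus = x$sequence$id, topology = "circular",
                     organism = x$organism %||% ""))
  } else {
    abort("expected a reference_annotation or annotation_set")
  }
}

#' Write a GenBank flat file
#'
#' Emits LOCUS (length, DNA, circular), the FEATURES table (including any
#' exon/intron features present) and a 60-column ORIGIN block.  Reading the
#' output back reproduces all feature keys, segments, strands and
#' qualifiers, and a second write is byte-identical.
#'
#' @param x A `reference_annotation` or [annotation_set][build_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(x, path) {
  p <- gb_parts(x)
  n <- nchar(p$rec$bases)
  for (f in p$features) {
    if (any(f$segments$start < 0L | f$segments$end > n)) {
      abort(sprintf("feature '%s' (%s) has a segment outside [1, %d]",
                    f$key, feature_name(f), n),
            class = "plastr_out_of_bounds")
    }
  }
  out <- character(0)
  topo <- p$meta$topology %||% "circular"
  out <- c(out, sprintf("LOCUS       %-16s %d bp    DNA     %s PLN",
                        p$rec$id, n, topo))
  out <- c(out, sprintf("DEFINITION  %s.",
                        if (nzchar(p$meta$organism %||% "")) p$meta$organism
                        else p$rec$id))
  out <- c(out, "FEATURES             Location/Qualifiers")
  emit_feature <- function(key, loc, quals) {
    lines <- sprintf("     %-16s%s", key, loc)
    for (i in seq_along(quals)) {
      nm <- names(quals)[i]; v <- quals[[i]]
      q <- if (is.na(v)) sprintf("/%s", nm)
      else if (grepl("^[0-9]+$", v)) sprintf("/%s=%s", nm, v)
      else sprintf("/%s=\"%s\"", nm, v)
      lines <- c(lines, paste0(strrep(" ", 21L), q))
    }
    lines
  }
  out <- c(out, emit_feature("source", sprintf("1..%d", n),
                             c(organism = p$meta$organism %||% p$rec$id,
                               mol_type = "genomic DNA")))
  for (f in p$features) {
    out <- c(out, emit_feature(f$key, format_location(f), f$qualifiers))
  }
  out <- c(out, "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    block <- substr(p$rec$bases, s, min(s + 59L, n))
    groups <- substring(block, seq(1L, nchar(block), by = 10L),
                        pmin(seq(10L, nchar(block) + 9L, by = 10L),
                             nchar(block)))
    out <- c(out, sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))))
  }
  out <- c(out, "//")
  writeLines(out, path)
  invisible(path)
}
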