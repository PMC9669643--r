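# Reference-based annotation transfer: extract feature templates from the
# reference, map each template's segments onto the target with a
# multi-round decreasing-identity schedule, rebuild gene models (introns,
# exons, trans-spliced genes), and QC coding features for internal stops.

GENE_CHILD_KEYS <- c("CDS", "tRNA", "rRNA")

#' Default mapping rounds
#'
#' Three rounds of decreasing identity (and coverage) thresholds; later
#' rounds rescue templates that diverged too far for earlier ones.
#'
#' @return A tibble with columns `identity` and `coverage`, one row per round.
#' @export
default_rounds <- function() {
  tibble(identity = c(0.98, 0.90, 0.80), coverage = c(1.00, 0.95, 0.90))
}

#' Extract feature templates from a reference annotation
#'
#' One template per gene-level feature: CDS/tRNA/rRNA features keep their
#' own exon structure (converted to transcription order), gene features
#' without children are carried as plain genes, and each IR-duplicated
#' gene copy yields its own template.  Segment sequences are extracted
#' with strand applied, so every template stores the sense sequence of
#' each exon.  A CDS without a parent gene is synthesized into a template
#' with a warning.
#'
#' @param ref A `reference_annotation` from [read_genbank()].
#' @return A list of feature templates: each a list with `key`, `name`,
#'   `qualifiers`, `segments` (transcription order), `trans_spliced`,
#'   `segment_sequences`, and `ref_start`.
#' @export
extract_reference_features <- function(ref) {
  feats <- ref$features
  bases <- as_bases(ref$sequence)
  keys <- vapply(feats, `[[`, character(1L), "key")
  gene_ix <- which(keys == "gene")
  child_ix <- which(keys %in% GENE_CHILD_KEYS)
  child_used <- logical(length(feats))

  overlap_len <- function(a, b) max(0L, min(a[2L], b[2L]) - max(a[1L], b[1L]))

  make_template <- function(f, extra_quals = character(0)) {
    seg <- segments_bio(f)
    seqs <- vapply(seq_len(nrow(seg)), function(i) {
      s <- substr(bases, seg$start[i] + 1L, seg$end[i])
      if (seg$strand[i] == "-") reverse_complement(s) else s
    }, character(1L))
    quals <- f$qualifiers
    for (nm in setdiff(names(extra_quals), names(quals))) {
      quals[nm] <- extra_quals[[nm]]
    }
    list(key = f$key,
         name = feature_name(f),
         qualifiers = quals,
         segments = seg,
         trans_spliced = is_trans_spliced(f),
         segment_sequences = seqs,
         ref_start = min(f$segments$start))
  }

  templates <- list()
  for (g in gene_ix) {
    gf <- feats[[g]]
    gname <- feature_name(gf)
    gspan <- feature_span(gf)
    cands <- child_ix[!child_used[child_ix]]
    cands <- cands[vapply(cands, function(ci) {
      identical(feature_name(feats[[ci]]), gname) &&
        overlap_len(feature_span(feats[[ci]]), gspan) > 0L
    }, logical(1L))]
    if (length(cands)) {
      best <- cands[which.max(vapply(cands, function(ci)
        overlap_len(feature_span(feats[[ci]]), gspan), numeric(1L)))]
      child_used[best] <- TRUE
      templates[[length(templates) + 1L]] <-
        make_template(feats[[best]], gf$qualifiers)
    } else {
      templates[[length(templates) + 1L]] <- make_template(gf)
    }
  }
  orphan <- child_ix[!child_used[child_ix]]
  for (ci in orphan) {
    warn(sprintf("%s '%s' has no parent gene; template synthesized from the %s itself",
                 keys[ci], feature_name(feats[[ci]]), keys[ci]))
    templates[[length(templates) + 1L]] <- make_template(feats[[ci]])
  }
  templates
}

## ---- segment search --------------------------------------------------------

aln_stats <- function(query, window, win_start0) {
  aln <- Biostrings::pairwiseAlignment(
    query, window, type = "global-local",
    substitutionMatrix = unit_submat(), gapOpening = 0, gapExtension = 1)
  pa <- base_chars(as.character(Biostrings::alignedPattern(aln)))
  sa <- base_chars(as.character(Biostrings::alignedSubject(aln)))
  sub_rng <- aln@subject@range
  list(identity = mean(pa == sa & pa != "-"),
       coverage = sum(pa != "-" & sa != "-") / nchar(query),
       start0 = win_start0 + Biostrings::start(sub_rng) - 1L,
       end0 = win_start0 + Biostrings::end(sub_rng))
}

# All distinct hits of `query` (sense sequence) on the doubled target, both
# strands, within `max_mm` mismatches/indels; refined boundaries and
# identities; coordinates reduced modulo the genome length.
search_segment <- function(query, doubled, n, max_mm) {
  L <- nchar(query)
  pad <- max(5L, ceiling(0.2 * L))
  out <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") query else reverse_complement(query)
    m <- tryCatch(
      Biostrings::matchPattern(pat, doubled, max.mismatch = max_mm,
                               with.indels = max_mm > 0L),
      error = function(e) NULL)
    if (is.null(m) || length(m) == 0L) next
    for (h in seq_along(m)) {
      st <- Biostrings::start(m)[h]; en <- Biostrings::end(m)[h]
      if (max_mm == 0L) {
        stats <- list(identity = 1, coverage = 1, start0 = st - 1L, end0 = en)
      } else {
        ws <- max(1L, st - pad); we <- min(length(doubled), en + pad)
        stats <- aln_stats(pat, as.character(doubled[ws:we]), ws - 1L)
      }
      out[[length(out) + 1L]] <-
        tibble(start = stats$start0, end = stats$end0, strand = strand,
               identity = stats$identity, coverage = stats$coverage)
    }
  }
  if (!length(out)) {
    return(tibble(start = integer(0), end = integer(0), strand = character(0),
                  identity = numeric(0), coverage = numeric(0)))
  }
  hits <- do.call(rbind, out)
  hits$len <- hits$end - hits$start
  smod <- hits$start %% n
  key <- paste(smod, hits$len, hits$strand)
  hits <- hits[!duplicated(key), , drop = FALSE]
  hits$start <- hits$start %% n
  hits$end <- hits$start + hits$len
  hits$len <- NULL
  hits
}

circ_dist <- function(a, b, n) {
  d <- abs(((a - b) %% n + n) %% n)
  pmin(d, n - d)
}

#' Map reference feature templates onto a target sequence
#'
#' Each template's segments are searched independently on the doubled
#' target (both strands), so hits wrap the origin.  A segment maps in a
#' round when its best alignment reaches that round's identity and query
#' coverage; rounds are applied in order to still-unmapped templates only,
#' and a template is mapped when all of its segments are.  Among competing
#' hits for one segment (e.g. the two IR copies of a duplicated gene), the
#' hit with the highest identity x coverage wins, ties broken by
#' consistency with the rotation offset implied by unambiguously mapped
#' templates.
#'
#' @param target Target sequence ([seq_record()] or string).
#' @param templates Templates from [extract_reference_features()].
#' @param rounds Threshold schedule, as from [default_rounds()]; identities
#'   must be strictly decreasing.
#' @return A list with `mapped` (list of mapped features: `template`,
#'   `name`, `segments` tibble with per-segment identity, `round_index`)
#'   and `unmapped` (templates that failed all rounds).
#' @export
map_features <- function(target, templates, rounds = default_rounds()) {
  stopifnot(nrow(rounds) >= 1L)
  if (any(diff(rounds$identity) >= 0)) {
    abort("round identities must be strictly decreasing")
  }
  b <- as_bases(target)
  n <- nchar(b)
  doubled <- Biostrings::DNAString(paste0(b, b))

  cand <- vector("list", length(templates))   # per template: list of hit tibbles
  round_ix <- rep(NA_integer_, length(templates))
  for (r in seq_len(nrow(rounds))) {
    idr <- rounds$identity[r]; covr <- rounds$coverage[r]
    for (ti in seq_along(templates)) {
      if (!is.na(round_ix[ti])) next
      tpl <- templates[[ti]]
      seg_hits <- lapply(tpl$segment_sequences, function(q) {
        max_mm <- floor((1 - idr) * nchar(q))
        h <- search_segment(q, doubled, n, max_mm)
        h[h$identity >= idr & h$coverage >= covr, , drop = FALSE]
      })
      if (all(vapply(seg_hits, nrow, integer(1L)) > 0L)) {
        cand[[ti]] <- seg_hits
        round_ix[ti] <- r
      }
    }
  }

  # rotation-offset and orientation consensus from templates whose hits are
  # unambiguous; used to break near-ties among competing hits (the two IR
  # copies of a duplicated gene give hits whose identities differ only by
  # mutation noise)
  offsets <- integer(0)
  same_strand <- logical(0)
  for (ti in seq_along(templates)) {
    if (is.na(round_ix[ti])) next
    if (all(vapply(cand[[ti]], nrow, integer(1L)) == 1L)) {
      off <- (cand[[ti]][[1L]]$start[1L] -
                templates[[ti]]$segments$start[1L]) %% n
      offsets <- c(offsets, off)
      same_strand <- c(same_strand, cand[[ti]][[1L]]$strand[1L] ==
                         templates[[ti]]$segments$strand[1L])
    }
  }
  consensus <- if (length(offsets)) {
    as.integer(names(sort(table(offsets), decreasing = TRUE))[1L])
  } else 0L
  flip_consensus <- if (length(same_strand)) mean(same_strand) < 0.5 else FALSE
  tie_tol <- 0.02   # identity differences within mutation noise are ties

  mapped <- list()
  unmapped <- list()
  for (ti in seq_along(templates)) {
    tpl <- templates[[ti]]
    if (is.na(round_ix[ti])) {
      unmapped[[length(unmapped) + 1L]] <- tpl
      next
    }
    segs <- lapply(seq_along(cand[[ti]]), function(si) {
      h <- cand[[ti]][[si]]
      score <- h$identity * h$coverage
      h <- h[score >= max(score) - tie_tol, , drop = FALSE]
      exp_strand <- if (flip_consensus) {
        c("+" = "-", "-" = "+")[tpl$segments$strand[si]]
      } else {
        tpl$segments$strand[si]
      }
      d <- circ_dist(h$start, (tpl$segments$start[si] + consensus) %% n, n)
      h <- h[order(h$strand != exp_strand, d,
                   -(h$identity * h$coverage), h$start), , drop = FALSE]
      h[1L, c("start", "end", "strand", "identity"), drop = FALSE]
    })
    segs <- do.call(rbind, segs)
    mapped[[length(mapped) + 1L]] <-
      list(template = tpl, name = tpl$name, segments = segs,
           round_index = round_ix[ti])
  }
  list(mapped = mapped, unmapped = unmapped)
}

## ---- annotation assembly ---------------------------------------------------

#' Build an annotation set from mapped features
#'
#' Emits, per mapped template: a gene feature spanning its segments, the
#' CDS/tRNA/rRNA feature with its join/complement/order location, and for
#' multi-exon features one exon per segment plus the introns derived as the
#' gaps between consecutive exons on the same strand.  Trans-spliced
#' features keep their reference segment order in an `order()` location.
#' Features are sorted by start coordinate.
#'
#' @param target The annotated sequence.
#' @param mapped Mapped features from [map_features()].
#' @param unmapped Templates that failed to map (reported, not emitted).
#' @return An object of class `annotation_set` with `sequence`, `features`
#'   (GenBank-ready), `mapped` (the input, for reporting), `unmapped`
#'   (tibble of names/keys) and `qc_flags`.
#' @export
build_annotation <- function(target, mapped, unmapped = list()) {
  rec <- if (inherits(target, "seq_record")) target else seq_record("target", target)
  n <- nchar(rec$bases)
  features <- list()
  for (mf in mapped) {
    tpl <- mf$template
    seg <- as.data.frame(mf$segments[, c("start", "end", "strand")])
    seg$start <- as.integer(seg$start); seg$end <- as.integer(seg$end)
    if (!tpl$trans_spliced && nrow(seg) > 1L) {
      chk <- seg[order(seg$start), ]
      if (any(chk$end[-nrow(chk)] > chk$start[-1L])) {
        abort(sprintf("feature '%s' has overlapping segments", mf$name))
      }
    }
    # stored (file-listed) order: transcription order is kept for order()
    # locations; minus-strand joins are listed in ascending coordinates.
    listed <- seg
    operator <- NA_character_
    if (tpl$trans_spliced) {
      operator <- "order"
    } else if (nrow(seg) > 1L) {
      operator <- "join"
      listed <- seg[order(seg$start), , drop = FALSE]
      rownames(listed) <- NULL
    }
    quals <- tpl$qualifiers
    if (!"gene" %in% names(quals)) quals <- c(gene = tpl$name, quals)
    gene_q <- c(gene = unname(quals[["gene"]]))
    features[[length(features) + 1L]] <-
      new_feature("gene", listed, gene_q, operator)
    if (tpl$key != "gene") {
      features[[length(features) + 1L]] <-
        new_feature(tpl$key, listed, quals, operator)
    }
    if (nrow(seg) > 1L) {
      for (i in seq_len(nrow(seg))) {  # exons in transcription order
        features[[length(features) + 1L]] <-
          new_feature("exon", seg[i, , drop = FALSE],
                      c(gene = tpl$name, number = as.character(i)))
      }
      for (i in seq_len(nrow(seg) - 1L)) {
        a <- seg[i, ]; b2 <- seg[i + 1L, ]
        if (a$strand != b2$strand) next
        early <- if (a$start <= b2$start) a else b2
        late <- if (a$start <= b2$start) b2 else a
        if (late$start <= early$end) next
        features[[length(features) + 1L]] <-
          new_feature("intron",
                      data.frame(start = early$end, end = late$start,
                                 strand = a$strand),
                      c(gene = tpl$name, number = as.character(i)))
      }
    }
  }
  key_rank <- c(gene = 0L, CDS = 1L, tRNA = 1L, rRNA = 1L,
                exon = 2L, intron = 3L)
  ord <- order(vapply(features, function(f) min(f$segments$start), integer(1L)),
               key_rank[vapply(features, `[[`, character(1L), "key")])
  features <- features[ord]
  un <- tibble(
    name = vapply(unmapped, `[[`, character(1L), "name"),
    key = vapply(unmapped, `[[`, character(1L), "key"))
  structure(list(sequence = rec, features = features, mapped = mapped,
                 unmapped = un, qc_flags = NULL, organism = ""),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %s: %d bp, %d features, %d unmapped\n",
              x$sequence$id, nchar(x$sequence$bases), length(x$features),
              nrow(x$unmapped)))
  invisible(x)
}

## ---- QC --------------------------------------------------------------------

#' Flag internal stop codons and frame problems in CDS features
#'
#' Every CDS is reassembled in transcription order with strand applied,
#' `codon_start` is honored, and the sequence is translated with the
#' plastid/bacterial code (translation table 11).  Flags are warnings
#' only — coordinates are never silently "fixed": an internal stop usually
#' means a mis-placed boundary that deserves inspection.
#'
#' @param annotation An [annotation_set][build_annotation()] or
#'   `reference_annotation`.
#' @param translation_table NCBI genetic code id (default 11).
#' @return A tibble of flags: `feature`, `issue` (one of `internal_stop`,
#'   `length_not_multiple_of_3`, `missing_terminal_stop`), `detail`.
#' @export
qc_internal_stops <- function(annotation, translation_table = 11L) {
  p <- gb_parts(annotation)
  bases <- p$rec$bases
  code <- Biostrings::getGeneticCode(as.character(translation_table))
  flags <- list()
  add <- function(feature, issue, detail) {
    flags[[length(flags) + 1L]] <<- tibble(feature = feature, issue = issue,
                                           detail = detail)
  }
  for (f in p$features) {
    if (f$key != "CDS") next
    nm <- feature_name(f)
    seg <- segments_bio(f)
    cds <- paste(vapply(seq_len(nrow(seg)), function(i) {
      s <- circ_substr(bases, seg$start[i], seg$end[i] - seg$start[i])
      if (seg$strand[i] == "-") reverse_complement(s) else s
    }, character(1L)), collapse = "")
    cs <- suppressWarnings(as.integer(qual_get(f$qualifiers, "codon_start") %||% "1"))
    if (is.na(cs) || cs < 1L || cs > 3L) cs <- 1L
    cds <- substr(cds, cs, nchar(cds))
    if (nchar(cds) %% 3L != 0L) {
      add(nm, "length_not_multiple_of_3",
          sprintf("CDS length %d", nchar(cds)))
    }
    n_codon <- nchar(cds) %/% 3L
    if (n_codon == 0L) next
    codons <- substring(cds, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    aa <- code[codons]
    aa[is.na(aa)] <- "X"   # codons containing ambiguity codes
    internal <- which(aa[-n_codon] == "*")
    for (i in internal) {
      add(nm, "internal_stop", sprintf("stop codon %s at codon %d of %d",
                                       codons[i], i, n_codon))
    }
    if (aa[n_codon] != "*") {
      add(nm, "missing_terminal_stop", sprintf("final codon %s", codons[n_codon]))
    }
  }
  if (!length(flags)) {
    return(tibble(feature = character(0), issue = character(0),
                  detail = character(0)))
  }
  do.call(rbind, flags)
}

#' One-call annotation transfer
#'
#' Extract templates from the reference, map them onto the target, build
#' the annotation set and attach QC flags.
#'
#' @param target Target sequence ([seq_record()] or string).
#' @param reference A `reference_annotation`.
#' @param rounds Mapping schedule (see [default_rounds()]).
#' @return An [annotation_set][build_annotation()] with `qc_flags` filled in.
#' @export
annotate_sequence <- function(target, reference, rounds = default_rounds()) {
  templates <- extract_reference_features(reference)
  res <- map_features(target, templates, rounds)
  ann <- build_annotation(target, res$mapped, res$unmapped)
  ann$qc_flags <- qc_internal_stops(ann)
  ann
}
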