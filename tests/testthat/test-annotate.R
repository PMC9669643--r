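test_that("template extraction applies strand and keeps exon structure", {
  d <- withr::local_tempdir()
  gb <- file.path(d, "toy.gb")
  bases <- "ACTCACTCAACCGGCTCCCCGGTTACGTACGTACGTACGTACGTACGTACGTACGTACGT"
  writeLines(c(
    "LOCUS       toy              60 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     gene            1..6",
    "                     /gene=\"toyA\"",
    "     gene            1..15",
    "                     /gene=\"toyJ\"",
    "     CDS             join(3..7,11..15)",
    "                     /gene=\"toyJ\"",
    "     gene            order(20..25,complement(40..45))",
    "                     /gene=\"toyT\"",
    "     CDS             order(20..25,complement(40..45))",
    "                     /gene=\"toyT\"",
    "ORIGIN",
    paste0("        1 ", tolower(paste(substring(bases, seq(1, 51, 10),
                                                 seq(10, 60, 10)),
                                       collapse = " "))),
    "//"), gb)
  ref <- read_genbank(gb)
  tpl <- extract_reference_features(ref)
  expect_length(tpl, 3L)
  names(tpl) <- vapply(tpl, `[[`, character(1L), "name")

  expect_equal(tpl[["toyA"]]$segments$start, 0L)
  expect_equal(tpl[["toyA"]]$segment_sequences, "ACTCAC")

  expect_equal(nrow(tpl[["toyJ"]]$segments), 2L)
  expect_equal(nchar(tpl[["toyJ"]]$segment_sequences), c(5L, 5L))
  expect_equal(tpl[["toyJ"]]$segment_sequences[1L], substr(bases, 3, 7))

  expect_true(tpl[["toyT"]]$trans_spliced)
  expect_equal(tpl[["toyT"]]$segments$strand, c("+", "-"))
  expect_equal(tpl[["toyT"]]$segment_sequences[2L],
               reverse_complement(substr(bases, 40, 45)))
})

test_that("a CDS without a parent gene is synthesized with a warning", {
  d <- withr::local_tempdir()
  gb <- file.path(d, "orphan.gb")
  writeLines(c(
    "LOCUS       toy              40 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     CDS             5..16",
    "                     /gene=\"lonely\"",
    "ORIGIN",
    "        1 acgtacgtac gtacgtacgt acgtacgtac gtacgtacgt",
    "//"), gb)
  ref <- read_genbank(gb)
  expect_warning(tpl <- extract_reference_features(ref), "no parent gene")
  expect_length(tpl, 1L)
  expect_equal(tpl[[1L]]$name, "lonely")
})

test_that("self-annotation reproduces every planted feature at round 1", {
  truth <- generate_plastome(rng_seed = 14L)
  d <- withr::local_tempdir()
  ref <- read_genbank(write_truth_genbank(truth, d))
  ann <- annotate_sequence(truth$genome, ref)
  expect_equal(nrow(ann$unmapped), 0L)
  expect_length(ann$mapped, 6L)
  for (mf in ann$mapped) {
    expect_equal(mf$round_index, 1L)
    expect_equal(mf$segments$start, mf$template$segments$start)
    expect_equal(mf$segments$end, mf$template$segments$end)
    expect_equal(mf$segments$strand, mf$template$segments$strand)
    expect_equal(mf$segments$identity, rep(1, nrow(mf$segments)))
  }
  # qualifiers survive into the emitted features
  cds <- Filter(function(f) f$key == "CDS", ann$features)
  expect_true(all(vapply(cds, function(f)
    "transl_table" %in% names(f$qualifiers), logical(1L))))
})

test_that("mapping is rotation-equivariant, wrapping the origin", {
  truth <- generate_plastome(rng_seed = 15L)
  n <- nchar(truth$genome$bases)
  tpl <- extract_reference_features(truth$annotation)
  for (k in c(5L, 1234L)) {
    rot <- transform_plastome(truth, rotation = k)
    res <- map_features(rot, tpl)
    expect_length(res$unmapped, 0L)
    for (mf in res$mapped) {
      expect_equal(mf$segments$start %% n,
                   (mf$template$segments$start - k) %% n)
      expect_equal(mf$segments$end - mf$segments$start,
                   mf$template$segments$end - mf$template$segments$start)
    }
  }
})

test_that("divergence is rescued by the decreasing-identity schedule", {
  truth <- generate_plastome(rng_seed = 16L)
  tpl <- extract_reference_features(truth$annotation)
  # mutate every template segment at 12%: too far for rounds 1-2 (0.98,
  # 0.90) but mapped by round 3 (0.80)
  b <- truth$genome$bases
  segs <- do.call(rbind, lapply(tpl, `[[`, "segments"))
  for (i in seq_len(nrow(segs))) {
    m <- mutate_plastome(truth, 0.12, exclude_boundaries = 3L,
                         rng_seed = 600L + i,
                         region = c(segs$start[i], segs$end[i]), seq = b)
    b <- m$bases
  }
  res <- map_features(circular_sequence("d", b), tpl)
  expect_length(res$unmapped, 0L)
  expect_true(all(vapply(res$mapped, `[[`, integer(1L), "round_index") == 3L))
  expect_error(map_features(truth$genome, tpl,
                            tibble::tibble(identity = c(0.9, 0.95),
                                           coverage = c(1, 1))),
               "strictly decreasing")
})

test_that("gene models are rebuilt with exons, introns and order locations", {
  truth <- generate_plastome(rng_seed = 17L)
  ann <- annotate_sequence(truth$genome, truth$annotation)
  by_key <- split(ann$features, vapply(ann$features, `[[`, character(1L), "key"))
  # single-exon toyA: gene + CDS only, no exon/intron for it
  toyb_cds <- Filter(function(f) plastr:::feature_name(f) == "toyB",
                     by_key$CDS)[[1L]]
  expect_equal(toyb_cds$operator, "join")
  exons <- Filter(function(f) plastr:::feature_name(f) == "toyB", by_key$exon)
  introns <- Filter(function(f) plastr:::feature_name(f) == "toyB",
                    by_key$intron)
  expect_length(exons, 2L)
  expect_length(introns, 1L)
  # the intron is exactly the gap between the exons
  e <- do.call(rbind, lapply(exons, `[[`, "segments"))
  e <- e[order(e$start), ]
  expect_equal(introns[[1L]]$segments$start, e$end[1L])
  expect_equal(introns[[1L]]$segments$end, e$start[2L])
  # exons + introns tile the feature span
  expect_equal(sum(e$end - e$start) +
                 sum(introns[[1L]]$segments$end - introns[[1L]]$segments$start),
               max(e$end) - min(e$start))
  # trans-spliced feature keeps order() with mixed strands and no intron
  rps <- Filter(function(f) plastr:::feature_name(f) == "toyRps12",
                by_key$CDS)[[1L]]
  expect_equal(rps$operator, "order")
  expect_setequal(unique(rps$segments$strand), c("-", "+"))
  expect_length(Filter(function(f) plastr:::feature_name(f) == "toyRps12",
                       by_key$intron), 0L)
  # both IR copies of toyIR annotate independently, mirrored
  toyir <- Filter(function(f) plastr:::feature_name(f) == "toyIR", by_key$CDS)
  expect_length(toyir, 2L)
  expect_setequal(vapply(toyir, function(f) f$segments$strand, character(1L)),
                  c("-", "+"))
})

test_that("unmapped templates are reported, not emitted", {
  truth <- generate_plastome(rng_seed = 18L)
  tpl <- extract_reference_features(truth$annotation)
  ghost <- tpl[[1L]]
  ghost$name <- "toyZ"
  ghost$qualifiers["gene"] <- "toyZ"
  ghost$segment_sequences <- random_seq(200, seed = 77)  # absent sequence
  ghost$segments <- data.frame(start = 0L, end = 200L, strand = "+")
  res <- map_features(truth$genome, c(tpl, list(ghost)))
  expect_length(res$unmapped, 1L)
  expect_equal(res$unmapped[[1L]]$name, "toyZ")
  ann <- build_annotation(truth$genome, res$mapped, res$unmapped)
  expect_equal(ann$unmapped$name, "toyZ")
  expect_false("toyZ" %in% vapply(ann$features, plastr:::feature_name,
                                  character(1L)))
})

test_that("internal-stop QC flags exactly the planted defects", {
  mk_cds <- function(bases, cds_seq, start0) {
    rec <- seq_record("chk", bases)
    f <- plastr:::new_feature("CDS",
      data.frame(start = start0, end = start0 + nchar(cds_seq), strand = "+"),
      c(gene = "g", codon_start = "1", transl_table = "11"))
    structure(list(sequence = rec, features = list(f), mapped = list(),
                   unmapped = tibble::tibble(), qc_flags = NULL,
                   organism = ""), class = "annotation_set")
  }
  b <- random_seq(60, seed = 9)
  ann <- mk_cds(paste0("ATGTGATAA", substr(b, 10, 60)), "ATGTGATAA", 0L)
  fl <- qc_internal_stops(ann)
  expect_equal(fl$issue, "internal_stop")
  expect_match(fl$detail, "codon 2")

  ann2 <- mk_cds(paste0("ATGAAATAA", substr(b, 10, 60)), "ATGAAATAA", 0L)
  expect_equal(nrow(qc_internal_stops(ann2)), 0L)

  ann3 <- mk_cds(paste0("ATGAAATAAG", substr(b, 11, 60)), "ATGAAATAAG", 0L)
  expect_true("length_not_multiple_of_3" %in% qc_internal_stops(ann3)$issue)

  # clean synthetic reference: no flags; one planted in-frame stop in toyA:
  # exactly that CDS is flagged
  truth <- generate_plastome(rng_seed = 19L)
  expect_equal(nrow(qc_internal_stops(truth$annotation)), 0L)
  iv <- NULL
  for (f in truth$annotation$features) {
    if (f$key == "CDS" && plastr:::feature_name(f) == "toyA") iv <- f$segments
  }
  chars <- strsplit(truth$genome$bases, "")[[1L]]
  chars[(iv$start + 4L):(iv$start + 6L)] <- c("T", "G", "A")  # codon 2
  broken <- truth$annotation
  broken$sequence <- seq_record("broken", paste(chars, collapse = ""))
  fl <- qc_internal_stops(broken)
  expect_equal(fl$feature[fl$issue == "internal_stop"], "toyA")
  expect_equal(sum(fl$issue == "internal_stop"), 1L)
})
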