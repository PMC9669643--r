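test_that("FASTA reading uppercases, joins wrapped lines, and round-trips", {
  d <- withr::local_tempdir()
  f <- file.path(d, "a.fasta")
  writeLines(c(">x", "acgt", "ACGT"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1L]]$bases, "ACGTACGT")

  writeLines(c(">a", "AC", ">b", "GT"), f)
  recs <- read_fasta(f)
  expect_equal(vapply(recs, `[[`, character(1L), "id"), c("a", "b"))

  # round trip is a fixed point, with wrapping at the requested width
  r71 <- seq_record("w", random_seq(71, 1))
  out <- file.path(d, "w.fasta")
  write_fasta(r71, out, width = 70L)
  lines <- readLines(out)
  expect_equal(nchar(lines[2:3]), c(70L, 1L))
  back <- read_fasta(out)
  expect_identical(back[[1L]]$bases, r71$bases)
  out2 <- file.path(d, "w2.fasta")
  write_fasta(back, out2, width = 70L)
  expect_identical(readLines(out), readLines(out2))
})

test_that("FASTA reader rejects degenerate input with line numbers", {
  d <- withr::local_tempdir()
  f <- file.path(d, "bad.fasta")
  writeLines(">x", f)
  expect_error(read_fasta(f), "empty sequence", class = "plastr_format_error")
  writeLines(c(">x", "ACGZ"), f)
  expect_error(read_fasta(f), "line 2", class = "plastr_format_error")
  expect_error(write_fasta(list(), file.path(d, "o.fasta")), "no records")
})

test_that("FASTQ round-trips through plain and gzip files", {
  d <- withr::local_tempdir()
  reads <- tibble::tibble(id = c("r1/1", "r2/1"),
                          seq = c("ACGTACGT", "GGGTTTAA"),
                          qual = c("IIIIIIII", "IIIIIIII"))
  for (ext in c("fastq", "fastq.gz")) {
    f <- file.path(d, paste0("x.", ext))
    write_fastq(reads, f)
    back <- read_fastq(f)
    expect_equal(back, reads)
  }
  f <- file.path(d, "trunc.fastq")
  writeLines(c("@r", "ACGT", "+", "II"), f)
  expect_error(read_fastq(f), "lengths differ", class = "plastr_format_error")
})

test_that("GenBank location grammar parses joins, complements and order", {
  d <- withr::local_tempdir()
  gb <- file.path(d, "toy.gb")
  writeLines(c(
    "LOCUS       toy              60 bp    DNA     circular PLN",
    "FEATURES             Location/Qualifiers",
    "     gene            complement(join(10..20,30..40))",
    "                     /gene=\"g1\"",
    "     CDS             order(5..10,complement(41..50))",
    "                     /gene=\"g2\"",
    "     gene            5..10",
    "                     /gene=\"g3\"",
    "ORIGIN",
    paste0("        1 ", paste(rep("acgtacgtac", 6), collapse = " ")),
    "//"), gb)
  ref <- read_genbank(gb)
  expect_length(ref$features, 3L)

  f1 <- ref$features[[1L]]
  expect_equal(f1$segments$start, c(9L, 29L))
  expect_equal(f1$segments$end, c(20L, 40L))
  expect_equal(f1$segments$strand, c("-", "-"))
  expect_equal(f1$operator, "join")

  f2 <- ref$features[[2L]]
  expect_equal(f2$operator, "order")
  expect_equal(f2$segments$strand, c("+", "-"))
  expect_true(plastr:::is_trans_spliced(f2))

  f3 <- ref$features[[3L]]
  expect_equal(unname(unlist(f3$segments[1L, c("start", "end")])), c(4L, 10L))
  expect_equal(f3$segments$strand, "+")
})

test_that("GenBank reader flags missing ORIGIN and bad locations", {
  d <- withr::local_tempdir()
  gb <- file.path(d, "noorigin.gb")
  writeLines(c("LOCUS       x  10 bp DNA circular",
               "FEATURES             Location/Qualifiers"), gb)
  expect_error(read_genbank(gb), "ORIGIN", class = "plastr_format_error")
  gb2 <- file.path(d, "badloc.gb")
  writeLines(c("LOCUS       x  10 bp DNA circular",
               "FEATURES             Location/Qualifiers",
               "     gene            frob(1..3)",
               "ORIGIN",
               "        1 acgtacgtac",
               "//"), gb2)
  expect_error(read_genbank(gb2), "gene", class = "plastr_format_error")
})

test_that("GenBank write/read is a fixed point on synthetic references", {
  d <- withr::local_tempdir()
  truth <- generate_plastome(rng_seed = 11L)
  gb <- file.path(d, "ref.gb")
  write_genbank(truth$annotation, gb)
  ref <- read_genbank(gb)
  expect_identical(ref$sequence$bases, truth$genome$bases)
  expect_equal(length(ref$features), length(truth$annotation$features))
  for (i in seq_along(ref$features)) {
    expect_identical(ref$features[[i]]$key, truth$annotation$features[[i]]$key)
    expect_equal(ref$features[[i]]$segments,
                 truth$annotation$features[[i]]$segments)
    expect_identical(ref$features[[i]]$qualifiers,
                     truth$annotation$features[[i]]$qualifiers)
  }
  gb2 <- file.path(d, "ref2.gb")
  write_genbank(ref, gb2)
  expect_identical(readLines(gb), readLines(gb2))
})

test_that("GenBank writer emits exon/intron lines and complement locations", {
  d <- withr::local_tempdir()
  truth <- generate_plastome(rng_seed = 3L)
  ann <- annotate_sequence(truth$genome, truth$annotation)
  gb <- file.path(d, "ann.gb")
  write_genbank(ann, gb)
  lines <- readLines(gb)
  # the two-exon toyB contributes 2 exon lines and 1 intron line
  expect_equal(sum(grepl("^     exon", lines)), 4L)   # toyB + trans-spliced
  expect_equal(sum(grepl("^     intron", lines)), 1L)
  # the minus-strand IR copy uses complement() location text
  expect_true(any(grepl("^     gene            complement\\(", lines)))
  # out-of-bounds segments are refused
  bad <- ann
  bad$features[[1L]]$segments$end <- nchar(ann$sequence$bases) + 50L
  expect_error(write_genbank(bad, file.path(d, "bad.gb")),
               class = "plastr_out_of_bounds")
})

test_that("feature table layout follows the 5-column rules", {
  d <- withr::local_tempdir()
  rec <- seq_record("psbA_test", random_seq(200, 2))
  plus <- plastr:::new_feature("gene",
    data.frame(start = 0L, end = 90L, strand = "+"), c(gene = "psbA"))
  minus <- plastr:::new_feature("gene",
    data.frame(start = 0L, end = 90L, strand = "-"), c(gene = "psbB"))
  cds <- plastr:::new_feature("CDS",
    data.frame(start = c(0L, 49L), end = c(30L, 100L),
               strand = c("+", "+")), c(gene = "psbC"), "join")
  ann <- structure(list(sequence = rec, features = list(plus, minus, cds),
                        mapped = list(), unmapped = tibble::tibble(),
                        qc_flags = NULL, organism = ""),
                   class = "annotation_set")
  tbl <- file.path(d, "x.tbl")
  write_feature_table(ann, tbl)
  lines <- readLines(tbl)
  expect_equal(lines[1L], ">Feature psbA_test")
  expect_equal(lines[2L], "1\t90\tgene")
  expect_equal(lines[3L], "\t\t\tgene\tpsbA")
  expect_equal(lines[4L], "90\t1\tgene")
  expect_equal(lines[6L], "1\t30\tCDS")
  expect_equal(lines[7L], "50\t100")
  expect_equal(sum(grepl("^>Feature", lines)), 1L)
  # round trip preserves keys and intervals
  back <- read_feature_table(tbl)
  expect_equal(back$seqid, "psbA_test")
  expect_equal(back$features[[3L]]$segments$start, c(0L, 49L))
  tbl2 <- file.path(d, "x2.tbl")
  write_feature_table(ann, tbl2)
  expect_identical(readLines(tbl), readLines(tbl2))
})

test_that("assembler config carries range, k-mer and read paths", {
  d <- withr::local_tempdir()
  s <- sample_config("samp", reference_genbank = "ref.gb",
                     assembly = "x.fasta", seed = "seed.fa",
                     size_range = c(120000L, 200000L))
  cfg <- file.path(d, "cfg.txt")
  write_assembler_config(s, c("r1.fq", "r2.fq"), cfg)
  lines <- readLines(cfg)
  expect_true(any(grepl("120000-200000", lines)))
  expect_true(any(grepl("^K-mer\\s+= 29$", lines)))
  expect_true(any(grepl("= chloro", lines)))
  expect_true(any(grepl("Forward reads\\s+= r1\\.fq", lines)))
  s$seed <- NULL
  expect_error(write_assembler_config(s, c("r1.fq", "r2.fq"), cfg), "seed")
  expect_false(file.exists(file.path(d, "never.txt")))
})

test_that("assembler output discovery returns candidates in option order", {
  d <- withr::local_tempdir()
  write_fasta(seq_record("c1", random_seq(50, 1)),
              file.path(d, "Circularized_assembly_1_samp.fasta"))
  out <- discover_assembler_output(d, "samp")
  expect_length(out, 1L)

  d2 <- withr::local_tempdir()
  write_fasta(seq_record("o1", random_seq(50, 2)),
              file.path(d2, "Option_1_samp.fasta"))
  write_fasta(seq_record("o2", random_seq(50, 3)),
              file.path(d2, "Option_2_samp.fasta"))
  out <- discover_assembler_output(d2, "samp")
  expect_equal(vapply(out, `[[`, character(1L), "id"), c("o1", "o2"))

  write_fasta(seq_record("o3", random_seq(50, 4)),
              file.path(d2, "Option_3_samp.fasta"))
  expect_error(discover_assembler_output(d2, "samp"),
               class = "plastr_candidate_overflow")
  expect_error(discover_assembler_output(withr::local_tempdir(), "samp"),
               class = "plastr_assembly_failed")
})
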