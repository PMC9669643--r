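# Ground-truthed synthetic plastomes: a canonical LSC-IRb-SSC-IRa genome
# with a planted gene set (single-exon CDS, two-exon CDS, a trans-spliced
# CDS spanning LSC and SSC on opposite strands, a tRNA, and a gene
# duplicated in both IRs), plus isomer transformations, point mutations,
# ambiguous bases and simulated paired-end reads.  Every generator is a
# pure function of its arguments including the seed.

SENSE_CODONS <- {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, c("TAA", "TAG", "TGA"))
}

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_bases <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Clean ORF: ATG start, sense codons, TAA stop; length = 3 * n_codons.
random_orf <- function(n_codons) {
  stopifnot(n_codons >= 3L)
  paste0("ATG", paste(sample(SENSE_CODONS, n_codons - 2L, replace = TRUE),
                      collapse = ""), "TAA")
}

# Fixed gene layout in region-local coordinates (0-based half-open).
TOY_LAYOUT <- list(
  toyA = list(region = "lsc", iv = c(100L, 400L)),
  toyB = list(region = "lsc", exon1 = c(600L, 780L), exon2 = c(860L, 1010L)),
  toyRps12_seg1 = list(region = "lsc", iv = c(1200L, 1320L)),
  toyIR = list(region = "irb", iv = c(50L, 230L)),
  toyRps12_seg2 = list(region = "ssc", iv = c(100L, 280L)),
  toyTrn = list(region = "ssc", iv = c(350L, 422L)))

MIN_LSC <- 1400L
MIN_IR <- 240L
MIN_SSC <- 430L

#' Generate a synthetic plastome with ground truth
#'
#' Builds a circular genome in canonical order LSC-IRb-SSC-IRa: the LSC and
#' SSC are uniform random sequence, one IR is drawn and planted as IRb with
#' its reverse complement as IRa, and a fixed gene set is written in with
#' known coordinates: `toyA` (single-exon CDS), `toyB` (two-exon CDS),
#' `toyRps12` (trans-spliced CDS: one segment in the LSC on the plus
#' strand, one in the SSC on the minus strand), `toyTrn` (tRNA), and
#' `toyIR` (CDS duplicated in both IRs).  All CDSs are clean open reading
#' frames under translation table 11.  The four region-junction bases are
#' pinned so that the planted IR pair is the unique maximal inverted
#' repeat (no chance one-base extension across a junction).
#'
#' @param lsc_len,ir_len,ssc_len Region lengths in bp (minimums 1400, 240
#'   and 430 to host the planted gene set).
#' @param rng_seed Integer seed; the same seed reproduces the genome
#'   byte-for-byte.
#' @param id Genome identifier.
#' @return An object of class `synthetic_truth`: `genome`
#'   ([circular_sequence()]), `structure` (planted [plastome_structure()]),
#'   `annotation` (`reference_annotation` with the planted features),
#'   `lengths`, and `rng_seed`.
#' @export
generate_plastome <- function(lsc_len = 2000L, ir_len = 400L, ssc_len = 600L,
                              rng_seed = 1L, id = "synthetic_plastome") {
  lsc_len <- as.integer(lsc_len); ir_len <- as.integer(ir_len)
  ssc_len <- as.integer(ssc_len)
  if (lsc_len < MIN_LSC || ir_len < MIN_IR || ssc_len < MIN_SSC) {
    abort(sprintf("regions too small for the planted gene set (need LSC >= %d, IR >= %d, SSC >= %d)",
                  MIN_LSC, MIN_IR, MIN_SSC))
  }
  with_seed(rng_seed, {
    lsc <- base_chars(random_bases(lsc_len))
    irb <- base_chars(random_bases(ir_len))
    ssc <- base_chars(random_bases(ssc_len))

    plant <- function(chars, iv, s) {
      stopifnot(nchar(s) == iv[2L] - iv[1L])
      chars[(iv[1L] + 1L):iv[2L]] <- base_chars(s)
      chars
    }

    orf_a <- random_orf(100L)                       # 300 nt
    orf_b <- random_orf(110L)                       # 330 nt over two exons
    orf_r <- random_orf(100L)                       # 300 nt trans-spliced
    orf_i <- random_orf(60L)                        # 180 nt inside the IR

    lsc <- plant(lsc, TOY_LAYOUT$toyA$iv, orf_a)
    lsc <- plant(lsc, TOY_LAYOUT$toyB$exon1, substr(orf_b, 1L, 180L))
    lsc <- plant(lsc, TOY_LAYOUT$toyB$exon2, substr(orf_b, 181L, 330L))
    lsc <- plant(lsc, TOY_LAYOUT$toyRps12_seg1$iv, substr(orf_r, 1L, 120L))
    irb <- plant(irb, TOY_LAYOUT$toyIR$iv, orf_i)
    ssc <- plant(ssc, TOY_LAYOUT$toyRps12_seg2$iv,
                 reverse_complement(substr(orf_r, 121L, 300L)))

    # pin the two junction bases at each single-copy region end to 'A' so
    # that IR extension across a junction meets guaranteed mismatches
    # (comp(A) = T): the planted IR pair is the unique maximal repeat
    lsc[1:2] <- "A"; lsc[(lsc_len - 1L):lsc_len] <- "A"
    ssc[1:2] <- "A"; ssc[(ssc_len - 1L):ssc_len] <- "A"

    irb_s <- paste(irb, collapse = "")
    genome <- paste0(paste(lsc, collapse = ""), irb_s,
                     paste(ssc, collapse = ""), reverse_complement(irb_s))
    n <- nchar(genome)
    L0 <- 0L; I0 <- lsc_len; S0 <- lsc_len + ir_len
    A0 <- lsc_len + ir_len + ssc_len

    planted <- plastome_structure(c(0L, I0), c(I0, S0), c(S0, A0), c(A0, n), n)

    seg1 <- function(iv, strand = "+") {
      data.frame(start = as.integer(iv[1L]), end = as.integer(iv[2L]),
                 strand = strand)
    }
    cds_q <- function(name, product) {
      c(gene = name, codon_start = "1", transl_table = "11",
        product = product)
    }
    g <- function(key, segments, quals, operator = NA_character_) {
      new_feature(key, segments, quals, operator)
    }
    feats <- list(
      g("gene", seg1(TOY_LAYOUT$toyA$iv + L0), c(gene = "toyA")),
      g("CDS", seg1(TOY_LAYOUT$toyA$iv + L0),
        cds_q("toyA", "toyA protein")),
      g("gene", seg1(c(TOY_LAYOUT$toyB$exon1[1L],
                       TOY_LAYOUT$toyB$exon2[2L]) + L0), c(gene = "toyB")),
      g("CDS", rbind(seg1(TOY_LAYOUT$toyB$exon1 + L0),
                     seg1(TOY_LAYOUT$toyB$exon2 + L0)),
        cds_q("toyB", "toyB protein"), "join"),
      g("gene", rbind(seg1(TOY_LAYOUT$toyRps12_seg1$iv + L0),
                      seg1(TOY_LAYOUT$toyRps12_seg2$iv + S0, "-")),
        c(gene = "toyRps12", trans_splicing = NA_character_), "order"),
      g("CDS", rbind(seg1(TOY_LAYOUT$toyRps12_seg1$iv + L0),
                     seg1(TOY_LAYOUT$toyRps12_seg2$iv + S0, "-")),
        c(cds_q("toyRps12", "toyRps12 protein"),
          trans_splicing = NA_character_), "order"),
      g("gene", seg1(TOY_LAYOUT$toyIR$iv + I0), c(gene = "toyIR")),
      g("CDS", seg1(TOY_LAYOUT$toyIR$iv + I0),
        cds_q("toyIR", "toyIR protein")),
      g("gene", seg1(c(ir_len - TOY_LAYOUT$toyIR$iv[2L],
                       ir_len - TOY_LAYOUT$toyIR$iv[1L]) + A0, "-"),
        c(gene = "toyIR")),
      g("CDS", seg1(c(ir_len - TOY_LAYOUT$toyIR$iv[2L],
                      ir_len - TOY_LAYOUT$toyIR$iv[1L]) + A0, "-"),
        cds_q("toyIR", "toyIR protein")),
      g("gene", seg1(TOY_LAYOUT$toyTrn$iv + S0), c(gene = "toyTrn")),
      g("tRNA", seg1(TOY_LAYOUT$toyTrn$iv + S0),
        c(gene = "toyTrn", product = "tRNA-Toy")))
    feats <- feats[order(vapply(feats, function(f) min(f$segments$start),
                                integer(1L)))]

    annotation <- structure(
      list(sequence = seq_record(id, genome),
           features = feats,
           source_metadata = list(locus = id, topology = "circular",
                                  organism = "synthetic construct")),
      class = "reference_annotation")

    structure(list(genome = circular_sequence(id, genome),
                   structure = planted,
                   annotation = annotation,
                   lengths = c(lsc = lsc_len, ir = ir_len, ssc = ssc_len),
                   rng_seed = rng_seed),
              class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("<synthetic_truth> %s: %d bp (LSC %d, IR %d, SSC %d), %d features, seed %d\n",
              x$genome$id, nchar(x$genome$bases), x$lengths["lsc"],
              x$lengths["ir"], x$lengths["ssc"],
              length(x$annotation$features), x$rng_seed))
  invisible(x)
}

#' Apply an isomer transformation
#'
#' Applies a rotation, an optional whole-molecule reverse complement, and
#' an optional in-place reverse complement of the SSC (the flip-flop
#' isomer), in that order.  The transformation is recorded in the result's
#' `transformation` attribute.
#'
#' @param truth A [generate_plastome()] result.
#' @param rotation Left-rotation offset in `[0, length)`.
#' @param flip Reverse-complement the whole molecule.
#' @param ssc_flip Reverse-complement the SSC segment in place.
#' @return A [circular_sequence()] of the transformed genome.
#' @export
transform_plastome <- function(truth, rotation = 0L, flip = FALSE,
                               ssc_flip = FALSE) {
  b <- truth$genome$bases
  n <- nchar(b)
  stopifnot(rotation >= 0L, rotation < n)
  # the SSC flip is applied on canonical coordinates before relocation;
  # rotation and strand flip only move the segment, so this equals
  # rotate -> flip -> flip-SSC-in-place on the transformed coordinates
  if (ssc_flip) {
    iv <- region_interval(truth$structure, "ssc")
    b <- splice_revcomp(b, iv[1L], iv[2L] - iv[1L])
  }
  if (rotation > 0L) b <- rotate_bases(b, rotation)
  if (flip) b <- reverse_complement(b)
  out <- circular_sequence(truth$genome$id, b)
  attr(out, "transformation") <- list(rotation = as.integer(rotation),
                                      flip = flip, ssc_flip = ssc_flip)
  out
}

feature_boundary_windows <- function(annotation, pad) {
  w <- integer(0)
  for (f in annotation$features) {
    for (i in seq_len(nrow(f$segments))) {
      s <- f$segments$start[i]; e <- f$segments$end[i]
      w <- c(w, seq(s, min(s + pad - 1L, e - 1L)),
             seq(max(e - pad, s), e - 1L))
    }
  }
  unique(w)
}

#' Plant point mutations
#'
#' Substitutes exactly `round(rate * n_eligible)` positions, drawn
#' uniformly from the eligible positions: every position outside
#' `exclude_boundaries` bases of any planted feature segment end (and,
#' optionally, inside `region`).  Mutated positions are recorded in the
#' result's `mutations` attribute (0-based).
#'
#' @param truth A [generate_plastome()] result.
#' @param rate Substitution rate in `[0, 0.25)`.
#' @param exclude_boundaries Bases spared at each segment end (default 3).
#' @param rng_seed Seed for position/base choice.
#' @param region Optional `c(start, end)` 0-based half-open interval to
#'   restrict mutations to (e.g. one IR copy).
#' @param seq Optional sequence to mutate instead of the truth genome
#'   (e.g. an already-transformed isomer at rotation 0).
#' @return A [circular_sequence()] with the `mutations` attribute.
#' @export
mutate_plastome <- function(truth, rate, exclude_boundaries = 3L,
                            rng_seed = 1L, region = NULL, seq = NULL) {
  stopifnot(rate >= 0, rate < 0.25)
  b <- if (is.null(seq)) truth$genome$bases else as_bases(seq)
  n <- nchar(b)
  eligible <- setdiff(seq.int(0L, n - 1L),
                      feature_boundary_windows(truth$annotation,
                                               exclude_boundaries))
  if (!is.null(region)) {
    eligible <- eligible[eligible >= region[1L] & eligible < region[2L]]
  }
  n_mut <- round(rate * length(eligible))
  with_seed(rng_seed, {
    chars <- base_chars(b)
    pos <- sort(sample(eligible, n_mut))
    for (p in pos) {
      chars[p + 1L] <- sample(setdiff(c("A", "C", "G", "T"), chars[p + 1L]), 1L)
    }
    out <- circular_sequence(truth$genome$id, paste(chars, collapse = ""))
    attr(out, "mutations") <- pos
    out
  })
}

#' Replace random positions with ambiguous bases
#'
#' @param seq A sequence record or string.
#' @param n_positions Number of distinct positions to replace with `N`
#'   (must be below length/100).
#' @param rng_seed Seed.
#' @return A list with `sequence` (Ns planted) and `truth`, a tibble of
#'   `position` (1-based) and the original `base`.
#' @export
inject_ambiguity <- function(seq, n_positions, rng_seed = 1L) {
  b <- as_bases(seq)
  n <- nchar(b)
  stopifnot(n_positions >= 0L, n_positions < n / 100)
  if (n_positions == 0L) {
    return(list(sequence = seq_record(seq_id(seq), b),
                truth = tibble(position = integer(0), base = character(0))))
  }
  with_seed(rng_seed, {
    pos <- sort(sample.int(n, n_positions))
    chars <- base_chars(b)
    orig <- chars[pos]
    chars[pos] <- "N"
    list(sequence = seq_record(seq_id(seq), paste(chars, collapse = "")),
         truth = tibble(position = pos, base = orig))
  })
}

#' Simulate paired-end reads from a circular genome
#'
#' Fragments of length `insert` are drawn uniformly on the circle (wrapping
#' the origin); mate 1 is the fragment's leading bases, mate 2 the reverse
#' complement of its trailing bases, with the mate order swapped for a
#' random half of the fragments to emulate strand randomness.  The read
#' count is `ceiling(coverage * length / (2 * read_len))`.
#'
#' @param genome A [circular_sequence()] or string.
#' @param coverage Target mean depth (default 30).
#' @param read_len Read length (default 100; real short-read data is 151).
#' @param insert Insert (fragment) size (default 300).
#' @param error_rate Per-base substitution error rate (default 0).
#' @param rng_seed Seed.
#' @return A list with `r1` and `r2`, tibbles of `id`, `seq`, `qual`.
#' @export
simulate_reads <- function(genome, coverage = 30, read_len = 100L,
                           insert = 300L, error_rate = 0, rng_seed = 1L) {
  b <- as_bases(genome)
  n <- nchar(b)
  stopifnot(read_len < insert, insert < n)
  n_pairs <- as.integer(ceiling(coverage * n / (2 * read_len)))
  with_seed(rng_seed, {
    starts <- sample.int(n, n_pairs, replace = TRUE) - 1L
    frags <- vapply(starts, function(s) circ_substr(b, s, insert),
                    character(1L))
    a <- substr(frags, 1L, read_len)
    z <- reverse_complement(substr(frags, insert - read_len + 1L, insert))
    swap <- sample(c(TRUE, FALSE), n_pairs, replace = TRUE)
    r1 <- ifelse(swap, z, a)
    r2 <- ifelse(swap, a, z)
    if (error_rate > 0) {
      corrupt <- function(reads) {
        vapply(reads, function(r) {
          ch <- base_chars(r)
          hit <- which(stats::runif(length(ch)) < error_rate)
          for (p in hit) {
            ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
          }
          paste(ch, collapse = "")
        }, character(1L), USE.NAMES = FALSE)
      }
      r1 <- corrupt(r1); r2 <- corrupt(r2)
    }
    ids <- sprintf("sim_%06d", seq_len(n_pairs))
    qual <- strrep("I", read_len)
    list(r1 = tibble(id = paste0(ids, "/1"), seq = unname(r1), qual = qual),
         r2 = tibble(id = paste0(ids, "/2"), seq = unname(r2), qual = qual))
  })
}

#' Write a synthetic truth bundle to disk
#'
#' Emits the genome FASTA, the annotated reference GenBank file, simulated
#' reads, and a tab-separated truth table of the planted structure.
#'
#' @param truth A [generate_plastome()] result.
#' @param dir Output directory (created if needed).
#' @param reads Simulate and write paired FASTQ files too?
#' @param ... Passed to [simulate_reads()].
#' @return Invisibly, the vector of files written.
#' @export
write_synthetic_bundle <- function(truth, dir, reads = TRUE, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fa <- file.path(dir, paste0(truth$genome$id, ".fasta"))
  write_fasta(truth$genome, fa); files <- c(files, fa)
  gb <- file.path(dir, paste0(truth$genome$id, ".gb"))
  write_genbank(truth$annotation, gb); files <- c(files, gb)
  tr <- file.path(dir, paste0(truth$genome$id, ".truth.tsv"))
  utils::write.table(as.data.frame(truth$structure$regions), tr, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  files <- c(files, tr)
  if (reads) {
    rr <- simulate_reads(truth$genome, rng_seed = truth$rng_seed, ...)
    f1 <- file.path(dir, paste0(truth$genome$id, "_R1.fastq"))
    f2 <- file.path(dir, paste0(truth$genome$id, "_R2.fastq"))
    write_fastq(rr$r1, f1); write_fastq(rr$r2, f2)
    files <- c(files, f1, f2)
  }
  invisible(files)
}
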