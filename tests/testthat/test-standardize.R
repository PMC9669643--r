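test_that("toy circle canonicalization matches the brute-force oracle", {
  ref <- t1_reference()
  p <- t1_params()
  refst <- resolve_reference_structure(ref, p)

  # the brute-force enumeration confirms T1 is the unique isomer whose LSC
  # leads in reference orientation; all isomers canonicalize back to it
  isomers <- enumerate_isomers(T1, c(14L, 18L))
  expect_true(T1 %in% isomers)
  picks <- sample(seq_along(isomers), 12L)
  for (i in picks) {
    ca <- canonicalize(circular_sequence("x", isomers[i]), NULL, ref, refst, p)
    expect_identical(ca$sequence$bases, T1)
  }

  # identity input: neutral provenance and idempotence
  ca <- canonicalize(circular_sequence("x", T1), NULL, ref, refst, p)
  expect_identical(ca$sequence$bases, T1)
  expect_equal(ca$provenance$rotation, 0L)
  expect_false(ca$provenance$flipped)
  expect_false(ca$provenance$ssc_flipped)

  rot5 <- rotate_bases_for_test(T1, 5L)
  expect_equal(rot5, "CTCAACCGGCTCCCCGGTTACTCA")
  cb <- canonicalize(circular_sequence("x", rot5), NULL, ref, refst, p)
  expect_identical(cb$sequence$bases, T1)
  expect_gt(cb$provenance$rotation, 0L)

  cc <- canonicalize(circular_sequence("x", reverse_complement(T1)),
                     NULL, ref, refst, p)
  expect_identical(cc$sequence$bases, T1)
  expect_true(cc$provenance$flipped)

  cd <- canonicalize(ca$sequence, NULL, ref, refst, p)
  expect_identical(cd$sequence$bases, ca$sequence$bases)
})

test_that("canonicalization is a class function over isomer transformations", {
  truth <- generate_plastome(rng_seed = 21L)
  n <- nchar(truth$genome$bases)
  p <- test_params()
  for (rot in c(0L, 911L)) {
    for (fl in c(FALSE, TRUE)) {
      for (sf in c(FALSE, TRUE)) {
        iso <- transform_plastome(truth, rotation = rot, flip = fl,
                                  ssc_flip = sf)
        ca <- canonicalize(iso, NULL, truth$annotation, truth$structure, p)
        expect_identical(ca$sequence$bases, truth$genome$bases)
        expect_equal(ca$provenance$flipped, fl)
        expect_equal(ca$provenance$ssc_flipped, sf)
      }
    }
  }
})

test_that("canonicalization preserves length and the canonical k-mer set", {
  truth <- generate_plastome(rng_seed = 33L)
  p <- test_params()
  iso <- transform_plastome(truth, rotation = 777L, flip = TRUE)
  ca <- canonicalize(iso, NULL, truth$annotation, truth$structure, p)
  expect_equal(nchar(ca$sequence$bases), nchar(iso$bases))
  canonical_kmers <- function(b, k = 12L) {
    d <- paste0(b, substr(b, 1, k - 1))   # circular k-mers
    km <- substring(d, 1:nchar(b), 1:nchar(b) + k - 1)
    sort(pmin(km, reverse_complement(km)))
  }
  expect_false(ca$provenance$ssc_flipped)
  expect_identical(canonical_kmers(ca$sequence$bases),
                   canonical_kmers(iso$bases))
})

test_that("candidate selection follows the reference SSC orientation", {
  truth <- generate_plastome(rng_seed = 12L)
  p <- test_params()
  native <- truth$genome
  flipped <- transform_plastome(truth, ssc_flip = TRUE)
  flipped <- seq_record("opt2", flipped$bases)

  one <- select_candidate(list(native), truth$annotation, truth$structure, p)
  expect_identical(one$bases, native$bases)

  sel <- select_candidate(list(native, flipped), truth$annotation,
                          truth$structure, p)
  expect_identical(sel$bases, native$bases)
  expect_equal(attr(sel, "candidate_index"), 1L)

  # order-independent
  sel2 <- select_candidate(list(flipped, native), truth$annotation,
                           truth$structure, p)
  expect_identical(sel2$bases, native$bases)
  expect_equal(attr(sel2, "candidate_index"), 2L)

  expect_error(select_candidate(
    list(seq_record("a", strrep("A", 50)), seq_record("b", strrep("C", 50))),
    truth$annotation, truth$structure, p),
    class = "plastr_no_quadripartite")
})

test_that("ambiguous-base correction follows depth and majority rules", {
  # an N with unanimous coverage is corrected; ACGT positions never change
  b <- random_seq(300, seed = 44)
  true_base <- substr(b, 151, 151)
  nb <- paste0(substr(b, 1, 150), "N", substr(b, 152, 300))
  reads <- vapply(0:7, function(o) substr(b, 101 + o, 200 + o), character(1))
  res <- correct_ambiguous(seq_record("x", nb), reads,
                           k = 21L, min_depth = 5L, min_majority = 0.7)
  expect_identical(res$sequence$bases, b)
  expect_equal(res$report$action, "corrected")
  expect_equal(res$report$new_base, true_base)
  expect_gte(res$report$depth, 8L)

  # no anchoring read: unchanged, with a warning recorded
  far <- substr(b, 1, 60)
  expect_warning(
    res2 <- correct_ambiguous(seq_record("x", nb), far, k = 21L),
    "unchanged")
  expect_identical(res2$sequence$bases, nb)
  expect_equal(res2$report$action, "unchanged")

  # 6/4 split is below the 0.7 majority: unchanged
  votes <- c(rep("A", 6), rep("G", 4))
  reads3 <- vapply(votes, function(v) {
    paste0(substr(b, 130, 150), v, substr(b, 152, 172))
  }, character(1), USE.NAMES = FALSE)
  expect_warning(
    res3 <- correct_ambiguous(seq_record("x", nb), reads3,
                              k = 21L, min_depth = 5L, min_majority = 0.7),
    "unchanged")
  expect_equal(res3$report$action, "unchanged")
  expect_equal(res3$report$depth, 20L)  # both flanks anchor every read
  expect_identical(res3$sequence$bases, nb)

  # zero ambiguous positions: identity with an empty report
  res4 <- correct_ambiguous(seq_record("x", b), reads)
  expect_identical(res4$sequence$bases, b)
  expect_equal(nrow(res4$report), 0L)
})

test_that("planted Ns are recovered from simulated 30x reads", {
  truth <- generate_plastome(rng_seed = 55L)
  amb <- inject_ambiguity(truth$genome, 10L, rng_seed = 56L)
  rr <- simulate_reads(truth$genome, coverage = 30, read_len = 100L,
                       insert = 300L, rng_seed = 57L)
  res <- suppressWarnings(correct_ambiguous(amb$sequence, list(rr$r1, rr$r2)))
  expect_identical(res$sequence$bases, truth$genome$bases)
  merged <- merge(as.data.frame(res$report), as.data.frame(amb$truth),
                  by = "position")
  expect_equal(sum(merged$new_base == merged$base), 10L)
})
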