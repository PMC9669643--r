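# Shared fixtures and independent oracles for the test suite.

# 24 bp toy circle with a single 6 bp inverted repeat pair:
# LSC [0,8), IRb [8,14) = AACCGG, SSC [14,18), IRa [18,24) = CCGGTT.
T1 <- "ACTCACTCAACCGGCTCCCCGGTT"

t1_params <- function() structure_params(min_length = 6L, min_identity = 1)

t1_reference <- function() {
  structure(list(sequence = seq_record("t1", T1),
                 features = list(),
                 source_metadata = list(locus = "t1", topology = "circular",
                                        organism = "")),
            class = "reference_annotation")
}

test_params <- function(min_identity = 1) {
  structure_params(min_length = 100L, min_identity = min_identity)
}

rotate_bases_for_test <- function(b, k) {
  n <- nchar(b)
  k <- k %% n
  paste0(substr(b, k + 1, n), substr(b, 1, k))
}

random_seq <- function(n, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Write a truth's annotation to a GenBank file and return the path.
write_truth_genbank <- function(truth, dir = withr::local_tempdir()) {
  gb <- file.path(dir, paste0(truth$genome$id, ".gb"))
  write_genbank(truth$annotation, gb)
  gb
}

# Exhaustive inverted-repeat oracle: dynamic programming over all common
# substrings of the doubled sequence and its reverse complement (O(n^2)
# cells, each the end of every substring pair comparison), keeping every
# maximal pair with disjoint copies on the circle.  Independent of the
# seed-and-extend search path.
brute_inverted_repeats <- function(b, min_len) {
  n <- nchar(b)
  D <- paste0(b, b)
  Tt <- reverse_complement(D)
  dc <- strsplit(D, "")[[1L]]
  tc <- strsplit(Tt, "")[[1L]]
  m <- 2L * n
  prev <- integer(m)
  cells <- list()
  for (i in seq_len(m)) {
    eq <- dc[i] == tc
    cur <- ifelse(eq, c(0L, prev[-m]) + 1L, 0L)
    endj <- which(prev >= min_len)
    for (j in endj) {
      if (j < m && cur[j + 1L] != 0L) next   # run continues: not maximal
      cells[[length(cells) + 1L]] <- c(i - 1L, j, prev[j])
    }
    prev <- cur
  }
  for (j in which(prev >= min_len)) {
    cells[[length(cells) + 1L]] <- c(m, j, prev[j])
  }
  if (!length(cells)) return(NULL)
  res <- list()
  ov <- function(a1, a2, b1, b2) a1 < b2 && b1 < a2
  for (cl in cells) {
    i <- cl[1L]; j <- cl[2L]; L <- cl[3L]
    if (L > n) next
    as0 <- (i - L) %% n
    bs0 <- (m - j) %% n
    if (ov(as0, as0 + L, bs0, bs0 + L) ||
        ov(as0, as0 + L, bs0 - n, bs0 - n + L) ||
        ov(as0, as0 + L, bs0 + n, bs0 + n + L)) next
    if (bs0 < as0) { t <- as0; as0 <- bs0; bs0 <- t }
    res[[length(res) + 1L]] <- c(a = as0, b = bs0, len = L)
  }
  if (!length(res)) return(NULL)
  mm <- unique(do.call(rbind, res))
  mm[order(-mm[, "len"]), , drop = FALSE]
}

# Brute-force canonicalization oracle for tiny circles: enumerate every
# rotation x strand x SSC-flip and return all distinct strings whose
# structure starts with the LSC at position 0 in reference orientation.
enumerate_isomers <- function(b, ssc_iv) {
  n <- nchar(b)
  out <- character(0)
  for (sf in c(FALSE, TRUE)) {
    x <- if (sf) {
      paste0(substr(b, 1, ssc_iv[1]),
             reverse_complement(substr(b, ssc_iv[1] + 1, ssc_iv[2])),
             substr(b, ssc_iv[2] + 1, n))
    } else b
    for (fl in c(FALSE, TRUE)) {
      y <- if (fl) reverse_complement(x) else x
      for (r in 0:(n - 1)) {
        out <- c(out, paste0(substr(y, r + 1, n), substr(y, 1, r)))
      }
    }
  }
  unique(out)
}
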