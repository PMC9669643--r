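# Adapters for the external organelle assembler (NOVOPlasty-style): config
# writing and output discovery.  The assembler itself is never required for
# the core pipeline (pre-assembled mode skips it).

#' Write an assembler config file
#'
#' Emits the key = value config template the external organelle assembler
#' expects: project name (the sample prefix), assembly type `chloro`, the
#' genome size range, k-mer size, seed path and the trimmed read paths.
#' Defaults follow standard plastome practice: k-mer 29, read length 151,
#' insert size 300, paired-end.
#'
#' @param sample A [sample_config()].
#' @param trimmed_read_paths Character vector of length 2: forward and
#'   reverse trimmed read files.
#' @param path Output path for the config file.
#' @param kmer K-mer size (default 29).
#' @param read_length Read length in bp (default 151).
#' @param insert_size Insert size in bp (default 300).
#' @return `path`, invisibly.
#' @export
write_assembler_config <- function(sample, trimmed_read_paths, path,
                                   kmer = 29L, read_length = 151L,
                                   insert_size = 300L) {
  if (is.null(sample$seed) || !nzchar(sample$seed %||% "")) {
    abort("sample has no seed path; cannot write assembler config")
  }
  if (is.null(sample$size_range) || length(sample$size_range) != 2L) {
    abort("sample has no genome size range; cannot write assembler config")
  }
  stopifnot(length(trimmed_read_paths) == 2L)
  rng <- sprintf("%d-%d", sample$size_range[1L], sample$size_range[2L])
  out <- c(
    "Project:",
    "-----------------------",
    sprintf("Project name          = %s", sample$prefix),
    "Type                  = chloro",
    sprintf("Genome Range          = %s", rng),
    sprintf("K-mer                 = %d", kmer),
    "Max memory            = ",
    "Extended log          = 0",
    "Save assembled reads  = no",
    sprintf("Seed Input            = %s", sample$seed),
    "Extend seed directly  = no",
    "Reference sequence    = ",
    "Variance detection    = ",
    "",
    "Dataset 1:",
    "-----------------------",
    sprintf("Read Length           = %d", read_length),
    sprintf("Insert size           = %d", insert_size),
    "Platform              = illumina",
    "Single/Paired         = PE",
    sprintf("Forward reads         = %s", trimmed_read_paths[1L]),
    sprintf("Reverse reads         = %s", trimmed_read_paths[2L])
  )
  writeLines(out, path)
  invisible(path)
}

#' Discover assembler output candidates
#'
#' A successful assembler run leaves either a single circularized assembly
#' or two candidates ("Option_1"/"Option_2") that differ in SSC
#' orientation.  Candidates are returned in option order.  Zero candidates
#' is an assembly failure; more than two aborts with a
#' `plastr_candidate_overflow` condition, mirroring the pipeline's refusal
#' to guess among ambiguous assemblies.
#'
#' @param dir Directory containing the assembler output.
#' @param prefix Sample prefix used as the assembler project name.
#' @return A list of 1 or 2 [seq_record()] candidates.
#' @export
discover_assembler_output <- function(dir, prefix) {
  if (!dir.exists(dir)) abort(sprintf("no such directory: %s", dir))
  esc <- gsub("([^A-Za-z0-9_])", "\\\\\\1", prefix)
  circ <- list.files(dir, sprintf("^Circularized_assembly_.*_%s\\.fasta$", esc),
                     full.names = TRUE)
  opts <- list.files(dir, sprintf("^Option_[0-9]+_%s\\.fasta$", esc),
                     full.names = TRUE)
  opt_no <- as.integer(sub("^Option_([0-9]+)_.*$", "\\1", basename(opts)))
  opts <- opts[order(opt_no)]
  files <- c(sort(circ), opts)
  if (length(files) == 0L) {
    abort(sprintf("assembly failed: no candidates for prefix '%s' in %s",
                  prefix, dir),
          class = "plastr_assembly_failed")
  }
  if (length(files) > 2L) {
    abort(sprintf(paste0("more than two assembly candidates for prefix '%s' ",
                         "(%d found); refusing to guess"),
                  prefix, length(files)),
          class = "plastr_candidate_overflow")
  }
  lapply(files, function(f) read_fasta(f)[[1L]])
}
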