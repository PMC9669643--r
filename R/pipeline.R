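# Batch orchestration: per-sample configuration, directory layout, stage
# logging, and the end-to-end run ordering
# candidates -> select -> correct -> structure -> canonicalize -> annotate
# -> GenBank/tbl output.  Pre-assembled mode is first class: the external
# trimmer/assembler are invoked only when reads mode is configured.

#' Parse an assembly size range
#'
#' @param text A string like `"120000-200000"`.
#' @return Integer vector `c(min_bp, max_bp)` with `min < max`.
#' @export
parse_range <- function(text) {
  if (!is.character(text) || length(text) != 1L ||
      !grepl("^\\s*[0-9]+\\s*-\\s*[0-9]+\\s*$", text)) {
    abort(sprintf("malformed size range '%s' (expected e.g. 120000-200000)",
                  as.character(text)[1L]),
          class = "plastr_config_error")
  }
  v <- as.integer(strsplit(gsub("\\s", "", text), "-", fixed = TRUE)[[1L]])
  if (v[1L] >= v[2L]) {
    abort(sprintf("size range minimum %d is not below maximum %d", v[1L], v[2L]),
          class = "plastr_config_error")
  }
  v
}

#' Per-sample configuration
#'
#' @param prefix Sample prefix; used as the output directory name.
#' @param reference_genbank Path to the annotated reference GenBank file.
#' @param reads Optional character vector `c(forward, reverse)` of FASTQ
#'   paths (reads mode and/or ambiguous-base correction).
#' @param assembly Optional pre-assembled input: a FASTA with 1-2 candidate
#'   isomers, or an assembler output directory to be discovered.
#' @param seed Optional seed-sequence FASTA (required only for reads mode).
#' @param size_range Expected assembly size range in bp (default
#'   `c(120000, 200000)`); the final length is checked against it.
#' @param params [structure_params()] for structure/standardization.
#' @param rounds Annotation mapping schedule (see [default_rounds()]).
#' @param tool_paths Named list of external tool locations (`fastp`,
#'   `assembler`) for reads mode.
#' @param subsample_reads Reads kept by the trimmer (default 10000000).
#' @return A `sample_config` object.
#' @export
sample_config <- function(prefix, reference_genbank, reads = NULL,
                          assembly = NULL, seed = NULL,
                          size_range = c(120000L, 200000L),
                          params = structure_params(), rounds = default_rounds(),
                          tool_paths = list(), subsample_reads = 10000000L) {
  if (!grepl("^[A-Za-z0-9._-]+$", prefix)) {
    abort(sprintf("prefix '%s' is not a valid directory name", prefix),
          class = "plastr_config_error")
  }
  if (length(size_range) != 2L || size_range[1L] >= size_range[2L]) {
    abort("size_range must be c(min, max) with min < max",
          class = "plastr_config_error")
  }
  has_reads <- !is.null(reads)
  if (is.null(assembly) && !has_reads) {
    abort(sprintf("sample '%s': either reads or a pre-assembled input is required",
                  prefix), class = "plastr_config_error")
  }
  structure(list(prefix = prefix, reference_genbank = reference_genbank,
                 reads = reads, assembly = assembly, seed = seed,
                 size_range = as.integer(size_range), params = params,
                 rounds = rounds, tool_paths = tool_paths,
                 subsample_reads = as.integer(subsample_reads)),
            class = "sample_config")
}

#' Parse a batch file-of-files
#'
#' One sample per non-empty, non-comment (`#`) line, whitespace-separated:
#' `prefix forward.fastq reverse.fastq` in reads mode, or
#' `prefix assembly.fasta` in pre-assembled mode.
#'
#' @param path Path to the batch file.
#' @param mode `"reads"` or `"assembly"`.
#' @return A list of per-sample field lists (`prefix` plus paths), to be
#'   merged with global defaults via [sample_config()].
#' @export
parse_batch_file <- function(path, mode = c("assembly", "reads")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) abort(sprintf("no such batch file: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (!length(keep)) {
    abort(sprintf("%s: batch file has no samples", path),
          class = "plastr_config_error")
  }
  seen <- character(0)
  out <- list()
  for (i in keep) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    want <- if (mode == "reads") 3L else 2L
    if (length(f) != want) {
      abort(sprintf("%s: line %d: expected %d fields, got %d",
                    path, i, want, length(f)),
            class = "plastr_config_error")
    }
    if (f[1L] %in% seen) {
      abort(sprintf("%s: line %d: duplicate prefix '%s'", path, i, f[1L]),
            class = "plastr_config_error")
    }
    seen <- c(seen, f[1L])
    for (p in f[-1L]) {
      if (!file.exists(p)) {
        abort(sprintf("%s: line %d: missing file '%s'", path, i, p),
              class = "plastr_config_error")
      }
    }
    out[[length(out) + 1L]] <-
      if (mode == "reads") list(prefix = f[1L], reads = f[2:3])
    else list(prefix = f[1L], assembly = f[2L])
  }
  out
}

#' Read a simple key: value pipeline config file
#'
#' @param path YAML-compatible `key: value` text file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such config file: %s", path))
  yaml::read_yaml(path)
}

## ---- stage logging ---------------------------------------------------------

stage_log <- function(log_dir, stage, lines, ok = TRUE, error = NULL) {
  f <- file.path(log_dir, paste0(stage, ".log"))
  final <- if (ok) "SUCCESS" else paste0("ERROR: ", error)
  writeLines(c(sprintf("[%s]", stage), lines, final), f)
  invisible(f)
}

## ---- per-sample run --------------------------------------------------------

#' Run the pipeline for one sample
#'
#' Creates `<outdir>/<prefix>/{logs,assembly,standardized,annotation}`,
#' then: discover/read candidates, select the isomer matching the
#' reference SSC orientation, correct ambiguous bases when reads are
#' available, resolve the quadripartite structure (falling back to
#' whole-molecule orientation with a warning when no IR is found),
#' canonicalize, annotate, and write the standardized FASTA, GenBank,
#' feature table and TSV reports.  Every stage appends to its own log
#' file; the final assembly length is checked against the size range.
#'
#' @param sample A [sample_config()].
#' @param outdir Parent output directory (default `"."`).
#' @return A one-row manifest tibble: `prefix`, `status`
#'   (`"complete"`/`"failed"`), `failed_stage`, `message`, `n_mapped`,
#'   `n_unmapped`, `n_qc_flags`, and an `outputs` list-column.
#' @export
run_sample <- function(sample, outdir = ".") {
  stopifnot(inherits(sample, "sample_config"))
  base <- file.path(outdir, sample$prefix)
  dirs <- file.path(base, c("logs", "assembly", "standardized", "annotation"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  logs <- dirs[1L]
  outputs <- character(0)
  failed <- function(stage, msg) {
    tibble(prefix = sample$prefix, status = "failed", failed_stage = stage,
           message = msg, n_mapped = NA_integer_, n_unmapped = NA_integer_,
           n_qc_flags = NA_integer_, outputs = list(outputs))
  }
  run_stage <- function(stage, expr) {
    res <- tryCatch(list(value = force(expr)), error = function(e) {
      stage_log(logs, stage, character(0), ok = FALSE,
                error = conditionMessage(e))
      structure(list(error = e), class = "plastr_stage_failure")
    })
    res
  }

  # -- candidates --
  st <- run_stage("candidates", {
    if (!is.null(sample$assembly)) {
      if (dir.exists(sample$assembly)) {
        discover_assembler_output(sample$assembly, sample$prefix)
      } else {
        recs <- read_fasta(sample$assembly)
        if (length(recs) > 2L) {
          abort(sprintf("more than two assembly candidates in %s (%d found)",
                        sample$assembly, length(recs)),
                class = "plastr_candidate_overflow")
        }
        recs
      }
    } else {
      run_external_assembly(sample, base, logs)
    }
  })
  if (inherits(st, "plastr_stage_failure")) {
    return(failed("candidates", conditionMessage(st$error)))
  }
  candidates <- st$value
  stage_log(logs, "candidates",
            sprintf("%d candidate(s): %s", length(candidates),
                    paste(vapply(candidates, seq_id, character(1L)),
                          collapse = ", ")))

  # -- reference --
  st <- run_stage("reference", {
    ref <- read_genbank(sample$reference_genbank)
    ref_structure <- tryCatch(
      resolve_reference_structure(ref, sample$params),
      error = function(e) NULL)
    list(ref = ref, ref_structure = ref_structure)
  })
  if (inherits(st, "plastr_stage_failure")) {
    return(failed("reference", conditionMessage(st$error)))
  }
  ref <- st$value$ref
  ref_structure <- st$value$ref_structure
  stage_log(logs, "reference",
            c(sprintf("reference %s: %d bp, %d features", ref$sequence$id,
                      nchar(ref$sequence$bases), length(ref$features)),
              if (is.null(ref_structure))
                "WARNING: reference structure unresolvable; whole-molecule fallback in use"
              else "reference structure resolved"))

  # -- select --
  st <- run_stage("select", {
    if (length(candidates) == 1L || is.null(ref_structure)) {
      out <- candidates[[1L]]
      attr(out, "candidate_index") <- 1L
      out
    } else {
      select_candidate(candidates, ref, ref_structure, sample$params)
    }
  })
  if (inherits(st, "plastr_stage_failure")) {
    return(failed("select", conditionMessage(st$error)))
  }
  chosen <- st$value
  stage_log(logs, "select",
            sprintf("selected candidate %d of %d",
                    attr(chosen, "candidate_index") %||% 1L,
                    length(candidates)))

  # -- correct --
  corr_report <- NULL
  st <- run_stage("correct", {
    if (!is.null(sample$reads)) {
      reads <- lapply(sample$reads, read_fastq)
      res <- withCallingHandlers(
        correct_ambiguous(chosen, reads),
        warning = function(w) invokeRestart("muffleWarning"))
      corr_report <- res$report
      out <- res$sequence
      attr(out, "candidate_index") <- attr(chosen, "candidate_index")
      out
    } else {
      chosen
    }
  })
  if (inherits(st, "plastr_stage_failure")) {
    return(failed("correct", conditionMessage(st$error)))
  }
  chosen <- st$value
  stage_log(logs, "correct", if (is.null(corr_report)) {
    "no reads supplied; correction skipped"
  } else {
    sprintf("%d ambiguous position(s), %d corrected", nrow(corr_report),
            sum(corr_report$action == "corrected"))
  })

  # -- structure + canonicalize --
  st <- run_stage("standardize", {
    struct <- tryCatch(resolve_structure(chosen, sample$params),
                       error = function(e) NULL)
    if (is.null(struct) || is.null(ref_structure)) {
      sa <- orient_to_reference(chosen, ref)
      list(sa = sa, warning = "quadripartite structure not resolved; whole-molecule orientation fallback")
    } else {
      list(sa = canonicalize(chosen, struct, ref, ref_structure,
                             sample$params),
           warning = NULL)
    }
  })
  if (inherits(st, "plastr_stage_failure")) {
    return(failed("standardize", conditionMessage(st$error)))
  }
  sa <- st$value$sa
  if (!is.null(corr_report) && nrow(corr_report)) {
    sa$provenance$corrected_positions <-
      corr_report$position[corr_report$action == "corrected"]
  }
  std_fasta <- file.path(base, "standardized",
                         paste0(sample$prefix, ".standardized.fasta"))
  write_fasta(sa$sequence, std_fasta)
  prov_tsv <- file.path(base, "standardized",
                        paste0(sample$prefix, ".provenance.tsv"))
  prov <- sa$provenance
  utils::write.table(
    data.frame(field = c("candidate_index", "rotation", "flipped",
                         "ssc_flipped", "fallback", "corrected_positions"),
               value = c(prov$candidate_index, prov$rotation, prov$flipped,
                         prov$ssc_flipped, prov$fallback,
                         paste(prov$corrected_positions, collapse = ","))),
    prov_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  outputs <- c(outputs, std_fasta, prov_tsv)
  len <- nchar(sa$sequence$bases)
  range_note <- if (len < sample$size_range[1L] || len > sample$size_range[2L]) {
    sprintf("WARNING: assembly length %d outside expected range %d-%d",
            len, sample$size_range[1L], sample$size_range[2L])
  } else {
    sprintf("assembly length %d within range %d-%d", len,
            sample$size_range[1L], sample$size_range[2L])
  }
  stage_log(logs, "standardize",
            c(sprintf("rotation %d, flipped %s, SSC flipped %s",
                      prov$rotation, prov$flipped, prov$ssc_flipped),
              st$value$warning, range_note))

  # -- annotate --
  st <- run_stage("annotate", {
    withCallingHandlers(
      annotate_sequence(sa$sequence, ref, sample$rounds),
      warning = function(w) invokeRestart("muffleWarning"))
  })
  if (inherits(st, "plastr_stage_failure")) {
    return(failed("annotate", conditionMessage(st$error)))
  }
  ann <- st$value
  ann$organism <- ref$source_metadata$organism %||% ""
  gb <- file.path(base, "annotation", paste0(sample$prefix, ".gb"))
  tbl <- file.path(base, "annotation", paste0(sample$prefix, ".tbl"))
  rpt <- file.path(base, "annotation",
                   paste0(sample$prefix, ".annotation_report.tsv"))
  write_genbank(ann, gb)
  write_feature_table(ann, tbl)
  write_annotation_report(ann, rpt)
  outputs <- c(outputs, gb, tbl, rpt)
  stage_log(logs, "annotate",
            sprintf("%d feature(s) mapped, %d unmapped, %d QC flag(s)",
                    length(ann$mapped), nrow(ann$unmapped),
                    nrow(ann$qc_flags)))

  tibble(prefix = sample$prefix, status = "complete",
         failed_stage = NA_character_, message = range_note,
         n_mapped = length(ann$mapped), n_unmapped = nrow(ann$unmapped),
         n_qc_flags = nrow(ann$qc_flags), outputs = list(outputs))
}

write_annotation_report <- function(ann, path) {
  rows <- lapply(ann$mapped, function(mf) {
    data.frame(name = mf$name, key = mf$template$key, status = "mapped",
               round = mf$round_index,
               segments = paste(sprintf("%d-%d(%s)", mf$segments$start + 1L,
                                        mf$segments$end, mf$segments$strand),
                                collapse = ","),
               min_identity = min(mf$segments$identity))
  })
  if (nrow(ann$unmapped)) {
    rows <- c(rows, lapply(seq_len(nrow(ann$unmapped)), function(i) {
      data.frame(name = ann$unmapped$name[i], key = ann$unmapped$key[i],
                 status = "unmapped", round = NA_integer_, segments = "",
                 min_identity = NA_real_)
    }))
  }
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(ann$qc_flags) && nrow(ann$qc_flags)) {
    qc_path <- sub("\\.tsv$", ".qc.tsv", path)
    utils::write.table(as.data.frame(ann$qc_flags), qc_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Reads-mode adapter: trim/subsample with fastp, write the assembler
# config, run the external assembler, and discover its candidates.  Only
# used when tool paths are configured.
run_external_assembly <- function(sample, base, logs) {
  if (is.null(sample$reads)) {
    abort("reads mode requested but no reads configured",
          class = "plastr_config_error")
  }
  fastp <- sample$tool_paths$fastp %||% Sys.which("fastp")
  assembler <- sample$tool_paths$assembler %||% ""
  if (!nzchar(assembler)) {
    abort("no assembler configured; supply a pre-assembled input or tool_paths$assembler",
          class = "plastr_config_error")
  }
  adir <- file.path(base, "assembly")
  t1 <- file.path(adir, paste0(sample$prefix, "_R1.trimmed.fastq.gz"))
  t2 <- file.path(adir, paste0(sample$prefix, "_R2.trimmed.fastq.gz"))
  if (nzchar(fastp)) {
    status <- system2(fastp, c("-i", sample$reads[1L], "-I", sample$reads[2L],
                               "-o", t1, "-O", t2,
                               "--reads_to_process", sample$subsample_reads,
                               "-j", file.path(adir, "fastp.json"),
                               "-h", file.path(adir, "fastp.html")),
                      stdout = file.path(logs, "fastp.out"),
                      stderr = file.path(logs, "fastp.err"))
    if (status != 0L) abort("fastp failed")
  } else {
    t1 <- sample$reads[1L]; t2 <- sample$reads[2L]
  }
  cfg <- file.path(adir, paste0(sample$prefix, ".assembler.config"))
  write_assembler_config(sample, c(t1, t2), cfg)
  status <- system2(assembler, c("-c", cfg),
                    stdout = file.path(logs, "assembler.out"),
                    stderr = file.path(logs, "assembler.err"))
  if (status != 0L) abort("assembler failed")
  discover_assembler_output(adir, sample$prefix)
}

#' Run a batch of samples
#'
#' Samples are processed independently: one failure (including a
#' candidate-overflow abort) does not stop the batch.
#'
#' @param samples A list of [sample_config()] objects.
#' @param outdir Parent output directory.
#' @return The run manifest: one row per sample (see [run_sample()]).
#' @export
run_batch <- function(samples, outdir = ".") {
  if (inherits(samples, "sample_config")) samples <- list(samples)
  if (!length(samples)) {
    abort("batch contains no samples", class = "plastr_config_error")
  }
  rows <- lapply(samples, function(s) {
    tryCatch(run_sample(s, outdir), error = function(e) {
      tibble(prefix = s$prefix, status = "failed",
             failed_stage = "setup", message = conditionMessage(e),
             n_mapped = NA_integer_, n_unmapped = NA_integer_,
             n_qc_flags = NA_integer_, outputs = list(character(0)))
    })
  })
  manifest <- do.call(rbind, rows)
  # a sample is complete only if every declared output exists and is non-empty
  ok <- vapply(seq_len(nrow(manifest)), function(i) {
    outs <- manifest$outputs[[i]]
    length(outs) > 0L && all(file.exists(outs)) &&
      all(file.size(outs) > 0L)
  }, logical(1L))
  manifest$status[manifest$status == "complete" & !ok] <- "failed"
  manifest
}
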