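# End-to-end orchestration: simulate cohorts to disk, run the full
# align -> call -> filter -> tabulate -> test pipeline over a FASTA plus
# group manifest, and write a stable output layout.

#' Write a simulated cohort to disk
#'
#' @param spec A [cohort_spec()].
#' @param out_dir Output directory (created if needed).
#' @param ref Reference object.
#' @return Invisibly, the paths written: `fasta`, `truth`, `spec`.
#' @export
simulate_to_files <- function(spec, out_dir, ref = load_reference()) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulate_cohort(spec, ref)
  fasta <- file.path(out_dir, "cohort.fasta")
  truth <- file.path(out_dir, "truth.tsv")
  spec_path <- file.path(out_dir, "cohort_spec.json")
  Biostrings::writeXStringSet(sim$sequences, fasta, width = 70L)
  write.table(sim$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.tsv")
  write.table(sim$truth[, c("sample_id", "group")], manifest, sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(spec), spec_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(list(fasta = fasta, truth = truth, spec = spec_path,
                 manifest = manifest))
}

#' Call every sample of a cohort
#'
#' @param sequences Named character vector or [Biostrings::DNAStringSet].
#' @param manifest data.frame `sample_id`, `group` ("case"/"control").
#' @param ref Reference object.
#' @param params [align_params()].
#' @param regions Region table.
#' @return List: `samples` (list of `sample_call`), `skipped` (data.frame
#'   `sample_id`, `reason` for unalignable sequences).
#' @export
call_cohort <- function(sequences, manifest, ref, params = align_params(),
                        regions = region_table()) {
  if (inherits(sequences, "DNAStringSet")) {
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  }
  if (length(sequences) == 0L) stop("no sequences", call. = FALSE)
  missing <- setdiff(names(sequences), manifest$sample_id)
  if (length(missing)) {
    stop("manifest missing sample(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  bad_grp <- setdiff(manifest$group, c("case", "control"))
  if (length(bad_grp)) {
    stop("manifest group must be case/control, found: ",
         paste(bad_grp, collapse = ", "), call. = FALSE)
  }
  samples <- list(); skipped <- list()
  for (id in names(sequences)) {
    grp <- manifest$group[match(id, manifest$sample_id)]
    res <- tryCatch(
      call_sample(sequences[[id]], ref, sample_id = id, group = grp,
                  params = params, regions = regions),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning("skipping ", id, ": ", conditionMessage(res), call. = FALSE)
      skipped[[length(skipped) + 1L]] <- data.frame(
        sample_id = id, reason = conditionMessage(res),
        stringsAsFactors = FALSE)
    } else {
      samples[[id]] <- res
    }
  }
  list(samples = samples,
       skipped = if (length(skipped)) do.call(rbind, skipped)
                 else data.frame(sample_id = character(0),
                                 reason = character(0)))
}

#' Run the full case-control pipeline
#'
#' Aligns every sample against the reference, extracts normalized variants,
#' screens phantom candidates, and writes per-sample variant calls, the D310
#' summary, the exclusion report, the association report (all variants and
#' the MDP subset), the sharing spectrum and a JSON run summary to
#' `out_dir`.
#'
#' @param fasta Path to the cohort FASTA.
#' @param manifest Path to a two-column TSV (`sample_id`, `group`) or a
#'   data.frame.
#' @param out_dir Output directory.
#' @param ref Reference object.
#' @param panel Phantom-score panel (see [score_variants()]); `NULL` uses the
#'   cohort self-panel.
#' @param params,regions,threshold,min_shared,policy Stage parameters.
#' @return Invisibly, a list with the in-memory results: `samples`,
#'   `skipped`, `calls`, `verdicts`, `filtered`, `association`, `d310`,
#'   `spectrum`, `partition`, `mdp`.
#' @export
run_pipeline <- function(fasta, manifest, out_dir, ref = load_reference(),
                         panel = NULL, params = align_params(),
                         regions = region_table(), threshold = 3L,
                         min_shared = 2L,
                         policy = c("exclude", "report-only")) {
  policy <- match.arg(policy)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta)
  if (length(seqs) == 0L) stop("no sequences", call. = FALSE)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (is.character(manifest)) {
    manifest <- read.delim(manifest, stringsAsFactors = FALSE)
  }

  cc <- call_cohort(seqs, manifest, ref, params, regions)
  calls <- calls_table(cc$samples)
  fps <- footprints_table(cc$samples)

  verdicts <- score_variants(calls, panel = panel, threshold = threshold,
                             min_shared = min_shared)
  flt <- apply_filter(calls, verdicts, policy = policy)

  # association over every surviving label
  assoc <- do.call(rbind, lapply(sort(unique(flt$calls$label)), function(l) {
    ct <- tryCatch(carrier_table(flt$calls, fps, l),
                   error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    cs <- tryCatch(chi_square(ct), error = function(e)
      list(statistic = NA_real_, p_value = NA_real_, significant = NA))
    data.frame(label = l,
               regions = paste(annotate_position(label_span(l)[1], regions),
                               collapse = ";"),
               case_carriers = ct$case_carriers, case_total = ct$case_total,
               control_carriers = ct$control_carriers,
               control_total = ct$control_total,
               case_pct = round(100 * ct$case_carriers / ct$case_total, 1),
               control_pct = round(100 * ct$control_carriers /
                                     ct$control_total, 1),
               p_value = cs$p_value, significant = cs$significant,
               stringsAsFactors = FALSE)
  }))
  if (is.null(assoc)) assoc <- data.frame()

  d310 <- do.call(rbind, lapply(cc$samples, function(s) data.frame(
    sample_id = s$sample_id, group = s$group,
    d310_category = if (is.null(s$d310)) "uncallable" else s$d310$category,
    tract1_len = if (is.null(s$d310)) NA_integer_ else s$d310$tract1_len,
    tract2_len = if (is.null(s$d310)) NA_integer_ else s$d310$tract2_len,
    stringsAsFactors = FALSE)))
  row.names(d310) <- NULL

  spectrum <- variant_spectrum(flt$calls)
  partition <- shared_unique_partition(flt$calls)
  mdp <- mdp_report(flt$calls, fps, regions)

  write.table(calls, file.path(out_dir, "calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(flt$excluded, file.path(out_dir, "excluded.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(assoc, file.path(out_dir, "association.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(d310, file.path(out_dir, "d310.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(spectrum, file.path(out_dir, "spectrum.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(mdp, file.path(out_dir, "mdp.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  summary <- list(
    n_samples = length(seqs), n_called = length(cc$samples),
    n_skipped = nrow(cc$skipped),
    n_distinct_labels = length(unique(calls$label)),
    n_phantom_candidates =
      sum(verdicts$verdict == "phantom_candidate"),
    n_rare_flagged = length(flt$rare),
    cases_only = length(partition$cases_only),
    controls_only = length(partition$controls_only),
    shared = length(partition$shared),
    policy = policy, threshold = threshold, min_shared = min_shared)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(samples = cc$samples, skipped = cc$skipped, calls = calls,
                 verdicts = verdicts, filtered = flt, association = assoc,
                 d310 = d310, spectrum = spectrum, partition = partition,
                 mdp = mdp))
}

#' Write one sample's variants as a single-sample VCF
#'
#' Converts the 3'-shifted internal representation to VCF's left-anchored
#' form: indels are shifted to their 5'-most equivalent placement and padded
#' with the preceding reference base, per the VCF specification; contig is
#' "chrM" with 1-based POS.
#'
#' @param sample A `sample_call` object.
#' @param ref Reference object.
#' @param path Output path.
#' @return Invisibly, the data.frame of VCF records written.
#' @export
write_sample_vcf <- function(sample, ref, path) {
  recs <- lapply(seq_len(nrow(sample$variants)), function(i) {
    v <- sample$variants[i, ]
    if (v$klass == "substitution") {
      return(data.frame(POS = v$position, REF = v$ref_allele,
                        ALT = v$alt_allele, stringsAsFactors = FALSE))
    }
    # 5'-shift the indel, then left-pad with the preceding reference base
    start <- v$position; raln <- v$ref_allele; aaln <- v$alt_allele
    if (v$klass %in% c("duplication", "insertion")) {
      ins <- if (v$klass == "duplication") v$ref_allele else v$alt_allele
      at <- if (v$klass == "duplication") v$end_position + 1L
            else v$end_position   # inserted before this ref position
      while (at > 1L &&
             substr(ref$sequence, at - 1L, at - 1L) ==
             substr(ins, nchar(ins), nchar(ins))) {
        ins <- paste0(substr(ins, nchar(ins), nchar(ins)),
                      substr(ins, 1, nchar(ins) - 1L))
        at <- at - 1L
      }
      pad <- substr(ref$sequence, at - 1L, at - 1L)
      return(data.frame(POS = at - 1L, REF = pad, ALT = paste0(pad, ins),
                        stringsAsFactors = FALSE))
    }
    if (v$klass == "deletion") {
      s <- v$position; e <- v$end_position
      while (s > 1L &&
             substr(ref$sequence, s - 1L, s - 1L) ==
             substr(ref$sequence, e, e)) {
        s <- s - 1L; e <- e - 1L
      }
      pad <- substr(ref$sequence, s - 1L, s - 1L)
      return(data.frame(POS = s - 1L, REF = paste0(pad,
                          substr(ref$sequence, s, e)),
                        ALT = pad, stringsAsFactors = FALSE))
    }
    data.frame(POS = v$position, REF = v$ref_allele, ALT = v$alt_allele,
               stringsAsFactors = FALSE)   # delins: already minimal
  })
  recs <- do.call(rbind, recs)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               paste0("##contig=<ID=chrM,length=", ref$length, ">"),
               paste0("##reference=", ref$name),
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (!is.null(recs) && nrow(recs)) {
    recs <- recs[order(recs$POS), , drop = FALSE]
    writeLines(sprintf("chrM\t%d\t.\t%s\t%s\t.\tPASS\t.",
                       recs$POS, recs$REF, recs$ALT), con)
  }
  invisible(recs)
}
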