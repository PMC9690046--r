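# Pairwise alignment of sample sequences against the reference and
# extraction of normalized variants, heteroplasmic sites and coverage.

#' Alignment scoring parameters
#'
#' @param match,mismatch,gap_open,gap_extend Integer scores; the first base of
#'   a gap costs `gap_open`, each further base `gap_extend`.
#' @param band Half-width of the banded global alignment used for
#'   near-complete genomes.
#' @param complete_min Minimum sequence length treated as a near-complete
#'   genome (aligned globally with banding); shorter sequences are located
#'   with free reference end gaps (semi-global).
#' @param min_identity Identity floor below which a sequence is rejected as
#'   unalignable.
#' @return List of parameters for [align_to_reference()].
#' @export
align_params <- function(match = 1L, mismatch = -2L, gap_open = -4L,
                         gap_extend = -1L, band = 200L,
                         complete_min = 15400L, min_identity = 0.90) {
  list(match = as.integer(match), mismatch = as.integer(mismatch),
       gap_open = as.integer(gap_open), gap_extend = as.integer(gap_extend),
       band = as.integer(band), complete_min = as.integer(complete_min),
       min_identity = min_identity)
}

#' Align one sample sequence to the reference
#'
#' Near-complete sequences (>= `complete_min` nt) are aligned globally with an
#' affine-gap banded dynamic program; shorter fragments (HVR1/HVR2 amplicons
#' and the like) are aligned semi-globally, i.e. located within the reference
#' with free reference end gaps. IUPAC ambiguity codes in the sample score as
#' a match against any of their component bases. If the optimal banded path
#' touches the band boundary the alignment is retried once with a doubled
#' band, then fails.
#'
#' @param seq Sample sequence (character string, A/C/G/T plus IUPAC codes),
#'   length >= 100.
#' @param ref A [load_reference()] object.
#' @param params [align_params()].
#' @param sample_id Identifier carried through to results.
#' @return A `mito_alignment` object: `sample_id`, `mode` ("global-banded" or
#'   "semi-global"), aligned strings `ref_aln`/`qry_aln`, covered reference
#'   span `ref_start`/`ref_end`, `identity`, `score`.
#' @export
align_to_reference <- function(seq, ref, params = align_params(),
                               sample_id = "sample") {
  seq <- toupper(seq)
  if (nchar(seq) < 100L) stop("sequence shorter than 100 nt", call. = FALSE)
  if (grepl("[^ACGTRYSWKMBDHVN]", seq)) {
    stop("sequence contains characters outside A/C/G/T + IUPAC codes",
         call. = FALSE)
  }
  complete <- nchar(seq) >= params$complete_min
  if (complete) {
    res <- cpp_align_banded(ref$sequence, seq, params$match, params$mismatch,
                            params$gap_open, params$gap_extend, params$band)
    if (isTRUE(res$band_edge)) {
      res <- cpp_align_banded(ref$sequence, seq, params$match,
                              params$mismatch, params$gap_open,
                              params$gap_extend, 2L * params$band)
      if (isTRUE(res$band_edge)) {
        stop("band overflow for '", sample_id,
             "' even after doubling the band", call. = FALSE)
      }
    }
    mode <- "global-banded"
  } else {
    res <- cpp_align_semiglobal(ref$sequence, seq, params$match,
                                params$mismatch, params$gap_open,
                                params$gap_extend)
    mode <- "semi-global"
  }

  ra <- strsplit(res$ref_aln, "")[[1]]
  qa <- strsplit(res$qry_aln, "")[[1]]
  is_match <- mapply(function(r, q) {
    if (r == "-" || q == "-") return(FALSE)
    if (q == r || q == "N") return(TRUE)   # N = missing, not a difference
    comp <- IUPAC_HET[q]
    !is.na(comp) && grepl(r, comp, fixed = TRUE)
  }, ra, qa, USE.NAMES = FALSE)
  identity <- mean(is_match)
  if (identity < params$min_identity) {
    stop("unalignable sequence '", sample_id, "': identity ",
         sprintf("%.3f", identity), " below floor ", params$min_identity,
         call. = FALSE)
  }
  ref_consumed <- sum(ra != "-")
  structure(
    list(sample_id = sample_id, mode = mode,
         ref_aln = res$ref_aln, qry_aln = res$qry_aln,
         ref_start = res$ref_start,
         ref_end = res$ref_start + ref_consumed - 1L,
         identity = identity, score = res$score),
    class = "mito_alignment"
  )
}

#' @export
print.mito_alignment <- function(x, ...) {
  cat("<mito_alignment> ", x$sample_id, " [", x$mode, "] ref ",
      x$ref_start, "..", x$ref_end,
      sprintf(", identity %.4f\n", x$identity), sep = "")
  invisible(x)
}

# Column walk shared by the extraction helpers. Calls fn(ref_char, qry_char,
# ref_pos) for every column; ref_pos is the 1-based reference position of the
# column (for insertion columns, the position of the last consumed ref base).
walk_columns <- function(aln, fn) {
  ra <- strsplit(aln$ref_aln, "")[[1]]
  qa <- strsplit(aln$qry_aln, "")[[1]]
  rp <- aln$ref_start - 1L
  for (i in seq_along(ra)) {
    if (ra[i] != "-") rp <- rp + 1L
    fn(ra[i], qa[i], rp)
  }
  invisible(NULL)
}

#' Extract raw differences from an alignment
#'
#' Mismatch columns become substitutions, maximal runs of gap columns one
#' indel each, and adjacent mixed runs (substitution touching an indel) are
#' merged into a single delins candidate before normalization. Columns where
#' the sample carries an IUPAC ambiguity code (or N) are censored here and
#' surface through [detect_heteroplasmy()] instead.
#'
#' @param aln A `mito_alignment`.
#' @param ref The reference object.
#' @return List of raw differences, each `list(start, ref_allele,
#'   alt_allele)`, suitable for [normalize_variant()].
#' @export
extract_variants <- function(aln, ref) {
  ra <- strsplit(aln$ref_aln, "")[[1]]
  qa <- strsplit(aln$qry_aln, "")[[1]]
  diffs <- list()
  run_ref <- character(0); run_alt <- character(0)
  run_start <- NA_integer_   # ref position of first ref base in run
  run_next <- NA_integer_    # ref position the run would insert before
  rp <- aln$ref_start - 1L

  flush <- function() {
    if (is.na(run_start) && length(run_alt) == 0L) return()
    start <- if (!is.na(run_start)) run_start else run_next
    diffs[[length(diffs) + 1L]] <<- list(
      start = start,
      ref_allele = paste(run_ref, collapse = ""),
      alt_allele = paste(run_alt, collapse = ""))
    run_ref <<- character(0); run_alt <<- character(0)
    run_start <<- NA_integer_; run_next <<- NA_integer_
  }

  for (i in seq_along(ra)) {
    r <- ra[i]; q <- qa[i]
    if (r != "-") rp <- rp + 1L
    ambiguous <- q != "-" && !(q %in% c("A", "C", "G", "T"))
    if (ambiguous || (r != "-" && q == r)) {
      flush()
      next
    }
    # difference column
    if (r != "-") {
      if (is.na(run_start) && length(run_alt) == 0L) run_start <- rp
      if (is.na(run_start)) run_start <- rp   # run began as pure insertion
      run_ref <- c(run_ref, r)
    } else if (is.na(run_start) && is.na(run_next)) {
      run_next <- rp + 1L
    }
    if (q != "-") run_alt <- c(run_alt, q)
  }
  flush()
  diffs
}

#' Report heteroplasmic (IUPAC-coded) sites in an alignment
#'
#' Every non-gap sample column carrying an IUPAC ambiguity code other than N
#' is reported with its reference position; N is treated as missing data.
#'
#' @param aln A `mito_alignment`.
#' @return data.frame `position`, `code`, `bases` (component bases, e.g.
#'   "CT" for Y).
#' @export
detect_heteroplasmy <- function(aln) {
  pos <- integer(0); code <- character(0)
  walk_columns(aln, function(r, q, rp) {
    if (r != "-" && q %in% names(IUPAC_HET)) {
      pos[[length(pos) + 1L]] <<- rp
      code[[length(code) + 1L]] <<- q
    }
  })
  data.frame(position = pos, code = code,
             bases = unname(IUPAC_HET[code]),
             stringsAsFactors = FALSE)
}

#' Reference interval covered by an alignment
#'
#' @param aln A `mito_alignment`.
#' @return Integer vector `c(start, end)`: the reference span covered by the
#'   sample, used downstream as "sample is callable at position p".
#' @export
coverage_footprint <- function(aln) {
  c(start = aln$ref_start, end = aln$ref_end)
}

# Project the aligned sample onto reference coordinates: a string of length
# 16,569 with the sample base at matched positions, "-" where the sample has
# a deletion, "." outside the footprint. Insertions are not representable in
# this projection and are dropped.
alignment_profile <- function(aln, ref) {
  chars <- rep(".", ref$length)
  walk_columns(aln, function(r, q, rp) {
    if (r != "-") chars[rp] <<- if (q == "-") "-" else q
  })
  paste(chars, collapse = "")
}

#' Call one sample end to end
#'
#' Aligns, extracts and normalizes variants, annotates regions, types the
#' D310 locus and collects heteroplasmic sites and the coverage footprint.
#'
#' @param seq Sample sequence string.
#' @param ref Reference object.
#' @param sample_id,group Sample metadata carried into the result.
#' @param params [align_params()].
#' @param regions Region table for annotation.
#' @return A `sample_call` object: `sample_id`, `group`, `footprint`,
#'   `variants` (data.frame with label/position/klass/regions), `d310`
#'   ([type_d310()] result, or NULL when the locus is not covered),
#'   `heteroplasmy`, `profile`, `identity`, `mode`.
#' @export
call_sample <- function(seq, ref, sample_id = "sample", group = NA_character_,
                        params = align_params(), regions = region_table()) {
  aln <- align_to_reference(seq, ref, params, sample_id = sample_id)
  raw <- extract_variants(aln, ref)
  vars <- do.call(rbind, lapply(raw, normalize_variant, ref = ref))
  if (is.null(vars)) {
    vars <- variant_record(integer(0), integer(0), character(0),
                           character(0), character(0), character(0))
  }
  vars$regions <- vapply(vars$position, function(p)
    paste(annotate_position(p, regions), collapse = ";"), character(1))
  fp <- coverage_footprint(aln)
  d310 <- if (fp["start"] <= 302L && fp["end"] >= 318L) {
    type_d310(vars, aln, ref)
  } else NULL
  structure(
    list(sample_id = sample_id, group = group,
         footprint = fp, variants = vars,
         d310 = d310, heteroplasmy = detect_heteroplasmy(aln),
         profile = alignment_profile(aln, ref),
         identity = aln$identity, mode = aln$mode),
    class = "sample_call"
  )
}

#' @export
print.sample_call <- function(x, ...) {
  cat("<sample_call> ", x$sample_id,
      if (!is.na(x$group)) paste0(" (", x$group, ")"),
      ": ", nrow(x$variants), " variants, footprint ",
      x$footprint["start"], "..", x$footprint["end"],
      if (!is.null(x$d310)) paste0(", D310 ", x$d310$category), "\n",
      sep = "")
  invisible(x)
}
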