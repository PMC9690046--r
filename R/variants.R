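# Variant representation and HGVS-style normalization against the reference.
#
# A raw difference is (start, ref_allele, alt_allele): ref_allele occupies
# reference positions start..start+nchar(ref_allele)-1; a pure insertion has
# ref_allele == "" and is inserted immediately BEFORE position `start`.
# Normalization trims the shared context, 3'-shifts indels to their most
# distal equivalent placement, folds insertions that duplicate the preceding
# reference run into duplications, and emits the canonical m.-style label.

IUPAC_HET <- c(R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
               B = "CGT", D = "AGT", H = "ACT", V = "ACG")

ref_base <- function(ref, i, len = 1L) substr(ref$sequence, i, i + len - 1L)

variant_record <- function(position, end_position, ref_allele, alt_allele,
                           klass, label) {
  data.frame(label = label, position = position, end_position = end_position,
             ref_allele = ref_allele, alt_allele = alt_allele, klass = klass,
             stringsAsFactors = FALSE)
}

#' Normalize a raw sequence difference into a canonical variant
#'
#' Applies the normalization rules used throughout the pipeline: shared
#' prefix/suffix context is trimmed to a minimal span; insertions and
#' deletions are shifted to their 3'-most equivalent placement (so a C
#' inserted anywhere in the 311-315 poly-C run becomes `m.315dup`, and one in
#' 303-309 becomes `m.309dup`); an insertion whose sequence equals the
#' immediately preceding reference run is emitted as a duplication; a
#' replacement that is neither a pure substitution nor a pure indel becomes a
#' minimal-span delins (e.g. `m.310delinsCCTC`).
#'
#' @param raw List with `start` (1-based), `ref_allele`, `alt_allele` (either
#'   may be `""`; an insertion is placed before `start`).
#' @param ref A [load_reference()] object.
#' @return One-row data.frame: `label`, `position`, `end_position`,
#'   `ref_allele`, `alt_allele`, `klass` (substitution, deletion, duplication,
#'   insertion, delins). `NULL` if the difference vanishes after trimming.
#' @examples
#' ref <- load_reference()
#' normalize_variant(list(start = 312, ref_allele = "", alt_allele = "C"), ref)
#' @export
normalize_variant <- function(raw, ref) {
  start <- as.integer(raw$start)
  ra <- toupper(raw$ref_allele)
  aa <- toupper(raw$alt_allele)
  n <- ref$length

  if (nzchar(ra) &&
      substr(ref$sequence, start, start + nchar(ra) - 1L) != ra) {
    stop("ref allele disagrees with reference at position ", start,
         call. = FALSE)
  }

  # trim shared prefix
  while (nzchar(ra) && nzchar(aa) &&
         substr(ra, 1, 1) == substr(aa, 1, 1)) {
    ra <- substr(ra, 2, nchar(ra)); aa <- substr(aa, 2, nchar(aa))
    start <- start + 1L
  }
  # trim shared suffix
  while (nzchar(ra) && nzchar(aa) &&
         substr(ra, nchar(ra), nchar(ra)) == substr(aa, nchar(aa), nchar(aa))) {
    ra <- substr(ra, 1, nchar(ra) - 1L); aa <- substr(aa, 1, nchar(aa) - 1L)
  }

  if (!nzchar(ra) && !nzchar(aa)) return(NULL)

  if (!nzchar(ra)) {                       # insertion before `start`
    s <- aa
    while (start <= n &&
           substr(ref$sequence, start, start) == substr(s, 1, 1)) {
      s <- paste0(substr(s, 2, nchar(s)), substr(s, 1, 1))
      start <- start + 1L
    }
    L <- nchar(s)
    if (start - 1L >= L &&
        substr(ref$sequence, start - L, start - 1L) == s) {
      lab <- if (L == 1L) sprintf("m.%ddup", start - 1L)
             else sprintf("m.%d_%ddup", start - L, start - 1L)
      return(variant_record(start - L, start - 1L, s, paste0(s, s),
                            "duplication", lab))
    }
    lab <- sprintf("m.%d_%dins%s", start - 1L, start, s)
    return(variant_record(start - 1L, start, "", s, "insertion", lab))
  }

  if (!nzchar(aa)) {                       # deletion of start..end
    end <- start + nchar(ra) - 1L
    while (end < n &&
           substr(ref$sequence, end + 1L, end + 1L) ==
           substr(ref$sequence, start, start)) {
      start <- start + 1L; end <- end + 1L
    }
    ra <- substr(ref$sequence, start, end)
    lab <- if (start == end) sprintf("m.%ddel", start)
           else sprintf("m.%d_%ddel", start, end)
    return(variant_record(start, end, ra, "", "deletion", lab))
  }

  if (nchar(ra) == 1L && nchar(aa) == 1L) {
    return(variant_record(start, start, ra, aa, "substitution",
                          sprintf("m.%d%s>%s", start, ra, aa)))
  }

  end <- start + nchar(ra) - 1L
  lab <- if (start == end) sprintf("m.%ddelins%s", start, aa)
         else sprintf("m.%d_%ddelins%s", start, end, aa)
  variant_record(start, end, ra, aa, "delins", lab)
}

#' Parse a canonical m.-style variant label into an edit
#'
#' Inverse of the label grammar emitted by [normalize_variant()]:
#' `m.{pos}{ref}>{alt}`, `m.{pos}del`, `m.{pos}_{end}del`, `m.{pos}dup`,
#' `m.{pos}_{end}dup`, `m.{pos}_{pos+1}ins{SEQ}`, `m.{pos}delins{SEQ}`,
#' `m.{pos}_{end}delins{SEQ}`.
#'
#' @param label Canonical label string.
#' @param ref A reference object; used to validate/derive reference alleles.
#' @return List `at` (1-based position where the edit starts), `del_len`
#'   (reference bases removed), `ins` (string inserted), plus `position`,
#'   `end_position` of the affected span.
#' @export
parse_variant_label <- function(label, ref) {
  m <- regmatches(label, regexec(
    "^m\\.(\\d+)(?:_(\\d+))?(?:([ACGT])>([ACGT])|delins([ACGT]+)|del|dup|ins([ACGT]+))$",
    label))[[1]]
  if (length(m) == 0L) stop("unparseable variant label: ", label, call. = FALSE)
  p1 <- as.integer(m[2])
  p2 <- if (nzchar(m[3])) as.integer(m[3]) else p1
  if (nzchar(m[4])) {                                   # substitution
    if (ref_base(ref, p1) != m[4])
      stop("label ", label, " disagrees with reference base ",
           ref_base(ref, p1), call. = FALSE)
    return(list(at = p1, del_len = 1L, ins = m[5], position = p1,
                end_position = p1))
  }
  if (nzchar(m[6])) {                                   # delins
    return(list(at = p1, del_len = p2 - p1 + 1L, ins = m[6], position = p1,
                end_position = p2))
  }
  if (nzchar(m[7])) {                                   # insertion
    if (p2 != p1 + 1L)
      stop("insertion label must use flanking positions: ", label,
           call. = FALSE)
    return(list(at = p2, del_len = 0L, ins = m[7], position = p1,
                end_position = p2))
  }
  if (grepl("dup$", label)) {
    unit <- ref_base(ref, p1, p2 - p1 + 1L)
    return(list(at = p2 + 1L, del_len = 0L, ins = unit, position = p1,
                end_position = p2))
  }
  list(at = p1, del_len = p2 - p1 + 1L, ins = "", position = p1,
       end_position = p2)                               # deletion
}

# Apply a set of edits (list of parse_variant_label() results, or rows with
# at/del_len/ins) to a sequence string. Overlapping edits are skipped in input
# order with a record of the conflict; edits are applied right-to-left so
# earlier coordinates stay valid.
apply_edits <- function(sequence, edits, labels = NULL) {
  if (length(edits) == 0L) {
    return(list(sequence = sequence, applied = integer(0),
                skipped = character(0)))
  }
  span_s <- vapply(edits, function(e) e$at, integer(1))
  span_e <- vapply(edits, function(e) e$at + max(e$del_len, 1L) - 1L, integer(1))
  keep <- logical(length(edits))
  occupied <- integer(0)
  skipped <- character(0)
  for (i in seq_along(edits)) {
    span <- seq.int(span_s[i], span_e[i])
    if (any(span %in% occupied)) {
      skipped <- c(skipped,
                   if (!is.null(labels)) labels[i] else as.character(i))
    } else {
      keep[i] <- TRUE
      occupied <- c(occupied, span)
    }
  }
  ord <- order(span_s, decreasing = TRUE)
  for (i in ord) {
    if (!keep[i]) next
    e <- edits[[i]]
    sequence <- paste0(substr(sequence, 1, e$at - 1L), e$ins,
                       substr(sequence, e$at + e$del_len, nchar(sequence)))
  }
  list(sequence = sequence, applied = which(keep), skipped = skipped)
}

# Apply labels to the reference and return the edited sequence (helper used
# by the simulator and by brute-force oracles in the tests).
apply_variant_labels <- function(labels, ref) {
  edits <- lapply(labels, parse_variant_label, ref = ref)
  apply_edits(ref$sequence, edits, labels = labels)
}
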