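# D310 poly-C locus typing. The locus window is fixed at 302-318: one base of
# context each side of the repeat region (C-run at 303-309, T at 310, C-run at
# 311-315), so indels whose 3'-shifted anchors sit at the run edges are still
# captured.

D310_WINDOW <- c(302L, 318L)

D310_CATEGORIES <- c("reference", "m.309dup", "m.309del", "m.310del",
                     "m.310T>C", "m.310delinsCCTC", "m.315dup", "other")

#' Type the D310 poly-C locus of one sample
#'
#' Classifies the sample's D310 locus (positions 302-318) from its normalized
#' variant set: no variants there is the reference allele (C7-T-C5); a single
#' C duplication in the 311-315 run is `m.315dup`; one in the 303-309 run is
#' `m.309dup`; loss of the 310 base is `m.310del`; a single-C loss in the
#' 303-309 run is `m.309del`; a substitution at 310 is `m.310T>C`; the
#' three-base replacement is `m.310delinsCCTC`. Anything else -- including
#' multi-variant tracts and tracts containing a heteroplasmic (IUPAC) base,
#' for which the tract length is undefined -- is the explicit category
#' `other`.
#'
#' @param variants Normalized variant data.frame for the sample (any
#'   positions; the function restricts to the locus window itself).
#' @param aln The sample's `mito_alignment` (used to read the literal tract).
#' @param ref Reference object.
#' @return List `category`, `tract1_len` (C-run starting at 303),
#'   `center` (bases between the two runs), `tract2_len`, `raw_tract`
#'   (the sample's literal bases across the window), `remark`.
#' @export
type_d310 <- function(variants, aln, ref) {
  fp <- coverage_footprint(aln)
  if (fp["start"] > D310_WINDOW[1] || fp["end"] < D310_WINDOW[2]) {
    stop("D310 locus not covered by the sample footprint", call. = FALSE)
  }

  # literal sample bases across the window (insertions included) plus a
  # narrower core (ref 302..316) used for tract-length bookkeeping
  tract_chars <- character(0)
  core_chars <- character(0)
  walk_columns(aln, function(r, q, rp) {
    if (q == "-") return()
    inside <- if (r != "-") rp >= D310_WINDOW[1] && rp <= D310_WINDOW[2]
              else rp >= D310_WINDOW[1] && rp < D310_WINDOW[2]
    core <- if (r != "-") rp >= 302L && rp <= 316L
            else rp >= 302L && rp <= 315L
    if (inside) tract_chars[[length(tract_chars) + 1L]] <<- q
    if (core) core_chars[[length(core_chars) + 1L]] <<- q
  })
  raw_tract <- paste(tract_chars, collapse = "")

  # tract bookkeeping on the repeat proper (drop the one-base context)
  core <- paste(core_chars, collapse = "")
  inner <- substr(core, 2, nchar(core) - 1L)
  t1 <- nchar(sub("^(C*).*$", "\\1", inner))
  rest <- substr(inner, t1 + 1L, nchar(inner))
  center <- sub("^([^C]*).*$", "\\1", rest)
  after <- substr(rest, nchar(center) + 1L, nchar(rest))
  t2 <- nchar(sub("^(C*).*$", "\\1", after))

  remark <- ""
  hets <- detect_heteroplasmy(aln)
  het_in_window <- any(hets$position >= D310_WINDOW[1] &
                       hets$position <= D310_WINDOW[2])

  span_hits <- variants$position <= D310_WINDOW[2] &
    variants$end_position >= D310_WINDOW[1]
  local <- variants[span_hits, , drop = FALSE]

  category <-
    if (het_in_window) {
      remark <- "heteroplasmic base inside the locus; tract length undefined"
      "other"
    } else if (nrow(local) == 0L) {
      "reference"
    } else if (nrow(local) > 1L) {
      "other"
    } else {
      lab <- local$label[1]
      if (lab == "m.315dup") "m.315dup"
      else if (lab == "m.309dup") "m.309dup"
      else if (lab == "m.310del") "m.310del"
      else if (lab == "m.310T>C") "m.310T>C"
      else if (lab == "m.310delinsCCTC") "m.310delinsCCTC"
      else if (lab == "m.309del") "m.309del"
      else "other"
    }

  list(category = category, tract1_len = t1, center = center,
       tract2_len = t2, raw_tract = raw_tract, remark = remark)
}
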