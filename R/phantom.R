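# Phantom-polymorphism screening: systematic sequencing artifacts are flagged
# by a reference-panel frequency score combined with within-cohort recurrence.
# A variant scoring below the threshold that is nonetheless shared by at
# least `min_shared` cohort samples is listed as a rare polymorphism and
# retained; a sub-threshold variant seen in fewer samples is a phantom
# candidate and (under the default policy) excluded from association.

#' Score cohort variants against a reference frequency panel
#'
#' @param calls Long data.frame of cohort calls with at least `sample_id` and
#'   `label` columns (see [calls_table()]).
#' @param panel Named numeric vector or two-column data.frame
#'   (`label`, `count`): occurrence counts of each variant in a reference
#'   panel of mitogenomes. Labels absent from the panel score 0. If `NULL`,
#'   the cohort's own carrier counts are used as the score (self-panel) and a
#'   message is emitted, since self-scoring weakens the rule.
#' @param threshold Panel score below which a variant is suspect (default 3).
#' @param min_shared Minimum number of cohort samples sharing a sub-threshold
#'   variant for it to be retained as "rare" (default 2).
#' @param whitelist Labels never filtered (default the six-variant backbone,
#'   [default_backbone()]); they are reported as "common" regardless of score.
#' @return data.frame `label`, `score`, `cohort_count`, `verdict`
#'   (common / rare / phantom_candidate), `whitelisted`.
#' @export
score_variants <- function(calls, panel = NULL, threshold = 3L,
                           min_shared = 2L, whitelist = default_backbone()) {
  labels <- unique(calls$label)
  cohort_count <- vapply(labels, function(l)
    length(unique(calls$sample_id[calls$label == l])), integer(1))
  if (is.null(panel)) {
    message("score_variants: no reference panel supplied; ",
            "falling back to the cohort's own carrier counts as scores")
    score <- cohort_count
  } else {
    if (is.data.frame(panel)) {
      panel <- stats::setNames(panel$count, panel$label)
    }
    score <- ifelse(labels %in% names(panel), panel[labels], 0)
  }
  whitelisted <- labels %in% whitelist
  verdict <- ifelse(whitelisted | score >= threshold, "common",
                    ifelse(cohort_count >= min_shared, "rare",
                           "phantom_candidate"))
  data.frame(label = labels, score = as.numeric(score),
             cohort_count = cohort_count, verdict = verdict,
             whitelisted = whitelisted, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Remove phantom-candidate calls from a cohort call set
#'
#' @param calls Long call data.frame (`sample_id`, `label`, ...).
#' @param verdicts Output of [score_variants()].
#' @param policy `"exclude"` removes phantom candidates from the returned
#'   calls; `"report-only"` removes nothing. Either way the exclusion report
#'   lists every call that is (or would be) removed.
#' @return List: `calls` (filtered), `excluded` (report of removed calls),
#'   `rare` (labels retained but flagged rare).
#' @export
apply_filter <- function(calls, verdicts,
                         policy = c("exclude", "report-only")) {
  policy <- match.arg(policy)
  phantom <- verdicts$label[verdicts$verdict == "phantom_candidate"]
  hit <- calls$label %in% phantom
  excluded <- calls[hit, c("sample_id", "label"), drop = FALSE]
  row.names(excluded) <- NULL
  kept <- if (policy == "exclude") calls[!hit, , drop = FALSE] else calls
  row.names(kept) <- NULL
  list(calls = kept, excluded = excluded,
       rare = verdicts$label[verdicts$verdict == "rare"])
}

#' Build a reference panel from a simulation truth table
#'
#' Turns the truth table of [simulate_cohort()] into a label -> carrier-count
#' panel (phantom artifact labels are not part of the truth biology and so
#' score 0), giving tests and demonstrations a panel with known properties.
#'
#' @param truth Truth data.frame from [simulate_cohort()].
#' @return Named numeric vector of carrier counts per label.
#' @export
truth_panel <- function(truth) {
  labs <- unlist(strsplit(truth$implanted_labels[
    nzchar(truth$implanted_labels)], ";", fixed = TRUE))
  tab <- table(labs)
  stats::setNames(as.numeric(tab), names(tab))
}
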