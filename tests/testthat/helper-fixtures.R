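library(mitovar)

REF <- load_reference()

# Edit the reference through a label set and return the mutated genome string
# (the simulator's own applicator, exposed for fixture construction).
mutate_ref <- function(labels) {
  mitovar:::apply_variant_labels(labels, REF)$sequence
}

# Replace the D310 core (reference positions 303..315, C7-T-C5) by an
# arbitrary tract string and return the full mutated genome.
with_tract <- function(tract) {
  paste0(substr(REF$sequence, 1, 302), tract,
         substr(REF$sequence, 316, REF$length))
}

# Cut an HVR window out of a (possibly edited) genome; delta corrects the
# right edge for the net length change of edits inside the window.
cut_window <- function(genome, window, delta = 0L) {
  substr(genome, window[1], window[2] + delta)
}

HVR1 <- c(16024L, 16383L)
HVR2 <- c(57L, 372L)

# A small complete-genome cohort shared by the statistics tests: 5 cases,
# 4 controls, no singletons/fragments, deterministic.
small_cohort <- local({
  spec <- cohort_spec(
    n_cases = 5, n_controls = 4,
    variant_freqs = data.frame(
      label = c("m.16519T>C", "m.10398A>G", "m.3010A>G"),
      case_p = c(0.7, 0.3, 0.4), control_p = c(0.3, 0.5, 0.2)),
    d310_mix = data.frame(allele = c("m.315dup", "m.310del"),
                          case_p = c(0.5, 0.3), control_p = c(0.3, 0.5)),
    seed = 42)
  sim <- simulate_cohort(spec, REF)
  cc <- call_cohort(sim$sequences, sim$truth[, c("sample_id", "group")], REF)
  list(spec = spec, sim = sim, samples = cc$samples,
       calls = calls_table(cc$samples),
       footprints = footprints_table(cc$samples))
})

truth_label_sets <- function(truth) {
  lapply(seq_len(nrow(truth)), function(i) {
    tr <- truth[i, ]
    labs <- character(0)
    if (nzchar(tr$implanted_labels))
      labs <- c(labs, strsplit(tr$implanted_labels, ";")[[1]])
    if (nzchar(tr$phantom_labels))
      labs <- c(labs, strsplit(tr$phantom_labels, ";")[[1]])
    if (!is.na(tr$d310_allele) && tr$d310_allele != "reference")
      labs <- c(labs, tr$d310_allele)
    sort(labs)
  })
}

# truth-derived long call table (labels as implanted, no alignment involved)
truth_calls <- function(truth) {
  sets <- truth_label_sets(truth)
  do.call(rbind, lapply(seq_along(sets), function(i) {
    if (length(sets[[i]]) == 0L) return(NULL)
    data.frame(sample_id = truth$sample_id[i], group = truth$group[i],
               label = sets[[i]], stringsAsFactors = FALSE)
  }))
}
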