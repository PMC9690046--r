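# Synthetic case/control mitogenome cohorts with a known implanted truth
# table, so every downstream stage is testable without any sequence download.

#' The common backbone polymorphisms
#'
#' The six near-ubiquitous substitutions used as the default haplogroup-like
#' backbone of simulated cohorts; they appear in the large majority of real
#' deposited mitogenomes and are whitelisted from phantom filtering by
#' default.
#'
#' @return Character vector of six canonical labels.
#' @export
default_backbone <- function() {
  c("m.263A>G", "m.750A>G", "m.1438A>G", "m.4769A>G", "m.8860A>G",
    "m.15326A>G")
}

#' Simulation recipe for a case/control cohort
#'
#' @param n_cases,n_controls Group sizes.
#' @param variant_freqs data.frame `label`, `case_p`, `control_p`: per-variant
#'   carrier probability in each group (independent Bernoulli implants).
#' @param d310_mix data.frame `allele` (a D310 category label such as
#'   "m.315dup" or "m.310del"), `case_p`, `control_p`; each sample draws
#'   exactly one allele categorically, the remainder of the probability mass
#'   going to the reference tract. Per-group sums must be <= 1.
#' @param backbone Labels implanted as a near-fixed backbone; `NULL` disables.
#' @param backbone_p Per-label backbone implant probability (default 0.98,
#'   the carriage rate these polymorphisms show in real cohorts).
#' @param singleton_rate Poisson mean of private random substitutions per
#'   sequence.
#' @param heteroplasmy_rate Probability that a sequence receives one
#'   IUPAC-coded heteroplasmic site.
#' @param phantom_sites data.frame `position`, `alt`, `fraction`: systematic
#'   artifact alleles; each is implanted (same alternate allele, same
#'   position) into `round(fraction * n)` samples drawn across both groups.
#' @param fragment_fraction Fraction of samples emitted as HVR fragments
#'   instead of complete genomes.
#' @param hvr1_p Probability a fragment is HVR1 (16024-16383) rather than
#'   HVR2 (57-372); default 1/3, matching the 12:24 HVR1:HVR2 split of
#'   deposited partial sequences in the breast-cancer cohorts this simulator
#'   emulates.
#' @param seed Integer seed; the same spec (including seed) yields
#'   byte-identical output.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_cases, n_controls,
                        variant_freqs = NULL, d310_mix = NULL,
                        backbone = default_backbone(), backbone_p = 0.98,
                        singleton_rate = 0, heteroplasmy_rate = 0,
                        phantom_sites = NULL, fragment_fraction = 0,
                        hvr1_p = 1 / 3, seed = 1L) {
  n_cases <- as.integer(n_cases); n_controls <- as.integer(n_controls)
  if (n_cases + n_controls <= 0L) {
    stop("cohort must contain at least one sample", call. = FALSE)
  }
  if (is.null(variant_freqs)) {
    variant_freqs <- data.frame(label = character(0), case_p = numeric(0),
                                control_p = numeric(0))
  }
  probs <- c(variant_freqs$case_p, variant_freqs$control_p, backbone_p,
             heteroplasmy_rate, fragment_fraction, hvr1_p)
  if (any(probs < 0 | probs > 1) || singleton_rate < 0) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.null(d310_mix)) {
    if (any(d310_mix$case_p < 0) || any(d310_mix$control_p < 0) ||
        sum(d310_mix$case_p) > 1 + 1e-9 || sum(d310_mix$control_p) > 1 + 1e-9) {
      stop("d310_mix group probabilities must be >= 0 and sum to <= 1",
           call. = FALSE)
    }
  }
  if (!is.null(phantom_sites)) {
    stopifnot(all(c("position", "alt", "fraction") %in% names(phantom_sites)))
  }
  structure(
    list(n_cases = n_cases, n_controls = n_controls,
         variant_freqs = variant_freqs, d310_mix = d310_mix,
         backbone = backbone, backbone_p = backbone_p,
         singleton_rate = singleton_rate,
         heteroplasmy_rate = heteroplasmy_rate,
         phantom_sites = phantom_sites,
         fragment_fraction = fragment_fraction, hvr1_p = hvr1_p,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

HVR_WINDOWS <- list(HVR1 = c(16024L, 16383L), HVR2 = c(57L, 372L))

# restore the caller's RNG state afterwards
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Simulate a case/control mitogenome cohort
#'
#' Draws each sample independently: spec'd variants per Bernoulli(group
#' probability), one D310 allele categorically (applied by editing the
#' 303-315 tract), private singleton substitutions at uniform non-conflicting
#' positions, at most one IUPAC heteroplasmic site, and systematic phantom
#' artifacts shared across groups. A stated fraction of samples is emitted as
#' an HVR1 or HVR2 fragment; fragment truth records list only the implants
#' inside the emitted window. Conflicting implants at overlapping positions
#' are skipped and logged, never silently merged.
#'
#' @param spec A [cohort_spec()].
#' @param ref Reference object.
#' @return List: `sequences` (named [Biostrings::DNAStringSet]), `truth`
#'   (data.frame: `sample_id`, `group`, `implanted_labels` (";"-joined),
#'   `d310_allele`, `phantom_labels`, `het_positions`, `fragment`), and
#'   `conflicts` (log of skipped implants).
#' @export
simulate_cohort <- function(spec, ref) {
  stopifnot(inherits(spec, "cohort_spec"))
  with_seed(spec$seed, {
    n <- spec$n_cases + spec$n_controls
    ids <- c(sprintf("case_%03d", seq_len(spec$n_cases)),
             sprintf("ctrl_%03d", seq_len(spec$n_controls)))
    groups <- rep(c("case", "control"), c(spec$n_cases, spec$n_controls))

    # per-sample spec'd implants
    implants <- vector("list", n)
    for (i in seq_len(n)) {
      p <- if (groups[i] == "case") spec$variant_freqs$case_p
           else spec$variant_freqs$control_p
      lab <- spec$variant_freqs$label[runif(length(p)) < p]
      if (!is.null(spec$backbone)) {
        lab <- c(spec$backbone[runif(length(spec$backbone)) < spec$backbone_p],
                 lab)
      }
      implants[[i]] <- lab
    }

    # one D310 allele per sample
    d310 <- rep("reference", n)
    if (!is.null(spec$d310_mix)) {
      for (i in seq_len(n)) {
        p <- if (groups[i] == "case") spec$d310_mix$case_p
             else spec$d310_mix$control_p
        d310[i] <- sample(c(spec$d310_mix$allele, "reference"),
                          1L, prob = c(p, max(0, 1 - sum(p))))
      }
    }

    # systematic artifacts: same alt allele, same position, a fixed number of
    # carriers drawn across both groups
    phantom <- replicate(n, character(0), simplify = FALSE)
    if (!is.null(spec$phantom_sites)) {
      transition <- c(A = "G", G = "A", C = "T", T = "C")
      for (k in seq_len(nrow(spec$phantom_sites))) {
        ps <- spec$phantom_sites[k, ]
        rb <- ref_base(ref, ps$position)
        alt <- if (is.null(ps$alt) || is.na(ps$alt)) transition[[rb]]
               else ps$alt
        if (rb == alt) stop("phantom alt equals reference base at ",
                            ps$position, call. = FALSE)
        carriers <- sample(n, max(0L, round(ps$fraction * n)))
        lab <- sprintf("m.%d%s>%s", ps$position, rb, alt)
        for (i in carriers) phantom[[i]] <- c(phantom[[i]], lab)
      }
    }

    # fragments
    frag <- rep("none", n)
    is_frag <- runif(n) < spec$fragment_fraction
    frag[is_frag] <- ifelse(runif(sum(is_frag)) < spec$hvr1_p, "HVR1", "HVR2")

    seqs <- character(n)
    truth <- vector("list", n)
    conflicts <- list()
    for (i in seq_len(n)) {
      res <- build_sample_sequence(
        implants[[i]], d310[i], phantom[[i]],
        singleton_rate = spec$singleton_rate,
        heteroplasmy_rate = spec$heteroplasmy_rate,
        fragment = frag[i], ref = ref)
      seqs[i] <- res$sequence
      if (length(res$skipped)) {
        conflicts[[length(conflicts) + 1L]] <- data.frame(
          sample_id = ids[i], label = res$skipped, stringsAsFactors = FALSE)
      }
      truth[[i]] <- data.frame(
        sample_id = ids[i], group = groups[i],
        implanted_labels = paste(res$implanted, collapse = ";"),
        d310_allele = res$d310_allele,
        phantom_labels = paste(res$phantoms, collapse = ";"),
        het_positions = paste(res$het_positions, collapse = ";"),
        fragment = frag[i], stringsAsFactors = FALSE)
    }

    sequences <- Biostrings::DNAStringSet(seqs)
    names(sequences) <- ids
    list(sequences = sequences, truth = do.call(rbind, truth),
         conflicts = if (length(conflicts)) do.call(rbind, conflicts)
                     else data.frame(sample_id = character(0),
                                     label = character(0)))
  })
}

D310_ALLELE_LABELS <- c("m.309dup", "m.309del", "m.310del", "m.310T>C",
                        "m.310delinsCCTC", "m.315dup")

# Assemble one sample sequence. Implant priority: D310 edit > spec'd variants
# > phantom artifacts; singletons and the heteroplasmic site are re-drawn to
# non-conflicting positions.
build_sample_sequence <- function(labels, d310_allele, phantom_labels,
                                  singleton_rate, heteroplasmy_rate,
                                  fragment, ref) {
  window <- if (fragment == "none") c(1L, ref$length)
            else HVR_WINDOWS[[fragment]]

  ordered <- character(0)
  if (d310_allele != "reference") {
    if (!d310_allele %in% D310_ALLELE_LABELS) {
      stop("unknown D310 allele label: ", d310_allele, call. = FALSE)
    }
    ordered <- d310_allele
  }
  ordered <- c(ordered, labels, phantom_labels)

  edits <- lapply(ordered, parse_variant_label, ref = ref)
  spans <- lapply(edits, function(e) {
    seq.int(e$at, e$at + max(e$del_len, 1L) - 1L)
  })

  # restrict to the emitted window
  in_window <- vapply(spans, function(s)
    all(s >= window[1] & s <= window[2]), logical(1))
  # the D310 tract additionally needs its context inside the window
  if (d310_allele != "reference" && fragment != "none") {
    in_window[1] <- window[1] <= 302L && window[2] >= 318L
  }
  ordered_w <- ordered[in_window]
  edits <- edits[in_window]
  spans <- spans[in_window]

  # conflict resolution in priority order
  occupied <- integer(0)
  keep <- logical(length(edits))
  for (i in seq_along(edits)) {
    if (any(spans[[i]] %in% occupied)) next
    keep[i] <- TRUE
    occupied <- c(occupied, spans[[i]])
  }
  skipped <- ordered_w[!keep]
  kept <- ordered_w[keep]
  edits <- edits[keep]

  # singletons: uniform positions, transitions/transversions at random
  n_single <- if (singleton_rate > 0) rpois(1, singleton_rate) else 0L
  singles <- character(0)
  guard <- c(occupied, seq.int(D310_WINDOW[1], D310_WINDOW[2]))
  for (k in seq_len(n_single)) {
    repeat {
      pos <- sample(seq.int(window[1], window[2]), 1L)
      if (!(pos %in% guard)) break
    }
    rb <- ref_base(ref, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    lab <- sprintf("m.%d%s>%s", pos, rb, alt)
    singles <- c(singles, lab)
    edits <- c(edits, list(parse_variant_label(lab, ref)))
    guard <- c(guard, pos)
  }

  # at most one heteroplasmic IUPAC site
  het_positions <- integer(0)
  if (heteroplasmy_rate > 0 && runif(1) < heteroplasmy_rate) {
    repeat {
      pos <- sample(seq.int(window[1], window[2]), 1L)
      if (!(pos %in% guard)) break
    }
    rb <- ref_base(ref, pos)
    other <- sample(setdiff(c("A", "C", "G", "T"), rb), 1L)
    pair <- paste(sort(c(rb, other)), collapse = "")
    code <- names(IUPAC_HET)[match(pair, IUPAC_HET)]
    edits <- c(edits, list(list(at = pos, del_len = 1L, ins = code)))
    het_positions <- pos
    guard <- c(guard, pos)
  }

  # all kept edits lie inside the window, so the window start is unshifted
  # and the end moves by the net length change of the applied edits
  applied <- apply_edits(ref$sequence, edits)
  delta <- sum(vapply(edits, function(e) nchar(e$ins) - e$del_len, numeric(1)))
  sequence <- substr(applied$sequence, window[1], window[2] + delta)

  is_phantom <- kept %in% phantom_labels & !kept %in% labels
  implanted <- c(setdiff(kept, c(D310_ALLELE_LABELS, kept[is_phantom])),
                 singles)
  list(sequence = sequence,
       implanted = implanted,
       phantoms = kept[is_phantom],
       d310_allele = if (fragment == "none" ||
                         (window[1] <= 302L && window[2] >= 318L)) {
         if (d310_allele %in% kept || d310_allele == "reference")
           d310_allele else "reference"
       } else NA_character_,
       het_positions = het_positions,
       skipped = skipped)
}

#' Cohort recipe mirroring a published breast-cancer case-control study
#'
#' Builds the [cohort_spec()] whose per-variant carrier probabilities and
#' D310 allele mix equal the carrier fractions reported in a published
#' breast-cancer mtDNA case-control comparison (78 case and 34 control
#' denominators at the D310 locus; the packaged counts table
#' `carrier_counts.tsv` holds the printed counts). The reported D310 carrier
#' fractions sum to slightly more than 1 within each group because the
#' published denominators are inconsistent; the categorical mix is therefore
#' normalized to sum to 1 (probabilities proportional to the printed counts).
#'
#' @param n_cases,n_controls Group sizes (defaults 78 and 34).
#' @param fragment_fraction,heteroplasmy_rate,singleton_rate,phantom_sites,seed
#'   Passed through to [cohort_spec()]; defaults emulate the study
#'   conditions: no private singletons, one-in-five sequences with a
#'   heteroplasmic site, seven single-carrier systematic artifacts, and a
#'   quarter of samples emitted as HVR fragments.
#' @return A `cohort_spec`.
#' @export
study_mirror_spec <- function(n_cases = 78L, n_controls = 34L,
                              fragment_fraction = 0.25,
                              heteroplasmy_rate = 0.2,
                              singleton_rate = 0,
                              phantom_sites = study_phantom_sites(),
                              seed = 1L) {
  counts <- read_carrier_counts(
    system.file("extdata", "carrier_counts.tsv", package = "mitovar"))
  sub <- counts[!counts$label %in% D310_ALLELE_LABELS, ]
  variant_freqs <- data.frame(
    label = sub$label,
    case_p = sub$case_carriers / sub$case_total,
    control_p = sub$control_carriers / sub$control_total,
    stringsAsFactors = FALSE)
  d <- counts[counts$label %in% D310_ALLELE_LABELS, ]
  case_p <- d$case_carriers / d$case_total
  control_p <- d$control_carriers / d$control_total
  if (sum(case_p) > 1) case_p <- case_p / sum(case_p)
  if (sum(control_p) > 1) control_p <- control_p / sum(control_p)
  d310_mix <- data.frame(allele = d$label, case_p = case_p,
                         control_p = control_p, stringsAsFactors = FALSE)
  cohort_spec(n_cases, n_controls, variant_freqs = variant_freqs,
              d310_mix = d310_mix,
              fragment_fraction = fragment_fraction,
              heteroplasmy_rate = heteroplasmy_rate,
              singleton_rate = singleton_rate,
              phantom_sites = phantom_sites, seed = seed)
}

#' @rdname study_mirror_spec
#' @param n Cohort size the single-carrier fraction is computed against.
#' @export
study_phantom_sites <- function(n = 112L) {
  data.frame(
    position = c(4021L, 5511L, 7028L, 9041L, 11253L, 13263L, 14470L),
    alt = NA_character_,   # transition of the reference base, set at run time
    fraction = 1 / n)
}
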