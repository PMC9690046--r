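# Coverage-aware carrier tables, the Pearson chi-square association test and
# cohort-level summaries (variant spectrum, shared/unique partition,
# between-population differences, MDP report).

#' Flatten a list of sample calls into a long call table
#'
#' @param samples List of `sample_call` objects ([call_sample()]).
#' @return data.frame `sample_id`, `group`, `label`, `position`,
#'   `end_position`, `klass`, `regions`.
#' @export
calls_table <- function(samples) {
  rows <- lapply(samples, function(s) {
    if (nrow(s$variants) == 0L) return(NULL)
    cbind(data.frame(sample_id = s$sample_id, group = s$group,
                     stringsAsFactors = FALSE),
          s$variants[, c("label", "position", "end_position", "klass",
                         "regions")])
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(sample_id = character(0), group = character(0),
                      label = character(0), position = integer(0),
                      end_position = integer(0), klass = character(0),
                      regions = character(0))
  }
  row.names(out) <- NULL
  out
}

#' Coverage footprints of a list of sample calls
#'
#' @param samples List of `sample_call` objects.
#' @return data.frame `sample_id`, `group`, `start`, `end`.
#' @export
footprints_table <- function(samples) {
  do.call(rbind, lapply(samples, function(s)
    data.frame(sample_id = s$sample_id, group = s$group,
               start = unname(s$footprint["start"]),
               end = unname(s$footprint["end"]),
               stringsAsFactors = FALSE)))
}

label_span <- function(label) {
  m <- regmatches(label, regexec("^m\\.(\\d+)(?:_(\\d+))?", label))[[1]]
  p1 <- as.integer(m[2])
  p2 <- if (nzchar(m[3])) as.integer(m[3]) else p1
  c(p1, p2)
}

#' Carrier/non-carrier 2x2 table for one variant
#'
#' Denominators are coverage-aware: a sample counts toward a group total only
#' if its footprint covers the variant's full reference span; it counts as a
#' carrier if its (filtered) call set contains the label.
#'
#' @param calls Long call table ([calls_table()]), usually phantom-filtered.
#' @param footprints Footprint table ([footprints_table()]).
#' @param label Canonical variant label.
#' @param groups Optional data.frame `sample_id`, `group`; defaults to the
#'   group column of `footprints`.
#' @return A `carrier_table` object: `label`, `case_carriers`, `case_total`,
#'   `control_carriers`, `control_total`.
#' @export
carrier_table <- function(calls, footprints, label, groups = NULL) {
  if (is.null(groups)) {
    groups <- footprints[, c("sample_id", "group")]
  }
  span <- label_span(label)
  fp <- merge(footprints[, c("sample_id", "start", "end")], groups,
              by = "sample_id")
  callable <- fp[fp$start <= span[1] & fp$end >= span[2], ]
  carriers <- unique(calls$sample_id[calls$label == label])
  ct <- function(g) {
    tot <- sum(callable$group == g)
    car <- sum(callable$group == g & callable$sample_id %in% carriers)
    c(car, tot)
  }
  cs <- ct("case"); co <- ct("control")
  if (cs[2] == 0L || co[2] == 0L) {
    stop("no callable samples in one group for ", label, call. = FALSE)
  }
  structure(list(label = label, case_carriers = cs[1], case_total = cs[2],
                 control_carriers = co[1], control_total = co[2]),
            class = "carrier_table")
}

#' Pearson chi-square test on a carrier 2x2 table
#'
#' Computes the uncorrected Pearson statistic `sum((O-E)^2/E)` over the
#' carrier/non-carrier x case/control table, with the upper-tail p-value from
#' the chi-square distribution with 1 df. No continuity correction is applied
#' (the corrected statistic does not reproduce published mtDNA carrier-table
#' p-values, see the package vignette). The significance flag uses alpha =
#' 0.05.
#'
#' @param t A `carrier_table` or list with `case_carriers`, `case_total`,
#'   `control_carriers`, `control_total`.
#' @return List `statistic`, `df` (1), `p_value`, `significant`.
#' @examples
#' chi_square(list(case_carriers = 27, case_total = 78,
#'                 control_carriers = 21, control_total = 34))
#' @export
chi_square <- function(t) {
  o <- matrix(c(t$case_carriers, t$case_total - t$case_carriers,
                t$control_carriers, t$control_total - t$control_carriers),
              nrow = 2,
              dimnames = list(c("carrier", "noncarrier"),
                              c("case", "control")))
  if (any(o < 0)) stop("negative cell count", call. = FALSE)
  if (any(rowSums(o) == 0) || any(colSums(o) == 0)) {
    stop("degenerate table: zero row or column margin", call. = FALSE)
  }
  e <- outer(rowSums(o), colSums(o)) / sum(o)
  stat <- sum((o - e)^2 / e)
  p <- pchisq(stat, df = 1, lower.tail = FALSE)
  list(statistic = stat, df = 1L, p_value = p, significant = p < 0.05)
}

#' Spectrum of variant sharing
#'
#' Histogram of distinct variants by the number of sequences carrying them:
#' how many variants are private (k = 1), how many appear in exactly k
#' sequences, and so on.
#'
#' @param calls Long call table.
#' @param scope `"combined"`, `"cases"` or `"controls"`.
#' @return data.frame `k` (number of carrying sequences), `n_variants`.
#' @export
variant_spectrum <- function(calls,
                             scope = c("combined", "cases", "controls")) {
  scope <- match.arg(scope)
  sub <- switch(scope,
                combined = calls,
                cases = calls[calls$group == "case", ],
                controls = calls[calls$group == "control", ])
  if (nrow(sub) == 0L) return(data.frame(k = integer(0),
                                         n_variants = integer(0)))
  per_label <- tapply(sub$sample_id, sub$label,
                      function(x) length(unique(x)))
  tab <- table(factor(per_label, levels = seq_len(max(per_label))))
  out <- data.frame(k = as.integer(names(tab)),
                    n_variants = as.integer(tab))
  out[out$n_variants > 0, , drop = FALSE]
}

#' Partition variant labels by group occurrence
#'
#' @param calls Long call table.
#' @return List of three disjoint character vectors: `cases_only`,
#'   `controls_only`, `shared`; their union is all distinct labels.
#' @export
shared_unique_partition <- function(calls) {
  in_case <- unique(calls$label[calls$group == "case"])
  in_ctrl <- unique(calls$label[calls$group == "control"])
  list(cases_only = sort(setdiff(in_case, in_ctrl)),
       controls_only = sort(setdiff(in_ctrl, in_case)),
       shared = sort(intersect(in_case, in_ctrl)))
}

#' Between-population sequence differences
#'
#' Computes, over the reference positions callable in every sample of both
#' groups, the classical between-population summaries: count of polymorphic
#' loci, fixed differences (every A-sample carries one allele and every
#' B-sample another), polymorphisms shared by both groups, loci monomorphic
#' in one group but polymorphic in the other, and the average number of
#' differing positions between one sequence from each group.
#'
#' @param samples_a,samples_b Lists of `sample_call` objects.
#' @return List `polymorphic_loci`, `fixed_differences`,
#'   `shared_polymorphisms`, `monomorphic_a_polymorphic_b`,
#'   `monomorphic_b_polymorphic_a`, `avg_pairwise_diff`, `n_positions`.
#' @export
population_diffs <- function(samples_a, samples_b) {
  if (length(samples_a) == 0L || length(samples_b) == 0L) {
    stop("both groups need at least one sequence", call. = FALSE)
  }
  all_s <- c(samples_a, samples_b)
  lo <- max(vapply(all_s, function(s) s$footprint[["start"]], numeric(1)))
  hi <- min(vapply(all_s, function(s) s$footprint[["end"]], numeric(1)))
  if (lo > hi) stop("no overlapping callable region", call. = FALSE)

  mat_for <- function(samples) {
    do.call(rbind, lapply(samples, function(s)
      strsplit(substr(s$profile, lo, hi), "")[[1]]))
  }
  A <- mat_for(samples_a); B <- mat_for(samples_b)

  poly <- function(col) length(unique(col)) > 1L
  a_poly <- apply(A, 2, poly); b_poly <- apply(B, 2, poly)
  combined_poly <- apply(rbind(A, B), 2, poly)
  fixed <- !a_poly & !b_poly & A[1, ] != B[1, ]

  pair_diffs <- outer(seq_len(nrow(A)), seq_len(nrow(B)),
                      Vectorize(function(i, j) sum(A[i, ] != B[j, ])))

  list(polymorphic_loci = sum(combined_poly),
       fixed_differences = sum(fixed),
       shared_polymorphisms = sum(a_poly & b_poly),
       monomorphic_a_polymorphic_b = sum(!a_poly & b_poly),
       monomorphic_b_polymorphic_a = sum(a_poly & !b_poly),
       avg_pairwise_diff = mean(pair_diffs),
       n_positions = hi - lo + 1L)
}

#' Association report for variants in MDP regions
#'
#' One row per called variant whose anchor falls inside a
#' mitochondrial-derived-peptide window (MOTS-c, Humanin, SHLP1-6), with both
#' group carrier frequencies and the chi-square p-value ("-" where the table
#' is degenerate); MDP regions without any variant contribute a placeholder
#' row.
#'
#' @param calls Long (filtered) call table.
#' @param footprints Footprint table.
#' @param regions Region table; only rows with category "MDP" are used.
#' @return data.frame `region`, `label`, `case_pct`, `control_pct`, `p`
#'   (formatted; "-" where untestable or absent).
#' @export
mdp_report <- function(calls, footprints, regions = region_table()) {
  mdp <- regions[regions$category == "MDP", ]
  rows <- list()
  for (i in seq_len(nrow(mdp))) {
    r <- mdp[i, ]
    hit <- calls$position >= r$start & calls$position <= r$end
    labs <- sort(unique(calls$label[hit]))
    if (length(labs) == 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        region = r$name, label = "-", case_pct = "-", control_pct = "-",
        p = "-", stringsAsFactors = FALSE)
      next
    }
    for (lab in labs) {
      ct <- carrier_table(calls, footprints, lab)
      p <- tryCatch(sprintf("%.3f", chi_square(ct)$p_value),
                    error = function(e) "-")
      rows[[length(rows) + 1L]] <- data.frame(
        region = r$name, label = lab,
        case_pct = sprintf("%.1f (%d/%d)",
                           100 * ct$case_carriers / ct$case_total,
                           ct$case_carriers, ct$case_total),
        control_pct = sprintf("%.1f (%d/%d)",
                              100 * ct$control_carriers / ct$control_total,
                              ct$control_carriers, ct$control_total),
        p = p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

read_carrier_counts <- function(path) {
  read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
}

#' Row-wise chi-square over a carrier-count table
#'
#' Applies the uncorrected Pearson test to each row of a table of carrier
#' counts -- e.g. counts transcribed from a published association table -- so
#' printed p-values can be regenerated directly from printed counts without
#' any sequence data. Rows with a zero margin get `NA` (reported as "-").
#'
#' @param counts data.frame (or path to a TSV) with columns `label`,
#'   `case_carriers`, `case_total`, `control_carriers`, `control_total`;
#'   extra columns (e.g. `region`, `dbsnp`) are passed through.
#' @return The input with appended `statistic`, `p_value`, `significant`.
#' @examples
#' table_stats(data.frame(label = "m.310del", case_carriers = 27,
#'                        case_total = 78, control_carriers = 21,
#'                        control_total = 34))
#' @export
table_stats <- function(counts) {
  if (is.character(counts)) counts <- read_carrier_counts(counts)
  res <- lapply(seq_len(nrow(counts)), function(i) {
    row <- counts[i, ]
    tryCatch(chi_square(row),
             error = function(e) list(statistic = NA_real_,
                                      p_value = NA_real_,
                                      significant = NA))
  })
  counts$statistic <- vapply(res, `[[`, numeric(1), "statistic")
  counts$p_value <- vapply(res, `[[`, numeric(1), "p_value")
  counts$significant <- vapply(res, `[[`, logical(1), "significant")
  counts
}
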