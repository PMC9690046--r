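# Carrier tables, the uncorrected Pearson test and cohort-level summaries.

test_that("chi_square matches chisq.test and the erfc identity", {
  set.seed(2024)
  for (k in 1:300) {
    ct <- list(case_carriers = sample(1:40, 1), case_total = 50,
               control_carriers = sample(1:25, 1), control_total = 30)
    res <- chi_square(ct)
    m <- matrix(c(ct$case_carriers, ct$case_total - ct$case_carriers,
                  ct$control_carriers,
                  ct$control_total - ct$control_carriers), 2)
    oracle <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(res$statistic, unname(oracle$statistic), tolerance = 1e-12)
    expect_lt(abs(res$p_value - oracle$p.value), 1e-10)
    # erfc identity for 1 df: p = 2 * Phi(-sqrt(X2))
    expect_lt(abs(res$p_value - 2 * pnorm(-sqrt(res$statistic))), 1e-10)
    expect_identical(res$significant, res$p_value < 0.05)
  }
})

test_that("proportional and degenerate tables behave as contracted", {
  res <- chi_square(list(case_carriers = 10, case_total = 20,
                         control_carriers = 5, control_total = 10))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  expect_error(chi_square(list(case_carriers = 0, case_total = 20,
                               control_carriers = 0, control_total = 10)),
               "degenerate")
})

test_that("carrier denominators are coverage-aware", {
  calls <- small_cohort$calls
  fps <- small_cohort$footprints
  # all samples are complete genomes here, so totals equal group sizes
  ct <- carrier_table(calls, fps, "m.16519T>C")
  expect_equal(ct$case_total, 5)
  expect_equal(ct$control_total, 4)
  # restrict footprints to HVR2 fragments: no sample covers 16519 any more
  fps2 <- fps; fps2$start <- 57L; fps2$end <- 372L
  expect_error(carrier_table(calls, fps2, "m.16519T>C"), "callable")
  # forced carriage: probability 1 in cases, 0 in controls
  spec <- cohort_spec(n_cases = 4, n_controls = 3,
                      variant_freqs = data.frame(label = "m.16519T>C",
                                                 case_p = 1, control_p = 0),
                      backbone = NULL, seed = 9)
  sim <- simulate_cohort(spec, REF)
  calls3 <- truth_calls(sim$truth)
  fps3 <- data.frame(sample_id = sim$truth$sample_id,
                     group = sim$truth$group, start = 1L, end = 16569L)
  ct3 <- carrier_table(calls3, fps3, "m.16519T>C")
  expect_equal(ct3$case_carriers, ct3$case_total)
  expect_equal(ct3$control_carriers, 0)
})

test_that("carrier fractions on a called cohort match the implanted truth", {
  calls <- small_cohort$calls
  fps <- small_cohort$footprints
  truth <- truth_calls(small_cohort$sim$truth)
  for (lab in c("m.16519T>C", "m.10398A>G", "m.315dup", "m.310del")) {
    ct <- carrier_table(calls, fps, lab)
    want_case <- length(unique(truth$sample_id[truth$label == lab &
                                               truth$group == "case"]))
    want_ctrl <- length(unique(truth$sample_id[truth$label == lab &
                                               truth$group == "control"]))
    expect_equal(ct$case_carriers, want_case, info = lab)
    expect_equal(ct$control_carriers, want_ctrl, info = lab)
  }
})

test_that("variant spectrum histograms sharing counts correctly", {
  calls <- data.frame(
    sample_id = c("a", "b", "c", "a", "a"),
    group = c("case", "case", "control", "case", "case"),
    label = c("m.1A>G", "m.1A>G", "m.1A>G", "m.2C>T", "m.3G>A"))
  sp <- variant_spectrum(calls)
  expect_equal(sp$n_variants[sp$k == 1], 2)
  expect_equal(sp$n_variants[sp$k == 3], 1)
  # invariant: sum k * n_variants = total distinct (sample, label) calls
  expect_equal(sum(sp$k * sp$n_variants), 5)
  # scope restriction
  sp_ctrl <- variant_spectrum(calls, scope = "controls")
  expect_equal(sum(sp_ctrl$n_variants), 1)
  # all-private and all-shared degenerate shapes
  priv <- data.frame(sample_id = c("a", "b"), group = "case",
                     label = c("m.1A>G", "m.2C>T"))
  expect_equal(variant_spectrum(priv)$k, 1)
  shared <- data.frame(sample_id = c("a", "b", "c"), group = "case",
                       label = "m.1A>G")
  expect_equal(variant_spectrum(shared),
               data.frame(k = 3L, n_variants = 1L),
               ignore_attr = TRUE)
})

test_that("spectrum of a singleton-free called cohort equals the truth", {
  sp <- variant_spectrum(small_cohort$calls)
  truth <- truth_calls(small_cohort$sim$truth)
  per_label <- tapply(truth$sample_id, truth$label,
                      function(x) length(unique(x)))
  want <- as.data.frame(table(as.integer(per_label)),
                        stringsAsFactors = FALSE)
  expect_equal(sp$n_variants, want$Freq)
  expect_equal(sp$k, as.integer(want$Var1))
})

test_that("labels partition into cases-only / controls-only / shared", {
  calls <- data.frame(
    sample_id = c("a", "b", "c", "d"),
    group = c("case", "control", "case", "control"),
    label = c("m.1A>G", "m.1A>G", "m.2C>T", "m.3G>A"))
  p <- shared_unique_partition(calls)
  expect_identical(p$shared, "m.1A>G")
  expect_identical(p$cases_only, "m.2C>T")
  expect_identical(p$controls_only, "m.3G>A")
  all_labs <- unique(calls$label)
  expect_setequal(c(p$shared, p$cases_only, p$controls_only), all_labs)
  # permutation invariance in sample order
  p2 <- shared_unique_partition(calls[sample(nrow(calls)), ])
  expect_identical(p, p2)
  empty <- calls[0, ]
  p3 <- shared_unique_partition(empty)
  expect_true(all(lengths(p3) == 0))
})

test_that("population differences match a brute-force oracle", {
  # identical groups: all zero
  s_ref <- call_sample(REF$sequence, REF, sample_id = "r1", group = "case")
  pd0 <- population_diffs(list(s_ref), list(s_ref))
  expect_equal(pd0$polymorphic_loci, 0)
  expect_equal(pd0$fixed_differences, 0)
  expect_equal(pd0$avg_pairwise_diff, 0)

  # forced fixed difference
  s_alt <- call_sample(mutate_ref("m.16519T>C"), REF, sample_id = "a1",
                       group = "control")
  pd1 <- population_diffs(list(s_ref, s_ref), list(s_alt, s_alt))
  expect_equal(pd1$fixed_differences, 1)
  expect_equal(pd1$avg_pairwise_diff, 1)
  expect_equal(pd1$shared_polymorphisms, 0)

  # random cohort vs independent Hamming loops
  samples <- small_cohort$samples
  A <- samples[1:5]; B <- samples[6:9]
  pd <- population_diffs(A, B)
  profs_a <- vapply(A, function(s) s$profile, character(1))
  profs_b <- vapply(B, function(s) s$profile, character(1))
  total <- 0
  for (x in profs_a) for (y in profs_b) {
    total <- total + sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  expect_equal(pd$avg_pairwise_diff, total / (length(A) * length(B)))
  # partition identity: combined-polymorphic loci decompose into shared,
  # group-exclusive, and between-group fixed differences
  expect_equal(pd$polymorphic_loci,
               pd$shared_polymorphisms + pd$monomorphic_a_polymorphic_b +
                 pd$monomorphic_b_polymorphic_a + pd$fixed_differences)
})

test_that("MDP report covers peptide windows and marks empty ones", {
  calls <- small_cohort$calls
  fps <- small_cohort$footprints
  rep <- mdp_report(calls, fps)
  # m.3010A>G sits inside SHLP6 (2990..3052)
  expect_true(any(rep$region == "SHLP6" & rep$label == "m.3010A>G"))
  # variants outside every MDP window never appear
  expect_false(any(grepl("16519", rep$label)))
  # windows without variants yield placeholder rows
  expect_true(any(rep$region == "MOTS-c" & rep$label == "-"))
  expect_true(all(c("region", "label", "case_pct", "control_pct", "p") %in%
                  names(rep)))
})

test_that("table_stats reproduces p-values straight from printed counts", {
  res <- table_stats(data.frame(
    label = c("m.310del", "m.1346A>G"),
    case_carriers = c(27, 1), case_total = c(78, 52),
    control_carriers = c(21, 0), control_total = c(34, 34)))
  expect_equal(res$p_value[1], 0.0076, tolerance = 0.01)
  expect_equal(res$p_value[2], 0.416, tolerance = 0.002)
  # zero-margin rows are reported as NA, not fatal
  res2 <- table_stats(data.frame(label = "x", case_carriers = 0,
                                 case_total = 10, control_carriers = 0,
                                 control_total = 10))
  expect_true(is.na(res2$p_value))
})
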