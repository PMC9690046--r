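# Synthetic cohort generator: determinism, forced/identity cases, fragment
# windows, conflict logging and frequency calibration.

test_that("identical specs give byte-identical cohorts", {
  spec <- study_mirror_spec(n_cases = 8, n_controls = 6, seed = 99)
  f1 <- tempfile(); f2 <- tempfile()
  p1 <- simulate_to_files(spec, f1)
  p2 <- simulate_to_files(spec, f2)
  expect_identical(readLines(p1$fasta), readLines(p2$fasta))
  expect_identical(readLines(p1$truth), readLines(p2$truth))
  # and a different seed changes the output
  p3 <- simulate_to_files(study_mirror_spec(n_cases = 8, n_controls = 6,
                                            seed = 100), tempfile())
  expect_false(identical(readLines(p1$fasta), readLines(p3$fasta)))
})

test_that("an all-zero spec reproduces the reference exactly", {
  spec <- cohort_spec(n_cases = 3, n_controls = 2, backbone = NULL)
  sim <- simulate_cohort(spec, REF)
  expect_true(all(as.character(sim$sequences) == REF$sequence))
  expect_true(all(sim$truth$implanted_labels == ""))
  expect_true(all(sim$truth$d310_allele == "reference"))
})

test_that("probability-one implants are present in every sequence", {
  spec <- cohort_spec(
    n_cases = 6, n_controls = 4,
    variant_freqs = data.frame(label = "m.16519T>C",
                               case_p = 1, control_p = 0),
    backbone = default_backbone(), backbone_p = 1, seed = 5)
  sim <- simulate_cohort(spec, REF)
  cases <- sim$truth$group == "case"
  expect_true(all(vapply(as.character(sim$sequences[cases]),
                         function(s) substr(s, 16519, 16519) == "C",
                         logical(1))))
  expect_true(all(vapply(as.character(sim$sequences[!cases]),
                         function(s) substr(s, 16519, 16519) == "T",
                         logical(1))))
  for (labs in strsplit(sim$truth$implanted_labels, ";")) {
    expect_true(all(default_backbone() %in% labs))
  }
})

test_that("the default backbone is the six common polymorphisms", {
  expect_setequal(default_backbone(),
                  c("m.263A>G", "m.750A>G", "m.1438A>G", "m.4769A>G",
                    "m.8860A>G", "m.15326A>G"))
  spec <- cohort_spec(n_cases = 4, n_controls = 0, backbone = NULL, seed = 2)
  sim <- simulate_cohort(spec, REF)
  expect_false(any(grepl("m\\.263A>G", sim$truth$implanted_labels)))
})

test_that("no truth record carries both m.310del and m.315dup", {
  spec <- study_mirror_spec(n_cases = 40, n_controls = 20, seed = 31)
  sim <- simulate_cohort(spec, REF)
  expect_false(any(sim$truth$d310_allele %in% "m.310del" &
                   sim$truth$d310_allele %in% "m.315dup"))
  # the allele is one categorical draw per sample
  expect_true(all(sim$truth$d310_allele %in%
                  c("reference", "m.309dup", "m.309del", "m.310del",
                    "m.310T>C", "m.310delinsCCTC", "m.315dup", NA)))
})

test_that("fragments are emitted at their HVR windows with restricted truth", {
  spec <- cohort_spec(
    n_cases = 30, n_controls = 0,
    variant_freqs = data.frame(label = c("m.16519T>C", "m.263A>G"),
                               case_p = c(1, 1), control_p = c(0, 0)),
    backbone = NULL, fragment_fraction = 1, seed = 8)
  sim <- simulate_cohort(spec, REF)
  expect_true(all(sim$truth$fragment %in% c("HVR1", "HVR2")))
  for (i in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[i, ]
    s <- as.character(sim$sequences[[i]])
    labs <- strsplit(tr$implanted_labels, ";")[[1]]
    if (tr$fragment == "HVR1") {
      expect_equal(nchar(s), 360)          # no indels inside this window
      expect_identical(labs, "m.16519T>C"[FALSE])  # 16519 lies outside HVR1
      expect_true(is.na(tr$d310_allele))
    } else {
      expect_identical(labs, "m.263A>G")   # 263 inside HVR2; 16519 outside
      expect_identical(substr(s, 263 - 57 + 1, 263 - 57 + 1), "G")
      expect_false(is.na(tr$d310_allele))
    }
  }
  # roughly one third HVR1
  expect_gt(mean(sim$truth$fragment == "HVR1"), 0.1)
  expect_lt(mean(sim$truth$fragment == "HVR1"), 0.6)
})

test_that("conflicting implants are skipped and logged, never merged", {
  spec <- cohort_spec(
    n_cases = 5, n_controls = 0,
    variant_freqs = data.frame(label = "m.310T>C", case_p = 1, control_p = 0),
    d310_mix = data.frame(allele = "m.310delinsCCTC", case_p = 1,
                          control_p = 0),
    backbone = NULL, seed = 3)
  sim <- simulate_cohort(spec, REF)
  expect_equal(nrow(sim$conflicts), 5)
  expect_true(all(sim$conflicts$label == "m.310T>C"))
  expect_true(all(sim$truth$d310_allele == "m.310delinsCCTC"))
})

test_that("empty cohorts and invalid probabilities are rejected", {
  expect_error(cohort_spec(0, 0), "at least one")
  expect_error(cohort_spec(2, 2, variant_freqs = data.frame(
    label = "m.16519T>C", case_p = 1.2, control_p = 0)), "\\[0, 1\\]")
  expect_error(cohort_spec(2, 2, d310_mix = data.frame(
    allele = c("m.315dup", "m.310del"), case_p = c(0.7, 0.6),
    control_p = c(0.1, 0.1))), "sum")
})

test_that("generated carrier fractions track the recipe frequencies", {
  # 200 independent seeds of the study-mirror recipe: the mean truth-table
  # carrier fraction of m.315dup among D310-callable cases stays within
  # three binomial standard errors of the published 60.2%
  fracs <- vapply(1:200, function(s) {
    spec <- study_mirror_spec(seed = s)
    sim <- simulate_cohort(spec, REF)
    tr <- sim$truth[sim$truth$group == "case" & !is.na(sim$truth$d310_allele), ]
    mean(tr$d310_allele == "m.315dup")
  }, numeric(1))
  p <- mean(fracs)
  se <- sqrt(0.602 * (1 - 0.602) / (200 * 78))
  expect_lt(abs(p - 0.602), 3 * se)
})
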