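# Normalization of raw differences into canonical labels: 3'-shifting,
# duplication folding, delins merging, and the VCF left-anchored conversion.

test_that("C insertions anywhere in a poly-C run normalize to the 3' dup", {
  # inserting a C before any position of the 311..315 run is the same edit
  for (at in 311:316) {
    v <- normalize_variant(list(start = at, ref_allele = "",
                                alt_allele = "C"), REF)
    expect_identical(v$label, "m.315dup")
    expect_identical(v$klass, "duplication")
  }
  for (at in 303:310) {
    v <- normalize_variant(list(start = at, ref_allele = "",
                                alt_allele = "C"), REF)
    expect_identical(v$label, "m.309dup")
  }
})

test_that("deletions and replacements at D310 get their canonical names", {
  v <- normalize_variant(list(start = 310, ref_allele = "T",
                              alt_allele = ""), REF)
  expect_identical(v$label, "m.310del")
  v <- normalize_variant(list(start = 310, ref_allele = "T",
                              alt_allele = "CCTC"), REF)
  expect_identical(v$label, "m.310delinsCCTC")
  expect_identical(v$klass, "delins")
  # deleting any C of the first run shifts to the run's 3' end
  for (at in 303:309) {
    v <- normalize_variant(list(start = at, ref_allele = "C",
                                alt_allele = ""), REF)
    expect_identical(v$label, "m.309del")
  }
})

test_that("shared context is trimmed to a minimal span", {
  # a 3-base replacement differing only at its middle base is a substitution
  ra <- substr(REF$sequence, 5000, 5002)
  aa <- ra
  mid <- substr(ra, 2, 2)
  substr(aa, 2, 2) <- setdiff(c("A", "C", "G", "T"), mid)[1]
  v <- normalize_variant(list(start = 5000, ref_allele = ra,
                              alt_allele = aa), REF)
  expect_identical(v$klass, "substitution")
  expect_identical(v$position, 5001L)
  # identical alleles vanish
  expect_null(normalize_variant(list(start = 5000, ref_allele = ra,
                                     alt_allele = ra), REF))
})

test_that("normalization is semantics-preserving and idempotent", {
  set.seed(101)
  raws <- list()
  for (k in 1:30) {
    pos <- sample(1000:16000, 1)
    type <- sample(c("sub", "del", "ins"), 1)
    raws[[k]] <- switch(type,
      sub = {
        rb <- substr(REF$sequence, pos, pos)
        list(start = pos, ref_allele = rb,
             alt_allele = sample(setdiff(c("A", "C", "G", "T"), rb), 1))
      },
      del = list(start = pos,
                 ref_allele = substr(REF$sequence, pos,
                                     pos + sample(0:2, 1)),
                 alt_allele = ""),
      ins = list(start = pos, ref_allele = "",
                 alt_allele = paste(sample(c("A", "C", "G", "T"),
                                           sample(1:3, 1), replace = TRUE),
                                    collapse = "")))
  }
  apply_raw <- function(raw) {
    # direct application of the raw difference, independent of the label path
    del_len <- nchar(raw$ref_allele)
    paste0(substr(REF$sequence, 1, raw$start - 1L), raw$alt_allele,
           substr(REF$sequence, raw$start + del_len, REF$length))
  }
  for (raw in raws) {
    v <- normalize_variant(raw, REF)
    if (is.null(v)) next
    edited_label <- mutate_ref(v$label)
    expect_identical(edited_label, apply_raw(raw), info = v$label)
    # idempotence: normalizing the label's own raw form returns the label
    e <- parse_variant_label(v$label, REF)
    v2 <- normalize_variant(list(
      start = if (e$del_len > 0) e$at else e$at,
      ref_allele = substr(REF$sequence, e$at, e$at + e$del_len - 1L),
      alt_allele = e$ins), REF)
    expect_identical(v2$label, v$label)
  }
})

test_that("emitted indels are maximally 3'-shifted", {
  set.seed(202)
  for (k in 1:25) {
    pos <- sample(500:16000, 1)
    raw <- if (k %% 2 == 0) {
      list(start = pos, ref_allele = substr(REF$sequence, pos, pos),
           alt_allele = "")
    } else {
      list(start = pos, ref_allele = "",
           alt_allele = sample(c("A", "C", "G", "T"), 1))
    }
    v <- normalize_variant(raw, REF)
    if (v$klass == "deletion") {
      # shifting one further right must change the deleted content
      expect_false(substr(REF$sequence, v$end_position + 1L,
                          v$end_position + 1L) ==
                   substr(REF$sequence, v$position, v$position),
                   info = v$label)
    } else if (v$klass %in% c("insertion", "duplication")) {
      ins_at <- v$end_position + if (v$klass == "duplication") 1L else 0L
      ins_seq <- if (v$klass == "duplication") v$ref_allele else v$alt_allele
      expect_false(substr(REF$sequence, ins_at, ins_at) ==
                   substr(ins_seq, 1, 1), info = v$label)
    }
  }
})

test_that("labels parse back to the edit they describe", {
  labs <- c("m.16519T>C", "m.310del", "m.315dup", "m.309dup",
            "m.310delinsCCTC", "m.2145del", "m.263A>G")
  for (lab in labs) {
    e <- parse_variant_label(lab, REF)
    v <- normalize_variant(list(
      start = e$at,
      ref_allele = substr(REF$sequence, e$at, e$at + e$del_len - 1L),
      alt_allele = e$ins), REF)
    expect_identical(v$label, lab)
  }
  expect_error(parse_variant_label("m.notalabel", REF), "unparseable")
  expect_error(parse_variant_label("m.16519A>C", REF), "disagrees")
})

test_that("VCF emission left-anchors indels and round-trips through vcfR", {
  skip_if_not_installed("vcfR")
  # m.310del and m.315dup must live in different samples (their combination
  # is string-equivalent to m.310T>C)
  s_del <- call_sample(mutate_ref("m.310del"), REF, sample_id = "del")
  recs_del <- write_sample_vcf(s_del, REF, tempfile(fileext = ".vcf"))
  expect_true(any(recs_del$POS == 309 & recs_del$REF == "CT" &
                  recs_del$ALT == "C"))

  labs <- c("m.16519T>C", "m.315dup", "m.2145del")
  seq <- mutate_ref(labs)
  s <- call_sample(seq, REF, sample_id = "vcfcheck")
  path <- tempfile(fileext = ".vcf")
  recs <- write_sample_vcf(s, REF, path)

  # canonical left-anchored form of the poly-C duplication
  expect_true(any(recs$POS == 310 & recs$REF == "T" & recs$ALT == "TC"))

  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  expect_equal(nrow(fix), length(labs))
  # applying the VCF records to the reference reproduces the sample sequence
  pos <- as.integer(fix$POS)
  ord <- order(pos, decreasing = TRUE)
  rebuilt <- REF$sequence
  for (i in ord) {
    expect_identical(substr(rebuilt, pos[i], pos[i] + nchar(fix$REF[i]) - 1L),
                     fix$REF[i])
    rebuilt <- paste0(substr(rebuilt, 1, pos[i] - 1L), fix$ALT[i],
                      substr(rebuilt, pos[i] + nchar(fix$REF[i]),
                             nchar(rebuilt)))
  }
  expect_identical(rebuilt, seq)
})
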