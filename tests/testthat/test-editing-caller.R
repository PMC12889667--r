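test_that("mismatch classification is strand-aware A>G / T>C", {
  expect_equal(classify_mismatch("A", "G", "+"), "A_to_I")
  expect_equal(classify_mismatch("T", "C", "-"), "A_to_I")
  expect_equal(classify_mismatch("C", "T", "+"), "other")
  expect_equal(classify_mismatch("A", "G", "-"), "other")
  expect_equal(classify_mismatch("A", "A", "+"), "none")
  expect_error(classify_mismatch("N", "G", "+"), "base")
  # vectorized
  expect_equal(
    classify_mismatch(c("A", "T"), c("G", "C"), c("+", "-")),
    c("A_to_I", "A_to_I")
  )
})

test_that("a clean candidate is called with the right level; homoplasmy is guarded", {
  ann <- one_gene_annotation("+")
  p10 <- pileup_row(50, "A", "+", c(90, 0, 10, 0), baseq = 30)
  cs <- call_sample(p10, ann)
  expect_equal(sum(cs$status == "call"), 1)
  expect_equal(cs$edit_level[1], 0.10)
  expect_equal(cs$mismatch[1], "A>G")
  p100 <- pileup_row(50, "A", "+", c(0, 0, 100, 0), baseq = 30)
  cs <- call_sample(p100, ann)
  expect_equal(cs$status, "rejected")
  expect_equal(cs$reason, "homoplasmic_SNV")
})

test_that("the minus-strand signature is T>C and evaluated on the sense stratum", {
  ann <- mito_annotation(
    data.frame(name = c("HG", "LG"), start = c(600L, 1L), end = c(700L, 500L),
               strand = c("+", "-"), class = "mRNA-like"),
    length = 1000L
  )
  p <- pileup_row(50, "T", "-", c(0, 10, 0, 90), baseq = 30)
  cs <- call_sample(p, ann)
  expect_equal(sum(cs$status == "call"), 1)
  expect_equal(cs$mismatch[1], "A>G") # reported on the transcript strand
  expect_equal(cs$strand[1], "-")
  # same counts on the antisense stratum are not evidence for LG
  p_anti <- pileup_row(50, "T", "+", c(0, 10, 0, 90), baseq = 30)
  expect_equal(nrow(call_sample(p_anti, ann)), 0)
})

test_that("rejection carries the first failing filter in the fixed order", {
  ann <- one_gene_annotation("+")
  params <- caller_params(min_baseq = 25, min_coverage = 50)
  # not_A_to_I dominates low quality
  p <- pileup_row(10, "C", "+", c(0, 5, 0, 5), baseq = 10)
  expect_equal(call_sample(p, ann, params)$reason, "not_A_to_I")
  # low_quality dominates low coverage
  p <- pileup_row(10, "A", "+", c(5, 0, 5, 0), baseq = 10)
  expect_equal(call_sample(p, ann, params)$reason, "low_quality")
  # low_coverage dominates low support
  p <- pileup_row(10, "A", "+", c(20, 0, 1, 0), baseq = 30)
  expect_equal(call_sample(p, ann, params)$reason, "low_coverage")
  # low_support (1 edited read) at adequate coverage
  p <- pileup_row(10, "A", "+", c(99, 0, 1, 0), baseq = 30)
  expect_equal(call_sample(p, ann, params)$reason, "low_support")
})

test_that("threshold comparisons are inclusive at the boundary", {
  ann <- one_gene_annotation("+")
  params <- caller_params(min_baseq = 25, min_coverage = 100,
                          min_edited_reads = 2, max_edit_level = 0.9)
  # exactly at min_coverage, min_edited_reads and min_baseq -> call
  p <- pileup_row(10, "A", "+", c(98, 0, 2, 0), baseq = 25)
  expect_equal(call_sample(p, ann, params)$status, "call")
  # exactly at max_edit_level -> still a call (maxima inclusive)
  p <- pileup_row(10, "A", "+", c(10, 0, 90, 0), baseq = 30)
  expect_equal(call_sample(p, ann, params)$status, "call")
})

test_that("overlapping genes on the same strand raise an ambiguity error", {
  expect_error(
    mito_annotation(
      data.frame(name = c("G1", "G1"), start = c(1L, 50L), end = c(100L, 150L),
                 strand = "+", class = "x"), length = 1000L
    ),
    "unique"
  )
  ann <- mito_annotation(
    data.frame(name = c("G1", "G2"), start = c(1L, 50L), end = c(100L, 150L),
               strand = "+", class = "x"),
    length = 1000L
  )
  p <- pileup_row(60, "A", "+", c(90, 0, 10, 0))
  expect_error(call_sample(p, ann), "ambiguity")
})

test_that("error-free calls are a subset of truth sites (exact precision with cohort filter)", {
  co <- simulate_cohort(toy_config(seq_error_rate = 0, snv_density = 2,
                                   n_samples_per_group = 5L))
  cs <- lapply(co$pileups, call_sample, annotation = co$annotation)
  cs <- apply_cohort_filters(cs)
  keys <- truth_site_keys(co$truth)
  for (s in cs) expect_true(all(call_keys(s) %in% keys))
  # injected homoplasmic SNVs never survive
  snv_keys <- unlist(lapply(c("+", "-"), function(st) paste(co$truth$snv_sites$pos, st)))
  for (s in cs) expect_length(intersect(call_keys(s), snv_keys), 0)
})

test_that("cohort filters reclassify shared high-VAF sites and non-recurrent calls", {
  ann <- one_gene_annotation("+")
  mk <- function(sid, g, a) {
    p <- pileup_row(50, "A", "+", c(a, 0, g, 0), baseq = 30, sample_id = sid)
    call_sample(p, ann)
  }
  # edit_level 0.95 in 9 of 10 samples -> cohort SNV everywhere
  cs <- c(lapply(1:9, function(i) mk(paste0("s", i), 95, 5)),
          list(mk("s10", 50, 50)))
  filt <- apply_cohort_filters(cs)
  for (s in filt) {
    expect_true(all(s$status == "rejected"))
    expect_true(all(s$reason == "cohort_SNV"))
  }
  # recurrence: a site called in exactly 1 sample is removed when enabled
  solo <- list(
    mk("s1", 10, 90),
    call_sample(pileup_row(60, "A", "+", c(90, 0, 10, 0), sample_id = "s2"), ann)
  )
  filt <- apply_cohort_filters(solo, recurrence = TRUE)
  expect_true(all(vapply(filt, function(s) all(s$reason == "non_recurrent"), TRUE)))
  filt_off <- apply_cohort_filters(solo, recurrence = FALSE)
  expect_true(all(vapply(filt_off, function(s) all(s$status == "call"), TRUE)))
})

test_that("raising min_edited_reads never increases the number of calls", {
  co <- simulate_cohort(toy_config(n_samples_per_group = 3L))
  n_calls <- function(thr) {
    cs <- lapply(co$pileups, call_sample, annotation = co$annotation,
                 params = caller_params(min_edited_reads = thr))
    sum(vapply(cs, function(s) sum(s$status == "call"), 1))
  }
  counts <- vapply(c(1, 2, 4, 8), n_calls, 1)
  expect_true(all(diff(counts) <= 0))
})

test_that("calling is deterministic for fixed inputs", {
  co <- simulate_cohort(toy_config(n_samples_per_group = 2L))
  c1 <- call_sample(co$pileups[[1]], co$annotation)
  c2 <- call_sample(co$pileups[[1]], co$annotation)
  expect_identical(c1, c2)
})

test_that("the mismatch spectrum is A>G dominated when edits are present", {
  expect_true(all(mismatch_spectrum(list())$spectrum == 0))
  ann <- one_gene_annotation("+")
  cs <- call_sample(pileup_row(10, "A", "+", c(90, 0, 10, 0)), ann)
  sp <- mismatch_spectrum(cs)
  expect_equal(sp$ag_fraction, 1.0)
  expect_equal(sum(sp$spectrum), 1)
  expect_length(sp$spectrum, 12)
  # simulation with sequencing error: A>G strictly dominates each other class
  co <- simulate_cohort(toy_config(seq_error_rate = 0.01,
                                   n_samples_per_group = 5L))
  calls <- lapply(co$pileups, call_sample, annotation = co$annotation)
  sp <- mismatch_spectrum(calls)
  expect_true(all(sp$spectrum["A>G"] > sp$spectrum[names(sp$spectrum) != "A>G"]))
})

test_that("call sets serialize and read back", {
  co <- simulate_cohort(toy_config(n_samples_per_group = 2L))
  cs <- lapply(co$pileups, call_sample, annotation = co$annotation)
  f <- tempfile(fileext = ".tsv")
  write_calls(cs, f)
  back <- read_calls(f)
  expect_equal(nrow(back), sum(vapply(cs, nrow, 1L)))
  expect_true(all(c("sample_id", "pos", "strand", "edit_level", "status") %in%
                    names(back)))
})
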