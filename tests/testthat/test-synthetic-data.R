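test_that("configuration validation names the offending field", {
  expect_error(toy_config(base_edit_rate = 1.5), "base_edit_rate")
  expect_error(toy_config(depth_mean = -1), "depth_mean")
  expect_error(toy_config(n_samples_per_group = 0), "n_samples_per_group")
  expect_error(toy_config(group_edit_multiplier = c(2, 1)), "reference")
  expect_error(toy_config(latent_assoc_strength = 2), "latent_assoc_strength")
})

test_that("aging defaults are a pure function with ordered groups and reference multiplier 1", {
  c1 <- aging_scenario_defaults()
  c2 <- aging_scenario_defaults()
  expect_identical(c1, c2)
  expect_identical(c1$group_labels, c("young", "middle", "old"))
  expect_identical(unname(c1$group_edit_multiplier), c(1, 1, 2))
  expect_equal(c1$group_edit_multiplier[[1]], 1.0)
  expect_equal(c1$annotation$length, 16569L)
})

test_that("with no mutation process every pileup position is pure reference", {
  cfg <- toy_config(base_edit_rate = 0, seq_error_rate = 0, snv_density = 0,
                    edit_site_density = 0, n_samples_per_group = 2L)
  co <- simulate_cohort(cfg)
  expect_equal(nrow(co$truth$edit_sites), 0)
  for (p in co$pileups) {
    cnt <- as.matrix(p[c("count_A", "count_C", "count_G", "count_T")])
    ref_reads <- cnt[cbind(seq_len(nrow(p)), match(p$ref, c("A", "C", "G", "T")))]
    expect_equal(ref_reads, rowSums(cnt))
  }
})

test_that("identical config and seed give byte-identical on-disk cohorts", {
  cfg <- toy_config(n_samples_per_group = 2L)
  d1 <- file.path(tempdir(), "cohort_rep1")
  d2 <- file.path(tempdir(), "cohort_rep2")
  unlink(c(d1, d2), recursive = TRUE)
  write_cohort(simulate_cohort(cfg), d1)
  write_cohort(simulate_cohort(cfg), d2)
  f1 <- list.files(d1, recursive = TRUE)
  f2 <- list.files(d2, recursive = TRUE)
  expect_identical(f1, f2)
  for (f in f1) {
    expect_identical(
      unname(tools::md5sum(file.path(d1, f))),
      unname(tools::md5sum(file.path(d2, f))),
      label = paste("checksum of", f)
    )
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("doubling depth_mean doubles realized mean depth (Monte Carlo over 20+ samples)", {
  mean_depth <- function(dm, seed) {
    co <- simulate_cohort(toy_config(
      depth_mean = dm, n_samples_per_group = 10L, seed = seed,
      antisense_fraction = 0, seq_error_rate = 0
    ))
    mean(co$truth$per_sample$true_depth)
  }
  r <- mean_depth(200, seed = 7) / mean_depth(100, seed = 7)
  expect_lt(abs(r / 2 - 1), 0.05)
})

test_that("error-free, SNV-free cohorts place every non-reference base at a truth edit site", {
  co <- simulate_cohort(toy_config(seq_error_rate = 0, snv_density = 0,
                                   n_samples_per_group = 3L))
  keys <- truth_site_keys(co$truth)
  es <- co$truth$edit_sites
  for (p in co$pileups) {
    cnt <- as.matrix(p[c("count_A", "count_C", "count_G", "count_T")])
    ref_i <- match(p$ref, c("A", "C", "G", "T"))
    nonref <- rowSums(cnt) - cnt[cbind(seq_len(nrow(p)), ref_i)]
    mism <- p[nonref > 0, ]
    # edits ride on sense reads, so the stratum equals the site's strand
    expect_true(all(paste(mism$pos, mism$strand) %in% keys))
  }
  # and the reference base is A on the annotated transcript strand
  refs <- sapply(seq_len(nrow(es)), function(i) {
    row <- co$pileups[[1]][co$pileups[[1]]$pos == es$pos[i] &
                             co$pileups[[1]]$strand == es$strand[i], ]
    if (nrow(row) == 0) NA_character_ else row$ref[1]
  })
  expected <- ifelse(es$strand == "+", "A", "T")
  expect_true(all(refs == expected, na.rm = TRUE))
})

test_that("realized depth variability matches depth_sigma within 25% at n >= 50", {
  co <- simulate_cohort(toy_config(
    n_samples_per_group = 60L, group_labels = "one",
    group_edit_multiplier = 1, depth_sigma = 0.25, seed = 11
  ))
  sd_log <- sd(log(co$truth$per_sample$true_depth))
  expect_lt(abs(sd_log - 0.25) / 0.25, 0.25)
})

test_that("signature-coupled expression panel attains the configured latent correlation", {
  co <- simulate_cohort(toy_config(
    n_samples_per_group = 100L, group_labels = "one",
    group_edit_multiplier = 1, latent_assoc_strength = 0.6, seed = 5
  ))
  z <- co$truth$per_sample$latent_z
  coupled <- co$expression$gene_sets$signature_coupled
  rs <- apply(co$expression$counts[coupled, ], 1, function(x) cor(x, z))
  expect_lt(abs(mean(abs(rs)) - 0.6), 0.15)
  # background genes stay uncoupled
  bg <- co$expression$gene_sets$background
  rs_bg <- apply(co$expression$counts[bg, ], 1, function(x) cor(x, z))
  expect_lt(mean(abs(rs_bg)), 0.15)
})

test_that("edit and SNV truth sites are disjoint and clinical values respect their ranges", {
  co <- simulate_cohort(toy_config(snv_density = 3, n_samples_per_group = 10L))
  expect_length(intersect(co$truth$edit_sites$pos, co$truth$snv_sites$pos), 0)
  cl <- co$clinical
  expect_true(all(cl$mmse >= 0 & cl$mmse <= 30))
  expect_true(all(cl$braak %in% 0:6))
  expect_true(all(cl$cerad %in% 0:3))
  expect_true(all(grepl("^e[234]/e[234]$", cl$apoe)))
  # monotone group dependence on average
  m <- tapply(cl$mmse, cl$group, mean)[unique(cl$group)]
  expect_gte(m[["ref"]], m[["alt"]])
})

test_that("antisense reads appear at the configured per-gene fraction", {
  co <- simulate_cohort(toy_config(
    antisense_fraction = 0.18, n_samples_per_group = 10L,
    group_labels = "one", group_edit_multiplier = 1, seed = 9
  ))
  af <- antisense_fraction(co$pileups, co$annotation)
  m <- mean(af$antisense_fraction[af$gene == "RNR2L"], na.rm = TRUE)
  expect_lt(abs(m - 0.18), 0.03)
})
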