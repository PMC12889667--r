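# frozen normality fixtures (standard-normal and strongly bimodal draws)
NORMAL_FIXTURE <- c(
  1.162685, -0.585924, 1.785465, -1.332594, -0.446567, 0.569606,
  -2.889718, -0.869018, -0.461703, -0.555541, -0.020135, -0.150382,
  -0.628127, 1.323221, -1.521351, -0.437428, 0.970578, 0.028223,
  -0.085782, 0.389214
)
BIMODAL_FIXTURE <- c(
  -3.025376, -2.74788, -3.139045, -3.165251, -2.779188, -3.032364,
  -3.051087, -3.3265, -3.903316, -3.177952, -3.227938, -2.912385,
  3.12642, 2.611653, 3.020786, 2.756088, 3.453256, 2.918517, 3.467476,
  2.928795, 3.384937, 2.997153, 2.879975, 3.006596
)

test_that("Shapiro-Wilk screen matches the oracle fixture and flags degeneracy", {
  r <- shapiro_wilk(NORMAL_FIXTURE)
  expect_equal(r$W, 0.9635628019, tolerance = 1e-6)
  expect_equal(r$p, 0.6172033658, tolerance = 1e-6)
  expect_lt(shapiro_wilk(BIMODAL_FIXTURE)$p, 0.05)
  d <- shapiro_wilk(rep(1, 10))
  expect_true(d$degenerate)
  expect_error(shapiro_wilk(c(1, 2)), "3 <= n")
})

test_that("Welch ANOVA: null identity, t-squared identity and reference agreement", {
  x <- NORMAL_FIXTURE
  # groups copied from one vector: F = 0, p = 1
  r0 <- welch_anova(list(a = x, b = x, c = x))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
  # two equal-size groups: Welch F equals the square of Welch's t
  set.seed(4)
  g1 <- rnorm(15); g2 <- rnorm(15, 0.8)
  w <- welch_anova(list(g1 = g1, g2 = g2))
  tt <- t.test(g1, g2) # Welch two-sample t
  expect_equal(w$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(w$df2, unname(tt$parameter), tolerance = 1e-10)
  expect_equal(w$p, tt$p.value, tolerance = 1e-10)
  # three unequal-variance groups against the reference implementation
  set.seed(9)
  gl <- list(a = rnorm(12, 0, 1), b = rnorm(20, 0.5, 2), c = rnorm(8, 1, 0.5))
  w3 <- welch_anova(gl)
  ref <- oneway.test(y ~ g, data = data.frame(
    y = unlist(gl), g = rep(names(gl), lengths(gl))
  ), var.equal = FALSE)
  expect_equal(w3$F, unname(ref$statistic), tolerance = 1e-8)
  expect_equal(w3$df2, unname(ref$parameter[2]), tolerance = 1e-8)
  expect_equal(w3$p, ref$p.value, tolerance = 1e-8)
  expect_error(welch_anova(list(a = rep(1, 5), b = rnorm(5))), "zero-variance")
})

test_that("Brown-Forsythe ANOVA reduces to Welch t-squared for two groups", {
  set.seed(10)
  g1 <- rnorm(14); g2 <- rnorm(18, 1, 3)
  bf <- brown_forsythe_anova(list(g1 = g1, g2 = g2))
  tt <- t.test(g1, g2)
  expect_equal(bf$F, unname(tt$statistic)^2, tolerance = 1e-10)
  r0 <- brown_forsythe_anova(list(a = NORMAL_FIXTURE, b = NORMAL_FIXTURE))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)
})

test_that("omnibus p never increases when one group's mean is scaled up", {
  set.seed(3)
  base <- list(a = rnorm(20), b = rnorm(20), c = rnorm(20))
  ps <- vapply(c(0, 0.5, 1, 2), function(shift) {
    gl <- base
    gl$c <- gl$c + shift
    welch_anova(gl)$p
  }, 1)
  expect_true(all(diff(ps) <= 0))
})

test_that("Welch and Brown-Forsythe agree on homoscedastic nulls", {
  set.seed(77)
  ps <- replicate(300, {
    gl <- list(a = rnorm(30), b = rnorm(30), c = rnorm(30))
    c(welch_anova(gl)$p, brown_forsythe_anova(gl)$p)
  })
  # the two tests reject the same nulls at alpha = 0.05 to within 0.02
  expect_lt(abs(mean(ps[1, ] < 0.05) - mean(ps[2, ] < 0.05)), 0.02)
  expect_gt(cor(ps[1, ], ps[2, ]), 0.99)
})

test_that("Dunnett T3: k = 1 identity, identical-group nullity, dominance", {
  set.seed(5)
  g1 <- rnorm(12); g2 <- rnorm(12, 1)
  d <- dunnett_t3(list(g1 = g1, g2 = g2))
  expect_equal(nrow(d), 1)
  expect_equal(d$p_adj, d$p, tolerance = 1e-4) # single comparison
  di <- dunnett_t3(list(a = NORMAL_FIXTURE, b = NORMAL_FIXTURE + 1e-9))
  expect_equal(di$p_adj, 1, tolerance = 1e-4)
  set.seed(6)
  gl <- list(a = rnorm(10), b = rnorm(14, 0.5, 2), c = rnorm(12, 1, 0.3))
  d3 <- dunnett_t3(gl)
  expect_equal(nrow(d3), 3)
  expect_true(all(d3$p_adj >= d3$p - 1e-12))
  expect_true(all(d3$p_adj <= 1 & d3$p_adj >= 0))
  # Sidak and Bonferroni alternates also dominate the raw p
  for (m in c("sidak", "bonferroni")) {
    alt <- posthoc_pairwise(gl, method = m)
    expect_true(all(alt$p_adj >= alt$p - 1e-12))
  }
})

test_that("group_comparison assembles summaries, normality, omnibus and post hoc", {
  set.seed(12)
  values <- c(rnorm(20, 10, 1), rnorm(20, 10, 2), rnorm(20, 14, 3))
  groups <- rep(c("x", "y", "z"), each = 20)
  gc <- group_comparison(values, groups)
  expect_equal(gc$groups$n, rep(20L, 3))
  expect_equal(gc$groups$sem, gc$groups$sd / sqrt(20))
  expect_equal(nrow(gc$posthoc), 3)
  expect_lt(gc$omnibus$welch$p, 0.05)
  expect_lt(gc$omnibus$brown_forsythe$p, 0.05)
  expect_false(any(is.na(gc$normality$p)))
})

test_that("relative expression divides group means by the reference mean", {
  m <- matrix(c(30, 20, 40, 20), nrow = 1,
              dimnames = list("g1", paste0("s", 1:4)))
  groups <- setNames(c("trt", "ctl", "trt", "ctl"), colnames(m))
  # equal library sizes: sf = 1 each, trt mean 35, ctl mean 20
  rel <- relative_expression(m, groups, "ctl", library_sf = rep(1, 4))
  expect_equal(rel$ratio[rel$group == "trt"], 1.75)
  expect_equal(rel$ratio[rel$group == "ctl"], 1.0)
  expect_error(relative_expression(m, groups, "nope"), "unknown group")
  # zero reference mean is flagged, not divided
  m0 <- rbind(m, g2 = c(5, 0, 5, 0))
  rel0 <- relative_expression(m0, groups, "ctl", library_sf = rep(1, 4))
  expect_true(is.na(rel0$ratio[rel0$gene == "g2" & rel0$group == "trt"]))
  expect_true(rel0$reference_zero[rel0$gene == "g2" & rel0$group == "trt"])
})

test_that("an injected two-fold group effect is recovered by the expression ratio", {
  set.seed(31)
  n <- 30
  mu <- 200
  counts <- cbind(
    matrix(rnbinom(20 * n, mu = mu, size = 30), nrow = 20),
    matrix(rnbinom(20 * n, mu = 2 * mu, size = 30), nrow = 20)
  )
  rownames(counts) <- paste0("g", 1:20)
  colnames(counts) <- paste0("s", seq_len(2 * n))
  groups <- rep(c("ref", "high"), each = n)
  rel <- relative_expression(counts, groups, "ref", library_sf = rep(1, 2 * n))
  expect_true(mean(rel$ratio[rel$group == "high"]) > 1.8 &&
                mean(rel$ratio[rel$group == "high"]) < 2.2)
})
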