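# independent enumeration oracle for the hypergeometric overlap:
# fix set1 = {1..n1}, enumerate every n2-subset of {1..N}, count those
# sharing >= k members with set1
enum_overlap_p <- function(N, n1, n2, k) {
  if (n2 == 0) return(if (k <= 0) 1 else 0)
  subsets <- utils::combn(N, n2)
  overlaps <- colSums(subsets <= n1)
  mean(overlaps >= k)
}

test_that("gene retention requires reads in strictly more than half the samples", {
  m <- rbind(
    six = c(rep(1, 6), rep(0, 4)),
    five = c(rep(1, 5), rep(0, 5)),
    zero = rep(0, 10)
  )
  colnames(m) <- paste0("s", 1:10)
  kept <- retain_genes(m)
  expect_true("six" %in% kept)
  expect_false("five" %in% kept)
  expect_false("zero" %in% kept)
  # configurable floor
  m2 <- rbind(lowcounts = rep(1, 10))
  colnames(m2) <- paste0("s", 1:10)
  expect_length(retain_genes(m2, floor = 1), 0)
})

test_that("correlation panel recovers exact and fixture correlations", {
  x <- as.numeric(1:20)
  mat <- rbind(same = x, anti = -2 * x + 50)
  colnames(mat) <- paste0("s", 1:20)
  panel <- correlate_panel(setNames(x, colnames(mat)), mat, adjustment = "none")
  expect_equal(panel$r[panel$variable == "same"], 1)
  expect_equal(panel$r[panel$variable == "anti"], -1)
  expect_lt(panel$p[1], 1e-10)
  # hand-sized anticorrelation example
  p3 <- correlate_panel(c(1, 2, 3), rbind(v = c(6, 4, 2)), adjustment = "none")
  expect_equal(p3$r, -1)
  # seed-pinned bivariate normal, rho = 0.5, n = 50: r near rho and p equal
  # to the closed-form t transform
  set.seed(15)
  t50 <- rnorm(50)
  y50 <- 0.5 * t50 + sqrt(1 - 0.25) * rnorm(50)
  panel <- correlate_panel(t50, rbind(y = y50), adjustment = "none")
  expect_lt(abs(panel$r - 0.5), 0.2)
  r <- panel$r
  tstat <- r * sqrt((50 - 2) / (1 - r^2))
  expect_equal(panel$p, 2 * pt(-abs(tstat), 48), tolerance = 1e-10)
  expect_equal(panel$n, 50L)
  expect_error(correlate_panel(rep(1, 50), rbind(y = y50)), "zero-variance")
})

test_that("correlation is invariant to affine transforms of the target", {
  set.seed(2)
  x <- rnorm(30)
  mat <- rbind(a = rnorm(30), b = rnorm(30, x))
  colnames(mat) <- paste0("s", 1:30)
  p1 <- correlate_panel(x, mat, adjustment = "none")
  p2 <- correlate_panel(3 * x + 7, mat, adjustment = "none")
  p3 <- correlate_panel(-2 * x, mat, adjustment = "none")
  expect_equal(p2$r, p1$r, tolerance = 1e-12)
  expect_equal(p3$r, -p1$r, tolerance = 1e-12)
  expect_equal(p3$p, p1$p, tolerance = 1e-12)
})

test_that("pairwise-complete handling reports per-row n and drops n < 3 rows", {
  x <- c(1, 2, 3, 4, NA, 6)
  mat <- rbind(full = c(2, 4, 6, 8, 10, 12), holey = c(1, 2, NA, NA, 5, NA))
  colnames(mat) <- paste0("s", 1:6)
  panel <- correlate_panel(x, mat, adjustment = "none")
  expect_equal(panel$n[panel$variable == "full"], 5L)
  expect_false("holey" %in% panel$variable) # only 2 complete pairs
})

test_that("BH and Bonferroni adjustments follow their formulas", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bonferroni_adjust(rep(0.03, 4)), rep(0.12, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bonferroni_adjust(c(-0.1)), "\\[0, 1\\]")
  # BH is monotone in sorted order and permutation-equivariant
  set.seed(1)
  p <- runif(50)
  adj <- bh_adjust(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-15))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm]), adj[perm])
  expect_true(all(adj >= p))
})

test_that("intersection of three panels yields consistent Venn regions", {
  set.seed(44)
  x <- rnorm(40)
  mat <- rbind(
    g1 = x + rnorm(40, 0, 0.2), g2 = x + rnorm(40, 0, 0.2),
    g3 = rnorm(40), g4 = rnorm(40)
  )
  colnames(mat) <- paste0("s", 1:40)
  pa <- correlate_panel(x, mat, adjustment = "none")
  # three identical panels: triple intersection = each significant set
  res <- intersect_criteria(list(A = pa, B = pa, C = pa))
  expect_setequal(res$triple, pa$variable[pa$p < 0.05])
  expect_equal(sum(res$regions), length(unique(unlist(res$sets))))
  # disjoint significant sets -> empty triple intersection
  pb <- pa; pb$p <- 1 - pa$p
  res2 <- intersect_criteria(list(A = pa, B = pb, C = pa))
  expect_length(res2$triple, 0)
  # mismatched universes are rejected
  pc <- pa[-1, ]
  expect_error(intersect_criteria(list(A = pa, B = pa, C = pc)), "universe")
})

test_that("hypergeometric overlap matches the worked examples and enumeration", {
  r <- hypergeom_overlap(10, paste0("g", 1:5), paste0("g", 1:5))
  expect_equal(r$p, 1 / choose(10, 5), tolerance = 1e-12)
  r2 <- hypergeom_overlap(4, c("a", "b"), c("a", "b"))
  expect_equal(r2$p, 1 / 6, tolerance = 1e-12)
  # k = 0 upper tail is certain
  r0 <- hypergeom_overlap(letters[1:10], letters[1:3], letters[4:6])
  expect_equal(r0$p, 1.0)
  expect_error(hypergeom_overlap(letters[1:4], c("a", "z"), "b"), "outside universe")
  # enumeration oracle sweep at small N (full N <= 12 sweep lives in the
  # acceptance suite)
  for (N in c(5, 8)) {
    for (n1 in 0:N) {
      for (n2 in 0:N) {
        u <- paste0("g", seq_len(N))
        s1 <- utils::head(u, n1)
        s2 <- rev(u)[seq_len(n2)]
        got <- hypergeom_overlap(u, s1, s2)
        want <- enum_overlap_p(N, n1, n2, got$k)
        expect_equal(got$p, want, tolerance = 1e-12)
      }
    }
  }
})
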