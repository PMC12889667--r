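as_group_list <- function(values, groups = NULL) {
  if (is.list(values)) {
    gl <- lapply(values, as.numeric)
    if (is.null(names(gl))) names(gl) <- paste0("group", seq_along(gl))
  } else {
    stopifnot(!is.null(groups), length(groups) == length(values))
    gl <- split(as.numeric(values), factor(groups, levels = unique(groups)))
  }
  gl
}

#' Shapiro-Wilk normality screen
#'
#' Thin wrapper around the standard Shapiro-Wilk test with explicit
#' handling of degenerate (zero-variance) input.
#'
#' @param values Numeric vector, `3 <= n <= 5000`.
#' @return list with `W`, `p` and `degenerate` (TRUE when the input has
#'   zero variance, in which case `W` and `p` are `NA`).
#' @export
shapiro_wilk <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) {
    return(list(W = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  t <- shapiro.test(values)
  list(W = unname(t$statistic), p = t$p.value, degenerate = FALSE)
}

check_groups <- function(gl, need_var = TRUE) {
  if (length(gl) < 2) stop("need at least 2 groups")
  ns <- vapply(gl, length, 1L)
  if (any(ns < 2)) stop("every group needs n >= 2")
  if (need_var) {
    vars <- vapply(gl, var, 1)
    if (any(vars <= 0)) {
      stop("zero-variance group: ", names(gl)[which(vars <= 0)[1]])
    }
  }
  gl
}

#' Welch's heteroscedastic one-way ANOVA
#'
#' The Welch F* statistic with fractional denominator degrees of freedom;
#' does not assume equal group variances. For two equal-variance,
#' equal-size groups it reduces to the square of the Welch t statistic.
#'
#' @param values Numeric vector of observations, or a list of per-group
#'   vectors.
#' @param groups Group labels (ignored when `values` is a list).
#' @return list `F`, `df1`, `df2`, `p`.
#' @export
welch_anova <- function(values, groups = NULL) {
  gl <- check_groups(as_group_list(values, groups))
  k <- length(gl)
  n <- vapply(gl, length, 1L)
  m <- vapply(gl, mean, 1)
  v <- vapply(gl, var, 1)
  w <- n / v
  sw <- sum(w)
  mw <- sum(w * m) / sw
  a <- sum(w * (m - mw)^2) / (k - 1)
  lambda <- sum((1 - w / sw)^2 / (n - 1))
  b <- 1 + 2 * (k - 2) / (k^2 - 1) * lambda
  Fstar <- a / b
  df1 <- k - 1
  df2 <- (k^2 - 1) / (3 * lambda)
  list(F = Fstar, df1 = df1, df2 = df2,
       p = pf(Fstar, df1, df2, lower.tail = FALSE))
}

#' Brown-Forsythe heteroscedastic one-way ANOVA
#'
#' The Brown-Forsythe F* test for equality of means under unequal
#' variances: the between-group sum of squares over
#' `sum((1 - n_i/N) * s_i^2)`, with Satterthwaite denominator degrees of
#' freedom. (This is the means test, not the Levene-type spread test.)
#'
#' @inheritParams welch_anova
#' @return list `F`, `df1`, `df2`, `p`.
#' @export
brown_forsythe_anova <- function(values, groups = NULL) {
  gl <- check_groups(as_group_list(values, groups))
  k <- length(gl)
  n <- vapply(gl, length, 1L)
  N <- sum(n)
  m <- vapply(gl, mean, 1)
  v <- vapply(gl, var, 1)
  gm <- sum(n * m) / N
  num <- sum(n * (m - gm)^2)
  den_terms <- (1 - n / N) * v
  Fstar <- num / sum(den_terms)
  c_i <- den_terms / sum(den_terms)
  df1 <- k - 1
  df2 <- 1 / sum(c_i^2 / (n - 1))
  list(F = Fstar, df1 = df1, df2 = df2,
       p = pf(Fstar, df1, df2, lower.tail = FALSE))
}

# CDF of the studentized maximum modulus: max of k independent |N(0,1)|
# studentized by a shared chi(nu)/sqrt(nu) denominator.
psmm <- function(q, k, nu) {
  if (q <= 0) return(0)
  dens <- function(u) {
    exp((nu / 2) * log(nu) + (nu - 1) * log(u) - nu * u^2 / 2 -
          ((nu / 2 - 1) * log(2) + lgamma(nu / 2)))
  }
  f <- function(u) (2 * pnorm(q * u) - 1)^k * dens(u)
  integrate(f, 0, Inf, rel.tol = 1e-9, abs.tol = 1e-12)$value
}

#' Dunnett's T3 pairwise comparisons
#'
#' All pairwise Welch-type t statistics with Welch-Satterthwaite degrees of
#' freedom; each adjusted p-value comes from the studentized maximum
#' modulus distribution with k = number of pairs, evaluated by numerical
#' integration (tolerance well below 1e-6). With a single comparison the
#' adjusted p equals the unadjusted Welch t p.
#'
#' @inheritParams welch_anova
#' @return data.frame `group1, group2, mean_diff, t, df, p, p_adj`.
#' @export
dunnett_t3 <- function(values, groups = NULL) {
  gl <- check_groups(as_group_list(values, groups))
  nm <- names(gl)
  pairs <- combn(length(gl), 2)
  k <- ncol(pairs)
  out <- lapply(seq_len(k), function(j) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x <- gl[[i1]]; y <- gl[[i2]]
    se2 <- var(x) / length(x) + var(y) / length(y)
    t <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((var(x) / length(x))^2 / (length(x) - 1) +
                     (var(y) / length(y))^2 / (length(y) - 1))
    p <- 2 * pt(-abs(t), df)
    p_adj <- 1 - psmm(abs(t), k, df)
    data.frame(
      group1 = nm[i1], group2 = nm[i2],
      mean_diff = mean(x) - mean(y), t = t, df = df,
      p = p, p_adj = min(1, max(p_adj, p)), stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}

#' Pairwise post hoc comparisons
#'
#' Welch-type pairwise t tests with the selected multiplicity correction:
#' Dunnett T3 (studentized maximum modulus), Sidak, or Bonferroni.
#'
#' @inheritParams welch_anova
#' @param method Correction method.
#' @return data.frame as in [dunnett_t3()].
#' @export
posthoc_pairwise <- function(values, groups = NULL,
                             method = c("dunnett_t3", "sidak", "bonferroni")) {
  method <- match.arg(method)
  res <- dunnett_t3(values, groups)
  k <- nrow(res)
  if (method == "sidak") {
    res$p_adj <- pmin(1, 1 - (1 - res$p)^k)
  } else if (method == "bonferroni") {
    res$p_adj <- pmin(1, res$p * k)
  }
  res
}

#' Full group comparison of a per-sample statistic
#'
#' The comparison toolkit applied to e.g. mt-dsRNA signatures by group:
#' per-group summaries (n, mean, SD, SEM), Shapiro-Wilk normality
#' screening, Welch and Brown-Forsythe omnibus ANOVAs, and pairwise post
#' hoc tests under the selected correction.
#'
#' @inheritParams welch_anova
#' @param posthoc Correction method for the pairwise tests.
#' @return An object of class `group_comparison` (a list with `groups`,
#'   `normality`, `omnibus`, `posthoc`).
#' @export
group_comparison <- function(values, groups = NULL,
                             posthoc = c("dunnett_t3", "sidak", "bonferroni")) {
  posthoc <- match.arg(posthoc)
  gl <- as_group_list(values, groups)
  summaries <- data.frame(
    group = names(gl),
    n = vapply(gl, length, 1L),
    mean = vapply(gl, mean, 1),
    sd = vapply(gl, sd, 1),
    stringsAsFactors = FALSE
  )
  summaries$sem <- summaries$sd / sqrt(summaries$n)
  normality <- do.call(rbind, lapply(names(gl), function(g) {
    sw <- if (length(gl[[g]]) >= 3 && length(gl[[g]]) <= 5000) {
      shapiro_wilk(gl[[g]])
    } else {
      list(W = NA_real_, p = NA_real_, degenerate = FALSE)
    }
    data.frame(group = g, W = sw$W, p = sw$p, stringsAsFactors = FALSE)
  }))
  structure(list(
    groups = summaries,
    normality = normality,
    omnibus = list(
      welch = welch_anova(gl),
      brown_forsythe = brown_forsythe_anova(gl)
    ),
    posthoc_method = posthoc,
    posthoc = posthoc_pairwise(gl, method = posthoc)
  ), class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison>\n")
  print(x$groups, row.names = FALSE)
  w <- x$omnibus$welch; b <- x$omnibus$brown_forsythe
  cat(sprintf("Welch ANOVA:          F = %.4g, df = (%g, %.2f), p = %.3g\n",
              w$F, w$df1, w$df2, w$p))
  cat(sprintf("Brown-Forsythe ANOVA: F = %.4g, df = (%g, %.2f), p = %.3g\n",
              b$F, b$df1, b$df2, b$p))
  cat("Post hoc (", x$posthoc_method, "):\n", sep = "")
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Relative expression by group
#'
#' For each gene, the group mean of library-size-normalized expression
#' divided by the reference group's mean. Normalized expression is counts
#' divided by the sample's library-size scaling factor (library size over
#' cohort mean). Genes with a zero reference mean are flagged (`ratio =
#' NA`), not divided.
#'
#' @param expr An [expression_matrix()] or counts matrix (genes x samples).
#' @param groups Named vector (by sample) or vector aligned to columns.
#' @param reference_group Label of the reference group.
#' @param library_sf Optional per-sample scaling factors; computed from
#'   column sums when omitted.
#' @return data.frame `gene, group, ratio, reference_zero`.
#' @export
relative_expression <- function(expr, groups, reference_group,
                                library_sf = NULL) {
  counts <- if (inherits(expr, "expression_matrix")) expr$counts else as.matrix(expr)
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  groups <- as.character(groups)
  if (!reference_group %in% groups) {
    stop("unknown group label: ", reference_group)
  }
  if (any(is.na(groups))) stop("every sample needs a group label")
  if (is.null(library_sf)) {
    ls <- colSums(counts)
    library_sf <- ls / mean(ls)
  }
  norm <- sweep(counts, 2, library_sf, "/")
  labels <- unique(groups)
  ref_mean <- rowMeans(norm[, groups == reference_group, drop = FALSE])
  out <- lapply(labels, function(g) {
    gm <- rowMeans(norm[, groups == g, drop = FALSE])
    data.frame(
      gene = rownames(counts), group = g,
      ratio = ifelse(ref_mean > 0, gm / ref_mean, NA_real_),
      reference_zero = ref_mean == 0,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
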