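#' Gene-retention filter
#'
#' A gene is retained iff it has reads (count above `floor`, default 0) in
#' strictly more than `min_fraction` of the included samples.
#'
#' @param expr An [expression_matrix()] or counts matrix (genes x samples).
#' @param samples Optional character vector restricting the sample set.
#' @param min_fraction Retention fraction (default 0.5: "more than half").
#' @param floor Count floor defining "has reads" (default 0, i.e. count >
#'   0).
#' @return Character vector of retained gene ids.
#' @export
retain_genes <- function(expr, samples = NULL, min_fraction = 0.5, floor = 0) {
  counts <- if (inherits(expr, "expression_matrix")) expr$counts else as.matrix(expr)
  if (!is.null(samples)) counts <- counts[, samples, drop = FALSE]
  if (ncol(counts) < 1) stop("need at least one sample")
  n_with <- rowSums(counts > floor)
  rownames(counts)[n_with > min_fraction * ncol(counts)]
}

#' Benjamini-Hochberg / Bonferroni adjustment
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values (BH step-up, monotone and capped at 1;
#'   Bonferroni `min(1, m * p)`).
#' @export
bh_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' @rdname bh_adjust
#' @export
bonferroni_adjust <- function(pvalues) {
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "bonferroni")
}

#' Pearson correlation panel
#'
#' Correlates a per-sample target (signature, MMSE, Braak, ChrM reads, ...)
#' against each row of a variable matrix, using pairwise-complete
#' observations. r is the product-moment coefficient; the two-sided p comes
#' from the t transform with n - 2 degrees of freedom; the chosen
#' adjustment is applied across the panel. Rows with fewer than 3 complete
#' pairs are dropped.
#'
#' @param target Named (or column-aligned) numeric vector.
#' @param mat Numeric matrix, variables in rows, samples in columns — or an
#'   [expression_matrix()].
#' @param universe Optional character vector restricting the rows (e.g.
#'   from [retain_genes()]).
#' @param adjustment `"BH"`, `"bonferroni"` or `"none"`.
#' @param alpha Significance level for the `significant` flag.
#' @return An object of class `correlation_panel`: data.frame `variable, n,
#'   r, p, p_adj, significant`, with the adjustment, alpha and sample set
#'   stored in attributes.
#' @export
correlate_panel <- function(target, mat, universe = NULL,
                            adjustment = c("BH", "bonferroni", "none"),
                            alpha = 0.05) {
  adjustment <- match.arg(adjustment)
  counts <- if (inherits(mat, "expression_matrix")) mat$counts else as.matrix(mat)
  if (!is.null(universe)) {
    bad <- setdiff(universe, rownames(counts))
    if (length(bad) > 0) stop("universe member absent from matrix: ", bad[1])
    counts <- counts[universe, , drop = FALSE]
  }
  if (!is.null(names(target))) {
    shared <- intersect(names(target), colnames(counts))
    if (length(shared) < 3) stop("fewer than 3 shared samples")
    target <- target[shared]
    counts <- counts[, shared, drop = FALSE]
  }
  if (length(target) != ncol(counts)) {
    stop("target and matrix columns must align")
  }
  if (sd(target, na.rm = TRUE) == 0 || all(is.na(target))) {
    stop("zero-variance target")
  }
  ok_t <- is.finite(target)
  res <- lapply(rownames(counts), function(g) {
    x <- counts[g, ]
    ok <- ok_t & is.finite(x)
    n <- sum(ok)
    if (n < 3) return(NULL)
    if (sd(x[ok]) == 0) {
      return(data.frame(variable = g, n = n, r = NA_real_, p = NA_real_,
                        stringsAsFactors = FALSE))
    }
    r <- cor(target[ok], x[ok])
    r <- max(-1, min(1, r))
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    data.frame(variable = g, n = n, r = r, p = 2 * pt(-abs(tstat), n - 2),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (is.null(out)) stop("no variable had 3 complete pairs")
  out$p_adj <- switch(adjustment,
    BH = bh_adjust(out$p[!is.na(out$p)])[match(seq_len(nrow(out)), which(!is.na(out$p)))],
    bonferroni = bonferroni_adjust(out$p[!is.na(out$p)])[match(seq_len(nrow(out)), which(!is.na(out$p)))],
    none = out$p
  )
  out$significant <- !is.na(out$p) & out$p_adj <= alpha
  structure(out, class = c("correlation_panel", "data.frame"),
            adjustment = adjustment, alpha = alpha,
            samples = colnames(counts))
}

panel_significant <- function(panel, rule = c("raw", "adjusted"), alpha = 0.05) {
  rule <- match.arg(rule)
  p <- if (rule == "raw") panel$p else panel$p_adj
  panel$variable[!is.na(p) & p < alpha]
}

#' Three-way intersectional analysis
#'
#' Given three correlation panels over one retained-gene universe (e.g.
#' genes vs MMSE, vs Braak, and vs the mt-dsRNA signature), computes the
#' per-panel significant sets under a uniform significance rule, all seven
#' regions of the three-set Venn diagram, and the triple-intersection gene
#' list.
#'
#' @param panels List of three `correlation_panel` objects (named; names
#'   label the criteria).
#' @param rule `"raw"` (default: raw p < alpha) or `"adjusted"`.
#' @param alpha Significance level.
#' @return list with `sets` (per-criterion significant genes), `regions`
#'   (named counts of the 7 exclusive Venn regions), `triple` (gene
#'   vector), `rule`, `alpha`.
#' @export
intersect_criteria <- function(panels, rule = c("raw", "adjusted"),
                               alpha = 0.05) {
  rule <- match.arg(rule)
  stopifnot(length(panels) == 3)
  if (is.null(names(panels))) names(panels) <- c("A", "B", "C")
  universes <- lapply(panels, function(p) sort(p$variable))
  if (!all(vapply(universes, identical, TRUE, y = universes[[1]]))) {
    stop("panels must share one retained-gene universe")
  }
  sets <- lapply(panels, panel_significant, rule = rule, alpha = alpha)
  A <- sets[[1]]; B <- sets[[2]]; C <- sets[[3]]
  triple <- Reduce(intersect, sets)
  regions <- c(
    sum(!(A %in% B) & !(A %in% C)),
    sum(!(B %in% A) & !(B %in% C)),
    sum(!(C %in% A) & !(C %in% B)),
    length(setdiff(intersect(A, B), C)),
    length(setdiff(intersect(A, C), B)),
    length(setdiff(intersect(B, C), A)),
    length(triple)
  )
  nm <- names(panels)
  names(regions) <- c(
    paste0(nm[1], "_only"), paste0(nm[2], "_only"), paste0(nm[3], "_only"),
    paste(nm[1], nm[2], sep = "&"), paste(nm[1], nm[3], sep = "&"),
    paste(nm[2], nm[3], sep = "&"), paste(nm, collapse = "&")
  )
  list(sets = sets, regions = regions, triple = triple, rule = rule,
       alpha = alpha)
}

#' Hypergeometric gene-set overlap
#'
#' The exact upper-tail probability of observing at least the given overlap
#' between two gene sets drawn from a finite universe, plus the odds ratio
#' of the implied 2x2 table.
#'
#' @param universe Either the universe as a character vector, or its size
#'   `N` as a single number.
#' @param set1,set2 Character vectors (subsets of the universe).
#' @return list `N, n1, n2, k, p, odds_ratio`.
#' @export
hypergeom_overlap <- function(universe, set1, set2) {
  if (is.character(universe)) {
    N <- length(unique(universe))
    bad <- c(setdiff(set1, universe), setdiff(set2, universe))
    if (length(bad) > 0) stop("set member outside universe: ", bad[1])
  } else {
    stopifnot(is.numeric(universe), length(universe) == 1)
    N <- as.integer(universe)
    if (length(unique(set1)) > N || length(unique(set2)) > N) {
      stop("set larger than universe")
    }
  }
  set1 <- unique(set1); set2 <- unique(set2)
  n1 <- length(set1); n2 <- length(set2)
  k <- length(intersect(set1, set2))
  p <- phyper(k - 1, n1, N - n1, n2, lower.tail = FALSE)
  a <- k; b <- n1 - k; cc <- n2 - k; d <- N - n1 - n2 + k
  if (d < 0) stop("sets exceed universe")
  odds <- if (b == 0 || cc == 0) Inf else (a * d) / (b * cc)
  if (a == 0 || d == 0) odds <- 0
  list(N = N, n1 = n1, n2 = n2, k = k, p = p, odds_ratio = odds)
}
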