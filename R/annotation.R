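#' @import data.table
#' @importFrom stats rbinom rlnorm rnbinom rnorm rpois runif quantile sd var
#'   pbinom pnorm pt pf phyper qnbinom integrate complete.cases cor p.adjust
#'   shapiro.test median setNames aggregate
#' @importFrom utils head combn
NULL

BASES <- c("A", "C", "G", "T")

base_complement <- function(b) {
  unname(c(A = "T", C = "G", G = "C", T = "A")[b])
}

#' Mitochondrial annotation
#'
#' Container for a circular mitochondrial chromosome: its length and a set of
#' strand-annotated gene intervals. Coordinates are 1-based inclusive. The
#' heavy (H) strand is represented as `+`, the light (L) strand as `-`.
#' A single gene may wrap the origin (represented by `start > end`).
#'
#' @param genes data.frame with columns `name`, `start`, `end`, `strand`
#'   (`"+"`/`"-"`) and `class` (e.g. `"rRNA-like"`, `"mRNA-like"`).
#' @param length Chromosome length in nucleotides.
#' @param chrom Chromosome name (default `"chrM"`).
#' @return An object of class `mito_annotation`.
#' @export
mito_annotation <- function(genes, length, chrom = "chrM") {
  stopifnot(is.data.frame(genes))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  required <- c("name", "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (base::length(missing_cols) > 0) {
    stop("annotation is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(genes$class)) genes$class <- "unspecified"
  if (!is.numeric(length) || base::length(length) != 1 || length < 1) {
    stop("chromosome length must be a single positive integer")
  }
  length <- as.integer(length)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  if (anyDuplicated(genes$name)) stop("gene names must be unique")
  if (!all(genes$strand %in% c("+", "-"))) stop("gene strand must be '+' or '-'")
  if (any(genes$start < 1 | genes$start > length | genes$end < 1 | genes$end > length)) {
    stop("gene coordinates must lie within [1, length]")
  }
  wrapped <- genes$start > genes$end
  if (sum(wrapped) > 1) stop("at most one gene may wrap the origin")
  if (!any(genes$strand == "+")) stop("at least one H-strand (+) gene is required")
  structure(
    list(chrom = chrom, length = length, genes = genes),
    class = "mito_annotation"
  )
}

#' @export
print.mito_annotation <- function(x, ...) {
  cat(sprintf(
    "<mito_annotation> %s (%d nt, circular), %d genes (%d H-strand, %d L-strand)\n",
    x$chrom, x$length, nrow(x$genes),
    sum(x$genes$strand == "+"), sum(x$genes$strand == "-")
  ))
  print(x$genes, row.names = FALSE)
  invisible(x)
}

#' Expand gene intervals to a per-position lookup table
#'
#' @param annotation A [mito_annotation()].
#' @return data.table with columns `pos`, `gene`, `strand`, `class`; one row
#'   per (position, gene), wrap-aware.
#' @keywords internal
gene_position_map <- function(annotation) {
  g <- annotation$genes
  out <- lapply(seq_len(nrow(g)), function(i) {
    pos <- if (g$start[i] <= g$end[i]) {
      seq.int(g$start[i], g$end[i])
    } else {
      c(seq.int(g$start[i], annotation$length), seq.int(1L, g$end[i]))
    }
    data.table(
      pos = pos, gene = g$name[i],
      strand = g$strand[i], class = g$class[i]
    )
  })
  rbindlist(out)
}

#' Human-ChrM-like default annotation
#'
#' A 16,569-nt circular chromosome carrying the major mitochondrial
#' transcripts: the two H-strand rRNAs (RNR1, RNR2), a representative set of
#' H-strand mRNAs, and the single L-strand mRNA (ND6). Intervals approximate
#' the human mitochondrial gene layout but are trimmed so that no two genes
#' on the same strand overlap.
#'
#' @return A [mito_annotation()] of length 16,569 nt.
#' @export
default_mito_annotation <- function() {
  genes <- data.frame(
    name = c(
      "RNR1", "RNR2", "ND1", "ND2", "CO1", "CO2", "ATP6", "CO3",
      "ND3", "ND4", "ND5", "ND6", "CYB"
    ),
    start = c(648L, 1671L, 3307L, 4470L, 5904L, 7586L, 8527L, 9208L,
              10059L, 10770L, 12337L, 14149L, 14747L),
    end = c(1601L, 3229L, 4262L, 5511L, 7445L, 8269L, 9207L, 9990L,
            10404L, 12137L, 14148L, 14673L, 15887L),
    strand = c("+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "+", "-", "+"),
    class = c("rRNA-like", "rRNA-like", rep("mRNA-like", 11)),
    stringsAsFactors = FALSE
  )
  mito_annotation(genes, length = 16569L)
}

#' Reduced toy annotation for fast tests
#'
#' A 2,000-nt circular chromosome with two H-strand rRNA-like genes and one
#' L-strand mRNA-like gene, preserving the strand structure of the full
#' default at a fraction of the size.
#'
#' @return A [mito_annotation()] of length 2,000 nt.
#' @export
toy_mito_annotation <- function() {
  genes <- data.frame(
    name = c("RNR1L", "RNR2L", "ND6L"),
    start = c(101L, 751L, 1501L),
    end = c(700L, 1400L, 1900L),
    strand = c("+", "+", "-"),
    class = c("rRNA-like", "rRNA-like", "mRNA-like"),
    stringsAsFactors = FALSE
  )
  mito_annotation(genes, length = 2000L)
}
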