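#' Bin edits along the chromosome
#'
#' Tiles `[1, length]` with fixed-size bins anchored at position 1 (the
#' final bin may be shorter; no circular wrap-around merging) and counts
#' accepted calls per bin, summed over samples. A site at position `p`
#' falls in bin `floor((p - 1) / bin_size) + 1`. Each bin also reports how
#' many of its bases are covered by H- and L-strand genes.
#'
#' @param callsets List of `editing_calls` (or a single one).
#' @param annotation A [mito_annotation()].
#' @param bin_size Bin width in nt (default 200).
#' @return data.frame with columns `bin, start, end, h_strand_bp,
#'   l_strand_bp, edit_count`.
#' @export
bin_edits <- function(callsets, annotation, bin_size = 200) {
  stopifnot(bin_size >= 1)
  if (inherits(callsets, "editing_calls")) callsets <- list(callsets)
  L <- annotation$length
  n_bins <- ceiling(L / bin_size)
  start <- (seq_len(n_bins) - 1L) * bin_size + 1L
  end <- pmin(seq_len(n_bins) * bin_size, L)
  posmap <- gene_position_map(annotation)
  bin_of <- function(p) (p - 1L) %/% as.integer(bin_size) + 1L
  h_bp <- tabulate(bin_of(unique(posmap[strand == "+", pos])), nbins = n_bins)
  l_bp <- tabulate(bin_of(unique(posmap[strand == "-", pos])), nbins = n_bins)
  all_rec <- rbindlist(lapply(callsets, as.data.frame))
  counts <- if (nrow(all_rec) > 0) {
    tabulate(bin_of(all_rec[status == "call", pos]), nbins = n_bins)
  } else {
    integer(n_bins)
  }
  data.frame(
    bin = seq_len(n_bins), start = start, end = end,
    h_strand_bp = h_bp, l_strand_bp = l_bp, edit_count = counts
  )
}

#' Per-gene share of ChrM edits
#'
#' Attributes each accepted call to the gene covering its (position,
#' transcript strand); calls outside any gene pool as `"intergenic"`.
#'
#' @param callsets List of `editing_calls` (or a single one).
#' @param annotation A [mito_annotation()].
#' @return data.frame `gene, edit_count, fraction` (fractions sum to 1 when
#'   any edits exist; the intergenic remainder is its own row).
#' @export
per_gene_edit_share <- function(callsets, annotation) {
  if (inherits(callsets, "editing_calls")) callsets <- list(callsets)
  all_rec <- rbindlist(lapply(callsets, as.data.frame))
  if (nrow(all_rec) == 0 || !any(all_rec$status == "call")) {
    return(data.frame(gene = character(0), edit_count = integer(0),
                      fraction = numeric(0)))
  }
  calls <- all_rec[status == "call"]
  posmap <- gene_position_map(annotation)
  m <- merge(calls[, .(pos, strand)], posmap, by = c("pos", "strand"),
             all.x = TRUE, sort = FALSE)
  gene <- ifelse(is.na(m$gene), "intergenic", m$gene)
  tab <- table(gene)
  out <- data.frame(
    gene = names(tab), edit_count = as.integer(tab),
    fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE
  )
  out[order(-out$edit_count), ]
}

#' Per-gene antisense-read fractions
#'
#' For each gene and sample, the coverage-weighted fraction of reads
#' oriented opposite the gene's transcript strand: antisense coverage over
#' total coverage across the gene's positions. Computed from the pileup
#' strand strata (read orientation), not from called edits. Genes with zero
#' coverage in a sample are reported as missing (`NA`), not 0.
#'
#' @param pileups Named list of pileup data.frames (or a single one).
#' @param annotation A [mito_annotation()].
#' @return data.frame `sample_id, gene, antisense_reads, total_reads,
#'   antisense_fraction`.
#' @export
antisense_fraction <- function(pileups, annotation) {
  if (is.data.frame(pileups)) pileups <- list(pileups)
  posmap <- gene_position_map(annotation)
  out <- lapply(pileups, function(p) {
    sid <- if (nrow(p) > 0) p$sample_id[1] else NA_character_
    dt <- as.data.table(p)
    dt[, total := count_A + count_C + count_G + count_T]
    per_gene <- lapply(seq_len(nrow(annotation$genes)), function(i) {
      g <- annotation$genes[i, ]
      gp <- posmap[gene == g$name, pos]
      rows <- dt[pos %in% gp]
      sense <- sum(rows[strand == g$strand, total])
      anti <- sum(rows[strand != g$strand, total])
      data.table(
        sample_id = sid, gene = g$name,
        antisense_reads = anti, total_reads = sense + anti,
        antisense_fraction = if (sense + anti > 0) anti / (sense + anti) else NA_real_
      )
    })
    rbindlist(per_gene)
  })
  as.data.frame(rbindlist(out))
}

#' Plot the binned editing landscape
#'
#' Bar chart of binned edit counts colored by the dominant strand class of
#' each bin. Requires ggplot2.
#'
#' @param bins Output of [bin_edits()].
#' @return A ggplot object.
#' @export
plot_edit_landscape <- function(bins) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  bins$strand_class <- ifelse(
    bins$h_strand_bp >= bins$l_strand_bp & bins$h_strand_bp > 0, "H-strand",
    ifelse(bins$l_strand_bp > 0, "L-strand", "intergenic")
  )
  ggplot2::ggplot(bins, ggplot2::aes(
    x = (start + end) / 2, y = edit_count, fill = strand_class
  )) +
    ggplot2::geom_col(width = bins$end - bins$start + 1) +
    ggplot2::scale_fill_manual(values = c(
      "H-strand" = "#2e7d32", "L-strand" = "#ef6c00", "intergenic" = "grey60"
    )) +
    ggplot2::labs(x = "ChrM position (nt)", y = "A-to-I edits per bin",
                  fill = NULL) +
    ggplot2::theme_minimal()
}
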