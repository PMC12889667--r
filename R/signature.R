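#' ChrM scaling factors
#'
#' A sample's ChrM scaling factor is its total mitochondrial read count
#' divided by the cohort mean of that count — a proxy for rRNA-depletion
#' efficiency and mitochondrial sequencing depth. The factors average to 1
#' over the cohort by construction.
#'
#' @param chrm_reads Numeric vector of per-sample ChrM read totals (named
#'   names are preserved).
#' @return Numeric vector of scaling factors.
#' @export
chrm_scaling_factors <- function(chrm_reads) {
  if (length(chrm_reads) < 1 || any(!is.finite(chrm_reads)) || any(chrm_reads < 0)) {
    stop("chrm_reads must be non-negative finite counts")
  }
  m <- mean(chrm_reads)
  if (m <= 0) stop("all-zero cohort: scaling factors undefined")
  chrm_reads / m
}

#' Total ChrM reads from a pileup
#'
#' Sums all base counts over both strand strata — the position-coverage
#' total, proportional to the sample's ChrM read yield for a fixed
#' chromosome.
#'
#' @param pileup A pileup data.frame.
#' @return A single number.
#' @export
chrm_read_total <- function(pileup) {
  sum(pileup$count_A, pileup$count_C, pileup$count_G, pileup$count_T)
}

#' Percentile-based sample QC
#'
#' A sample passes QC iff its scaling factor lies within the closed
#' interval `[P_lower, P_upper]` of the cohort's scaling-factor
#' distribution. Percentiles use linear interpolation between closest ranks
#' (R quantile type 7), pinned so the QC decision is bit-reproducible.
#' Samples exactly at a percentile bound pass ("within" read inclusively).
#'
#' @param sf Numeric vector of scaling factors.
#' @param lower,upper Percentile bounds (default 5 and 95).
#' @return Logical vector, `TRUE` = pass.
#' @export
percentile_qc <- function(sf, lower = 5, upper = 95) {
  if (!(lower >= 0 && lower < upper && upper <= 100)) {
    stop("need 0 <= lower < upper <= 100")
  }
  q <- quantile(sf, probs = c(lower, upper) / 100, type = 7, names = FALSE)
  sf >= q[1] & sf <= q[2]
}

count_edits <- function(callset, counting_mode = c("sites", "edited_reads")) {
  counting_mode <- match.arg(counting_mode)
  df <- as.data.frame(callset)
  calls <- df[df$status == "call", , drop = FALSE]
  if (counting_mode == "sites") nrow(calls) else sum(calls$edited_reads)
}

#' mt-dsRNA signature for one sample
#'
#' The per-sample statistic: the ChrM A-to-I edit count divided by the
#' sample's ChrM scaling factor. Two counting modes are provided because
#' "edit counts" can mean distinct edited sites or read-level edit events:
#' `"sites"` (default; distinct called sites) or `"edited_reads"` (sum of
#' edit-supporting reads, which scales linearly with the underlying editing
#' rate even when per-site detection saturates).
#'
#' @param callset An `editing_calls` object (or a precomputed numeric raw
#'   edit count).
#' @param sf The sample's ChrM scaling factor (> 0).
#' @param counting_mode `"sites"` or `"edited_reads"`.
#' @return The normalized signature value.
#' @export
mt_dsrna_signature <- function(callset, sf, counting_mode = c("sites", "edited_reads")) {
  if (!is.numeric(sf) || length(sf) != 1 || !is.finite(sf) || sf <= 0) {
    stop("scaling factor must be a single positive number")
  }
  raw <- if (is.numeric(callset)) callset else count_edits(callset, counting_mode)
  raw / sf
}

#' Transcriptome-wide signature
#'
#' The transcriptome-wide analogue: genome-wide A-to-I edit count divided
#' by the sample's library-size scaling factor.
#'
#' @param genomewide_edit_count Raw transcriptome-wide edit count.
#' @param library_sf Library-size scaling factor (> 0).
#' @return The normalized value.
#' @export
transcriptome_signature <- function(genomewide_edit_count, library_sf) {
  if (!is.numeric(library_sf) || length(library_sf) != 1 ||
      !is.finite(library_sf) || library_sf <= 0) {
    stop("scaling factor must be a single positive number")
  }
  genomewide_edit_count / library_sf
}

#' Build the per-sample signature table
#'
#' Computes scaling factors on ALL samples, then applies the percentile QC
#' rule; factors are deliberately not recomputed after exclusion (the rule
#' is expressed in terms of each sample's already-computed factor).
#' `qc_pass == FALSE` marks a sample for exclusion from downstream group
#' statistics; edit calling itself is never gated on QC.
#'
#' @param callsets Named list of `editing_calls`, one per sample.
#' @param chrm_reads Named numeric vector of per-sample ChrM read totals
#'   (same names as `callsets`).
#' @param groups Optional named vector of group labels.
#' @param library_size Optional named vector of total mapped reads; enables
#'   `library_sf` and the transcriptome-wide columns.
#' @param tw_raw_edits Optional named vector of transcriptome-wide edit
#'   counts.
#' @param counting_mode Passed to [mt_dsrna_signature()].
#' @param lower,upper QC percentile bounds.
#' @param recompute_sf_after_qc Off-by-default option to recompute factors
#'   on the QC-passing subset (changes the cohort mean; documented, not
#'   default behaviour).
#' @return A data.frame with one row per sample: `sample_id, group,
#'   chrm_reads, library_size, chrm_sf, library_sf, qc_pass, raw_edits,
#'   signature, tw_raw_edits, tw_signature`.
#' @export
build_signature_table <- function(callsets, chrm_reads, groups = NULL,
                                  library_size = NULL, tw_raw_edits = NULL,
                                  counting_mode = c("sites", "edited_reads"),
                                  lower = 5, upper = 95,
                                  recompute_sf_after_qc = FALSE) {
  counting_mode <- match.arg(counting_mode)
  ids <- names(callsets)
  if (is.null(ids)) stop("callsets must be a named list")
  chrm_reads <- chrm_reads[ids]
  sf <- chrm_scaling_factors(chrm_reads)
  qc <- percentile_qc(sf, lower, upper)
  if (recompute_sf_after_qc) {
    sf_kept <- chrm_reads / mean(chrm_reads[qc])
    sf <- sf_kept
  }
  raw <- vapply(callsets, count_edits, numeric(1), counting_mode = counting_mode)
  lib_sf <- if (!is.null(library_size)) {
    library_size <- library_size[ids]
    library_size / mean(library_size)
  } else {
    rep(NA_real_, length(ids))
  }
  tw_sig <- if (!is.null(tw_raw_edits) && !is.null(library_size)) {
    tw_raw_edits <- tw_raw_edits[ids]
    tw_raw_edits / lib_sf
  } else {
    rep(NA_real_, length(ids))
  }
  data.frame(
    sample_id = ids,
    group = if (is.null(groups)) NA_character_ else unname(groups[ids]),
    chrm_reads = unname(chrm_reads),
    library_size = if (is.null(library_size)) NA_real_ else unname(library_size),
    chrm_sf = unname(sf),
    library_sf = unname(lib_sf),
    qc_pass = unname(qc),
    raw_edits = unname(raw),
    signature = unname(raw / sf),
    tw_raw_edits = if (is.null(tw_raw_edits)) NA_real_ else unname(tw_raw_edits),
    tw_signature = unname(tw_sig),
    stringsAsFactors = FALSE
  )
}
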