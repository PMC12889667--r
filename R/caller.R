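#' Editing-caller parameters
#'
#' Thresholds controlling the per-sample and cohort-level filters. The
#' caller's three filtering goals are: exclude single-nucleotide variants
#' (per-sample homoplasmy guard `max_edit_level` plus the cohort
#' variant-allele-fraction rule), exclude sequencing errors (`min_baseq`,
#' `min_coverage`, `min_edited_reads`, `min_edit_level`), and exclude
#' mapping-style artifacts (represented by the quality and coverage
#' thresholds, since alignment is upstream of the pileup evidence).
#' All minimum thresholds are inclusive (`>=`), all maxima inclusive
#' (`<=`).
#'
#' @param min_baseq Minimum mean Phred base quality at a site.
#' @param min_coverage Minimum read coverage on the transcript strand.
#' @param min_edited_reads Minimum reads supporting the edit (default 2).
#' @param min_edit_level Minimum editing level (fraction of reads).
#' @param max_edit_level Homoplasmy guard: candidates above this level are
#'   rejected as variants (default 0.9).
#' @param recurrence_min_samples Minimum number of samples a site must be
#'   called in when recurrence filtering is enabled (default 2).
#' @param snv_vaf_threshold Cohort rule: variant-allele fraction at or above
#'   which a sample is counted as "variant-like" at a site (default 0.9).
#' @param snv_sample_fraction Cohort rule: fraction of covered samples that
#'   must be variant-like for the site to be reclassified as a cohort SNV
#'   (default 0.5).
#' @return A validated list of class `caller_params`.
#' @export
caller_params <- function(min_baseq = 25,
                          min_coverage = 10,
                          min_edited_reads = 2,
                          min_edit_level = 0.01,
                          max_edit_level = 0.9,
                          recurrence_min_samples = 2,
                          snv_vaf_threshold = 0.9,
                          snv_sample_fraction = 0.5) {
  p <- list(
    min_baseq = min_baseq, min_coverage = min_coverage,
    min_edited_reads = min_edited_reads, min_edit_level = min_edit_level,
    max_edit_level = max_edit_level,
    recurrence_min_samples = recurrence_min_samples,
    snv_vaf_threshold = snv_vaf_threshold,
    snv_sample_fraction = snv_sample_fraction
  )
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1 || x < 0, TRUE))) {
    stop("caller thresholds must be single non-negative numbers")
  }
  if (!(min_edit_level > 0 && min_edit_level < max_edit_level && max_edit_level <= 1)) {
    stop("need 0 < min_edit_level < max_edit_level <= 1")
  }
  structure(p, class = "caller_params")
}

REJECTION_REASONS <- c(
  "not_A_to_I", "low_quality", "low_coverage", "low_support",
  "homoplasmic_SNV", "cohort_SNV", "non_recurrent"
)

#' Classify a mismatch as A-to-I or not
#'
#' A-to-I editing leaves an A>G footprint on the transcript strand: on a
#' plus-strand (H-strand) transcript the plus-strand pileup shows A>G; on a
#' minus-strand (L-strand) transcript it shows T>C.
#'
#' @param ref_plus Reference base on the plus strand.
#' @param alt_plus Observed alternate base on the plus strand.
#' @param transcript_strand `"+"` or `"-"`.
#' @return Character vector over `{"A_to_I", "other", "none"}`.
#' @export
classify_mismatch <- function(ref_plus, alt_plus, transcript_strand) {
  if (any(!ref_plus %in% BASES) || any(!alt_plus %in% BASES)) {
    stop("invalid base symbol")
  }
  if (any(!transcript_strand %in% c("+", "-"))) stop("invalid strand symbol")
  out <- rep("other", max(length(ref_plus), length(alt_plus), length(transcript_strand)))
  ref_plus <- rep_len(ref_plus, length(out))
  alt_plus <- rep_len(alt_plus, length(out))
  transcript_strand <- rep_len(transcript_strand, length(out))
  out[alt_plus == ref_plus] <- "none"
  a2i <- (transcript_strand == "+" & ref_plus == "A" & alt_plus == "G") |
    (transcript_strand == "-" & ref_plus == "T" & alt_plus == "C")
  out[a2i] <- "A_to_I"
  out
}

# transcript-strand mismatch label, e.g. "A>G"
ts_mismatch_label <- function(ref_plus, alt_plus, strand) {
  r <- ifelse(strand == "+", ref_plus, base_complement(ref_plus))
  a <- ifelse(strand == "+", alt_plus, base_complement(alt_plus))
  paste0(r, ">", a)
}

#' Call A-to-I editing sites in one sample
#'
#' Evaluates every annotated-gene position on the transcript strand of its
#' covering gene, using the read-orientation stratum that matches that
#' strand (sense reads). Candidates are positions with any non-reference
#' base; each rejected candidate carries the first failing filter in the
#' fixed order `not_A_to_I -> low_quality -> low_coverage -> low_support ->
#' homoplasmic_SNV`.
#'
#' @param pileup Pileup data.frame (dialect of [read_pileup()]).
#' @param annotation A [mito_annotation()].
#' @param params A [caller_params()].
#' @return An object of class `editing_calls`: a data.frame with columns
#'   `sample_id, pos, strand, gene, ref, alt, mismatch, edited_reads,
#'   coverage, edit_level, status, reason` (one row per candidate; calls
#'   have `status == "call"` and `reason == NA`).
#' @export
call_sample <- function(pileup, annotation, params = caller_params()) {
  pileup <- validate_pileup(pileup, annotation)
  posmap <- gene_position_map(annotation)
  if (anyDuplicated(posmap, by = c("pos", "strand"))) {
    dup <- posmap[duplicated(posmap, by = c("pos", "strand"))][1]
    stop("ambiguity error: position ", dup$pos,
         " is covered by two genes on strand ", dup$strand)
  }
  sid <- if (nrow(pileup) > 0) pileup$sample_id[1] else NA_character_
  empty <- data.frame(
    sample_id = character(0), pos = integer(0), strand = character(0),
    gene = character(0), ref = character(0), alt = character(0),
    mismatch = character(0), edited_reads = integer(0), coverage = integer(0),
    edit_level = numeric(0), status = character(0), reason = character(0),
    stringsAsFactors = FALSE
  )
  as_calls <- function(df) {
    structure(df, class = c("editing_calls", "data.frame"), sample_id = sid)
  }
  if (nrow(pileup) == 0) return(as_calls(empty))

  # candidate screen before any join: rows with a non-reference base
  cnt <- cbind(pileup$count_A, pileup$count_C, pileup$count_G, pileup$count_T)
  cov <- rowSums(cnt)
  ref_i <- match(pileup$ref, BASES)
  nonref <- cnt
  nonref[cbind(seq_len(nrow(cnt)), ref_i)] <- -1L
  alt_i <- max.col(nonref, ties.method = "first")
  alt_reads <- nonref[cbind(seq_len(nrow(cnt)), alt_i)]
  cand <- which(alt_reads > 0)
  if (length(cand) == 0) return(as_calls(empty))

  # transcript-strand assignment: the stratum must carry a gene
  pm_key <- posmap$pos * 2L + (posmap$strand == "-")
  cand_key <- pileup$pos[cand] * 2L + (pileup$strand[cand] == "-")
  gi <- match(cand_key, pm_key)
  cand <- cand[!is.na(gi)]
  gi <- gi[!is.na(gi)]
  if (length(cand) == 0) return(as_calls(empty))

  ref <- pileup$ref[cand]
  strand <- pileup$strand[cand]
  alt <- BASES[alt_i[cand]]
  alt_reads <- alt_reads[cand]
  cov <- cov[cand]
  level <- alt_reads / cov

  cls <- classify_mismatch(ref, alt, strand)
  reason <- rep(NA_character_, length(cand))
  reason[cls != "A_to_I"] <- "not_A_to_I"
  f <- is.na(reason) & pileup$mean_baseq[cand] < params$min_baseq
  reason[f] <- "low_quality"
  f <- is.na(reason) & cov < params$min_coverage
  reason[f] <- "low_coverage"
  f <- is.na(reason) &
    (alt_reads < params$min_edited_reads | level < params$min_edit_level)
  reason[f] <- "low_support"
  f <- is.na(reason) & level > params$max_edit_level
  reason[f] <- "homoplasmic_SNV"

  out <- data.frame(
    sample_id = pileup$sample_id[cand], pos = pileup$pos[cand],
    strand = strand, gene = posmap$gene[gi], ref = ref, alt = alt,
    mismatch = ts_mismatch_label(ref, alt, strand),
    edited_reads = as.integer(alt_reads), coverage = as.integer(cov),
    edit_level = level,
    status = ifelse(is.na(reason), "call", "rejected"),
    reason = reason,
    stringsAsFactors = FALSE
  )
  out <- out[order(out$strand, out$pos), ]
  rownames(out) <- NULL
  as_calls(out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Apply cohort-level filters to per-sample call sets
#'
#' Two cohort rules: (a) sites whose variant-allele fraction is at or above
#' `snv_vaf_threshold` in at least `snv_sample_fraction` of the covered
#' samples are reclassified `cohort_SNV` everywhere (covered = samples with
#' an evidence record at the site); (b) optionally, calls at sites called in
#' fewer than `recurrence_min_samples` samples are reclassified
#' `non_recurrent`. Recurrence filtering is off by default: cross-subject
#' recurrence is a credibility signal, not a stated filter.
#'
#' @param callsets List of `editing_calls` objects (one per sample).
#' @param params A [caller_params()].
#' @param recurrence Logical; enable the recurrence filter.
#' @return The list of call sets with reclassified rows.
#' @export
apply_cohort_filters <- function(callsets, params = caller_params(),
                                 recurrence = FALSE) {
  stopifnot(length(callsets) >= 1)
  all_rec <- rbindlist(lapply(callsets, as.data.frame))
  if (nrow(all_rec) == 0) return(callsets)
  site_stats <- all_rec[, .(
    n_covered = .N,
    n_high = sum(edit_level >= params$snv_vaf_threshold),
    n_called = sum(status == "call")
  ), by = .(pos, strand)]
  snv_sites <- site_stats[n_high >= params$snv_sample_fraction * n_covered &
                            n_high > 0]
  rare_sites <- if (recurrence) {
    site_stats[n_called > 0 & n_called < params$recurrence_min_samples]
  } else {
    site_stats[0]
  }
  lapply(callsets, function(cs) {
    sid <- attr(cs, "sample_id")
    df <- as.data.frame(cs)
    key <- paste(df$pos, df$strand)
    is_snv <- key %in% paste(snv_sites$pos, snv_sites$strand)
    df$status[is_snv] <- "rejected"
    df$reason[is_snv] <- "cohort_SNV"
    if (nrow(rare_sites) > 0) {
      is_rare <- df$status == "call" &
        key %in% paste(rare_sites$pos, rare_sites$strand)
      df$status[is_rare] <- "rejected"
      df$reason[is_rare] <- "non_recurrent"
    }
    structure(df, class = c("editing_calls", "data.frame"), sample_id = sid)
  })
}

#' Mismatch spectrum across candidates
#'
#' Dataset-level QC: counts every candidate record (calls and rejected
#' candidates alike) by its transcript-strand mismatch class. A-to-I
#' editing should make A>G dominate the twelve classes.
#'
#' @param callsets List of `editing_calls` (or a single one).
#' @param calls_only Count only accepted calls (default `FALSE`).
#' @return A list with `spectrum` (named count vector over the 12 mismatch
#'   classes) and `ag_fraction` (A>G share of all mismatches; `NaN` when no
#'   mismatches).
#' @export
mismatch_spectrum <- function(callsets, calls_only = FALSE) {
  if (inherits(callsets, "editing_calls")) callsets <- list(callsets)
  all_rec <- rbindlist(lapply(callsets, as.data.frame))
  classes <- as.vector(outer(BASES, BASES, function(r, a) paste0(r, ">", a)))
  classes <- classes[substr(classes, 1, 1) != substr(classes, 3, 3)]
  spectrum <- setNames(integer(length(classes)), sort(classes))
  if (nrow(all_rec) > 0) {
    if (calls_only) all_rec <- all_rec[status == "call"]
    tab <- table(all_rec$mismatch)
    spectrum[names(tab)] <- as.integer(tab)
  }
  total <- sum(spectrum)
  list(spectrum = spectrum,
       ag_fraction = if (total > 0) unname(spectrum["A>G"]) / total else NaN)
}

#' Serialize / read call sets
#'
#' TSV with columns
#' `sample_id pos strand ref edited_reads coverage edit_level status reason`
#' plus `gene`, `alt` and `mismatch`.
#'
#' @param callsets List of `editing_calls`.
#' @param path Output path.
#' @return `path` invisibly; `read_calls` returns a single data.frame.
#' @export
write_calls <- function(callsets, path) {
  if (inherits(callsets, "editing_calls")) callsets <- list(callsets)
  all_rec <- rbindlist(lapply(callsets, as.data.frame))
  data.table::fwrite(all_rec, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_calls
#' @export
read_calls <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
}
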