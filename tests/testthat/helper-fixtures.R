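# Shared fixtures: small cohorts on the 2,000-nt toy chromosome so module
# tests stay fast; the full-length chromosome is exercised in the
# acceptance suite.

toy_config <- function(..., seed = 42L) {
  defaults <- list(
    annotation = toy_mito_annotation(),
    n_samples_per_group = 4L,
    group_labels = c("ref", "alt"),
    group_edit_multiplier = c(ref = 1, alt = 2),
    edit_site_density = 20,
    seed = seed
  )
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

# single pileup row in the dialect's column order
pileup_row <- function(pos, ref, strand, counts, baseq = 35,
                       sample_id = "S1", chrom = "chrM") {
  data.frame(
    sample_id = sample_id, chrom = chrom, pos = as.integer(pos), ref = ref,
    strand = strand, count_A = counts[1], count_C = counts[2],
    count_G = counts[3], count_T = counts[4], mean_baseq = baseq,
    stringsAsFactors = FALSE
  )
}

# a minimal one-gene annotation for hand-built pileups
one_gene_annotation <- function(strand = "+", length = 1000L) {
  mito_annotation(
    data.frame(name = "G1", start = 1L, end = 500L, strand = strand,
               class = "rRNA-like", stringsAsFactors = FALSE),
    length = length
  )
}

truth_site_keys <- function(truth) {
  paste(truth$edit_sites$pos, truth$edit_sites$strand)
}

call_keys <- function(callset) {
  df <- as.data.frame(callset)
  paste(df$pos, df$strand)[df$status == "call"]
}
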