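#' Simulation configuration
#'
#' Assembles and validates the configuration for [simulate_cohort()]. The
#' generator emulates the statistical structure the downstream analysis
#' assumes: per-sample variability in mitochondrial rRNA-depletion efficiency
#' (log-normal ChrM depth), group-dependent A-to-I editing rates at
#' dsRNA-designated sites, homoplasmic variants and sequencing error that
#' challenge the caller, antisense transcription over annotated genes, and
#' expression/clinical tables with a configurable latent correlation to the
#' true per-sample editing burden.
#'
#' @param annotation A [mito_annotation()] supplying the genome length and
#'   gene models.
#' @param n_samples_per_group Samples per group (positive integer).
#' @param group_labels Ordered character vector of group labels.
#' @param group_edit_multiplier Named (or positionally matched) numeric vector
#'   of per-group multipliers on `base_edit_rate`; the first (reference)
#'   group must have multiplier 1.
#' @param depth_mean Median ChrM read depth per position (reads).
#' @param depth_sigma Log-scale SD of per-sample depth (depletion
#'   variability).
#' @param edit_site_density Expected dsRNA-designated editable sites per kb.
#' @param base_edit_rate Per-read editing probability at an editable site in
#'   the reference group.
#' @param signature_sd Log-scale SD of a per-sample editing-propensity random
#'   effect; this latent propensity is what expression panels and clinical
#'   scores couple to.
#' @param snv_density Homoplasmic variant sites per kb.
#' @param seq_error_rate Per-base miscall probability.
#' @param antisense_fraction Per-gene probability that a read is antisense.
#'   Either a single value or a named vector by gene.
#' @param n_nuclear_genes Number of nuclear genes in the expression matrix.
#' @param latent_assoc_strength Correlation in `[-1, 1]` between the latent
#'   signature and the designated signature-coupled gene panel (and, with the
#'   appropriate sign, the clinical scores).
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration including this seed.
#' @return A validated list of class `sim_config`.
#' @export
simulation_config <- function(annotation = default_mito_annotation(),
                              n_samples_per_group = 40L,
                              group_labels = "reference",
                              group_edit_multiplier = 1,
                              depth_mean = 100,
                              depth_sigma = 0.25,
                              edit_site_density = 15,
                              base_edit_rate = 0.05,
                              signature_sd = 0.3,
                              snv_density = 0.5,
                              seq_error_rate = 0.001,
                              antisense_fraction = 0.18,
                              n_nuclear_genes = 300L,
                              latent_assoc_strength = 0.6,
                              seed = 1L) {
  if (!inherits(annotation, "mito_annotation")) {
    stop("invalid configuration: 'annotation' must be a mito_annotation")
  }
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != as.integer(x)) {
      stop("invalid configuration: '", nm, "' must be a positive integer")
    }
    as.integer(x)
  }
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || any(is.na(x)) || any(x < 0) || any(x > 1)) {
      stop("invalid configuration: '", nm, "' must lie in [0, 1]")
    }
    x
  }
  chk_pos <- function(x, nm, strict = TRUE) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || (strict && x <= 0) || (!strict && x < 0)) {
      stop("invalid configuration: '", nm, "' must be ", if (strict) "> 0" else ">= 0")
    }
    x
  }
  n_samples_per_group <- chk_count(n_samples_per_group, "n_samples_per_group")
  if (!is.character(group_labels) || length(group_labels) < 1 ||
      anyDuplicated(group_labels)) {
    stop("invalid configuration: 'group_labels' must be distinct strings")
  }
  if (length(group_edit_multiplier) != length(group_labels)) {
    stop("invalid configuration: 'group_edit_multiplier' must match group_labels")
  }
  if (!is.numeric(group_edit_multiplier) || any(group_edit_multiplier < 0)) {
    stop("invalid configuration: 'group_edit_multiplier' must be non-negative")
  }
  if (abs(group_edit_multiplier[[1]] - 1) > 1e-12) {
    stop("invalid configuration: 'group_edit_multiplier' reference (first) group must be 1.0")
  }
  group_edit_multiplier <- setNames(as.numeric(group_edit_multiplier), group_labels)
  depth_mean <- chk_pos(depth_mean, "depth_mean")
  depth_sigma <- chk_pos(depth_sigma, "depth_sigma", strict = FALSE)
  edit_site_density <- chk_pos(edit_site_density, "edit_site_density", strict = FALSE)
  base_edit_rate <- chk_prob(base_edit_rate, "base_edit_rate")
  signature_sd <- chk_pos(signature_sd, "signature_sd", strict = FALSE)
  snv_density <- chk_pos(snv_density, "snv_density", strict = FALSE)
  seq_error_rate <- chk_prob(seq_error_rate, "seq_error_rate")
  antisense_fraction <- chk_prob(antisense_fraction, "antisense_fraction")
  n_nuclear_genes <- chk_count(n_nuclear_genes, "n_nuclear_genes")
  if (!is.numeric(latent_assoc_strength) || length(latent_assoc_strength) != 1 ||
      abs(latent_assoc_strength) > 1) {
    stop("invalid configuration: 'latent_assoc_strength' must lie in [-1, 1]")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) stop("invalid configuration: 'seed' must be an integer")
  structure(
    list(
      annotation = annotation,
      n_samples_per_group = n_samples_per_group,
      group_labels = group_labels,
      group_edit_multiplier = group_edit_multiplier,
      depth_mean = depth_mean,
      depth_sigma = depth_sigma,
      edit_site_density = edit_site_density,
      base_edit_rate = base_edit_rate,
      signature_sd = signature_sd,
      snv_density = snv_density,
      seq_error_rate = seq_error_rate,
      antisense_fraction = antisense_fraction,
      n_nuclear_genes = n_nuclear_genes,
      latent_assoc_strength = latent_assoc_strength,
      seed = seed
    ),
    class = "sim_config"
  )
}

#' Aging-scenario default configuration
#'
#' Three age groups on the full-length (16,569 nt) chromosome with editing
#' multipliers (1.0, 1.0, 2.0): mitochondrial A-to-I editing is flat through
#' midlife and doubles in the oldest group, mirroring the two-fold rise in
#' edited ChrM transcripts reported in aged human cortex. 40 samples per
#' group. All other parameters are the package defaults.
#'
#' @param seed Integer seed stored in the configuration.
#' @return A `sim_config`.
#' @export
aging_scenario_defaults <- function(seed = 1L) {
  simulation_config(
    annotation = default_mito_annotation(),
    n_samples_per_group = 40L,
    group_labels = c("young", "middle", "old"),
    group_edit_multiplier = c(young = 1, middle = 1, old = 2),
    seed = seed
  )
}

#' Per-sample depth sampler
#'
#' Realized mean ChrM depths are log-normal with median `depth_mean` and
#' log-scale SD `depth_sigma` — the heavy-tailed rRNA-depletion variability
#' that the percentile QC rule is designed to trim.
#'
#' @param n Number of samples.
#' @param depth_mean Median depth.
#' @param depth_sigma Log-scale SD.
#' @return Numeric vector of depths.
#' @export
sample_depths <- function(n, depth_mean, depth_sigma) {
  rlnorm(n, meanlog = log(depth_mean), sdlog = depth_sigma)
}

# Chain-binomial multinomial split of n errors over 3 alternative bases.
split_errors <- function(n_err) {
  e1 <- rbinom(length(n_err), n_err, 1 / 3)
  e2 <- rbinom(length(n_err), n_err - e1, 1 / 2)
  cbind(e1, e2, n_err - e1 - e2)
}

# Precompute everything about the read layer that does not depend on the
# sample: base indices, error-target bases, and the aggregation map from
# layer rows to output (pos, stratum) pileup rows.
prepare_sim_frame <- function(layer) {
  # sort by (stratum, pos) so that, when no two genes share a (pos, stratum),
  # layer rows coincide with output pileup rows and no aggregation copy is
  # needed
  layer <- copy(layer)
  setorder(layer, stratum, pos)
  n <- nrow(layer)
  true_i <- match(layer$true_base, BASES)
  ed_i <- match(layer$edit_base, BASES)
  other <- matrix(0L, nrow = n, ncol = 3)
  for (b in 1:4) {
    rows <- true_i == b
    other[rows, ] <- matrix(setdiff(1:4, b), sum(rows), 3, byrow = TRUE)
  }
  rowkey <- paste(layer$stratum, layer$pos)
  skel <- unique(data.table(
    strand = layer$stratum, pos = layer$pos, ref = layer$ref, rowkey = rowkey
  ))
  setorder(skel, strand, pos)
  gid <- match(rowkey, skel$rowkey)
  he <- which(!is.na(ed_i))
  rows <- seq_len(n)
  list(
    layer = layer, n = n, frac = layer$frac,
    edit_rows = he, # sense-orientation rows at edit sites
    idx_true = cbind(rows, true_i),
    idx_ed = cbind(he, ed_i[he]),
    other = other,
    gid = gid, n_groups = nrow(skel),
    direct = anyDuplicated(gid) == 0 && all(gid == seq_len(n)),
    skel_pos = skel$pos, skel_ref = skel$ref, skel_strand = skel$strand
  )
}

# Simulate one sample's pileup from a prepared frame.
sim_sample_pileup <- function(sample_id, chrom, frame, depth, edit_rate,
                              seq_error_rate) {
  n <- frame$n
  er <- frame$edit_rows
  reads <- rpois(n, depth * frame$frac)
  # edited reads occur only on sense-orientation reads at edit sites
  edited_er <- rbinom(length(er), reads[er], edit_rate)
  unedited <- reads
  unedited[er] <- unedited[er] - edited_er
  errs <- rbinom(n, unedited, seq_error_rate)
  retained <- unedited - errs

  counts <- matrix(0L, nrow = n, ncol = 4L)
  counts[frame$idx_true] <- retained
  counts[frame$idx_ed] <- counts[frame$idx_ed] + edited_er
  miscalled <- which(errs > 0)
  if (length(miscalled) > 0) {
    err_split <- split_errors(errs[miscalled])
    for (j in 1:3) {
      idx <- cbind(miscalled, frame$other[miscalled, j])
      counts[idx] <- counts[idx] + err_split[, j]
    }
  }
  # every (pos, stratum) group has at least one layer row; when groups are
  # unique and pre-sorted the aggregation is the identity
  agg <- if (frame$direct) counts else rowsum(counts, frame$gid, reorder = TRUE)
  stopifnot(nrow(agg) == frame$n_groups)
  keep <- rowSums(agg) > 0
  agg <- agg[keep, , drop = FALSE]
  baseq <- round(rnorm(nrow(agg), 35, 2), 1)
  baseq[baseq < 2] <- 2
  out <- list(
    sample_id = rep(sample_id, nrow(agg)), chrom = rep(chrom, nrow(agg)),
    pos = frame$skel_pos[keep], ref = frame$skel_ref[keep],
    strand = frame$skel_strand[keep],
    count_A = agg[, 1], count_C = agg[, 2], count_G = agg[, 3],
    count_T = agg[, 4],
    mean_baseq = baseq
  )
  structure(out, class = "data.frame", row.names = c(NA, -nrow(agg)))
}

#' Simulate a cohort with known ground truth
#'
#' Generates, under a single seed: a strand-aware pileup per sample over the
#' annotated genes; an expression count matrix whose designated panel is
#' coupled to the latent per-sample editing propensity; a clinical table with
#' monotone group dependence and latent coupling; and truth tables for every
#' injected quantity.
#'
#' Reads are simulated at the pileup level. For every position of every
#' gene, sense-read coverage is Poisson around the sample's realized depth,
#' a per-gene fraction of reads is flipped to the antisense orientation, and
#' base identities follow: the plus-strand reference everywhere, the
#' alternate allele at homoplasmic variant sites, A-to-I edits (G on the
#' plus strand for H-strand genes, C for L-strand genes) at editable sites
#' on sense reads only, and uniform miscalls at `seq_error_rate`.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `annotation`, `pileups` (named list of
#'   per-sample data.frames), `expression` (list with `counts` matrix and
#'   `gene_sets`), `clinical` (data.frame), and `truth` (list of truth
#'   tables).
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) stop("config must be a sim_config")
  set.seed(config$seed)
  ann <- config$annotation
  L <- ann$length

  ref_seq <- sample(BASES, L, replace = TRUE)
  posmap <- gene_position_map(ann)
  posmap[, ref := ref_seq[pos]]
  # transcript-strand base: complement of plus-strand ref for L-strand genes
  posmap[, ts_base := ifelse(strand == "+", ref, base_complement(ref))]

  # --- truth: edit sites (ref base A on the transcript strand) ---
  candidates <- posmap[ts_base == "A"]
  n_edit <- min(rpois(1, config$edit_site_density * L / 1000), nrow(candidates))
  edit_idx <- sort(sample.int(nrow(candidates), n_edit))
  edit_sites <- candidates[edit_idx]
  edit_sites[, edit_base := ifelse(strand == "+", "G", "C")]

  # --- truth: homoplasmic SNV sites, disjoint from edit sites ---
  snv_pool <- posmap[!(pos %in% edit_sites$pos)]
  snv_pool <- snv_pool[!duplicated(pos)]
  n_snv <- min(rpois(1, config$snv_density * L / 1000), nrow(snv_pool))
  snv_idx <- sort(sample.int(nrow(snv_pool), n_snv))
  snv_sites <- snv_pool[snv_idx, .(pos, ref)]
  if (n_snv > 0) {
    snv_sites[, alt := vapply(ref, function(b) sample(setdiff(BASES, b), 1), "")]
  } else {
    snv_sites[, alt := character(0)]
  }

  # --- samples ---
  groups <- rep(config$group_labels, each = config$n_samples_per_group)
  n_total <- length(groups)
  sample_ids <- sprintf("S%03d_%s", seq_len(n_total), groups)
  depths <- sample_depths(n_total, config$depth_mean, config$depth_sigma)
  propensity <- exp(rnorm(n_total, 0, config$signature_sd))
  multiplier <- config$group_edit_multiplier[groups]

  # per-gene antisense fraction
  af_by_gene <- config$antisense_fraction
  if (is.null(names(af_by_gene))) {
    af_by_gene <- setNames(rep(af_by_gene, nrow(ann$genes)), ann$genes$name)
  }
  af_by_gene <- af_by_gene[ann$genes$name]

  # read layer: one row per (pos, gene, orientation)
  base_layer <- posmap[, .(pos, gene, gstrand = strand, ref)]
  base_layer[, af := af_by_gene[gene]]
  sense <- copy(base_layer)[, `:=`(sense = TRUE, stratum = gstrand, frac = 1 - af)]
  anti <- copy(base_layer)[, `:=`(
    sense = FALSE, stratum = ifelse(gstrand == "+", "-", "+"), frac = af
  )]
  layer <- rbindlist(list(sense, anti))
  # true (pre-edit, pre-error) base on the plus strand: SNV alt where injected
  layer[, true_base := ref]
  if (n_snv > 0) {
    m <- match(layer$pos, snv_sites$pos)
    layer[!is.na(m), true_base := snv_sites$alt[m[!is.na(m)]]]
  }
  layer[, edit_base := NA_character_]
  key <- paste(layer$pos, layer$gene)
  ekey <- paste(edit_sites$pos, edit_sites$gene)
  em <- match(key, ekey)
  layer[!is.na(em) & layer$sense, edit_base := edit_sites$edit_base[em[!is.na(em) & layer$sense]]]
  layer[, is_edit := !is.na(edit_base)]

  pileups <- vector("list", n_total)
  names(pileups) <- sample_ids
  exp_edited_reads <- numeric(n_total)
  exp_detect_sites <- numeric(n_total)
  sense_edit <- layer[sense & is_edit]
  frame <- prepare_sim_frame(layer)
  for (s in seq_len(n_total)) {
    rate_s <- pmin(1, config$base_edit_rate * multiplier[s] * propensity[s])
    pileups[[s]] <- sim_sample_pileup(
      sample_ids[s], ann$chrom, frame, depths[s], rate_s,
      config$seq_error_rate
    )
    lam <- depths[s] * sense_edit$frac * rate_s
    exp_edited_reads[s] <- sum(lam)
    # expected number of sites with >= 2 edited reads (Poisson approximation)
    exp_detect_sites[s] <- sum(1 - exp(-lam) - lam * exp(-lam))
  }

  # --- latent signature and expression matrix ---
  lat <- log(pmax(config$base_edit_rate * multiplier * propensity, 1e-12))
  z <- if (sd(lat) > 0) as.numeric(scale(lat)) else rep(0, n_total)
  rho <- config$latent_assoc_strength
  ng <- config$n_nuclear_genes
  gene_ids <- sprintf("G%04d", seq_len(ng))
  mu <- rlnorm(ng, log(100), 1)
  size <- 20
  n_coupled <- min(40L, ng)
  counts <- matrix(0L, nrow = ng, ncol = n_total,
                   dimnames = list(gene_ids, sample_ids))
  for (g in seq_len(ng)) {
    if (g <= n_coupled && rho != 0) {
      latg <- rho * z + sqrt(1 - rho^2) * rnorm(n_total)
      counts[g, ] <- qnbinom(pnorm(latg), mu = mu[g], size = size)
    } else {
      counts[g, ] <- rnbinom(n_total, mu = mu[g], size = size)
    }
  }
  half <- n_coupled %/% 2
  gene_sets <- list(
    signature_coupled = gene_ids[seq_len(n_coupled)],
    mito_like = gene_ids[seq.int(half + 1, min(half + n_coupled, ng))],
    background = gene_ids[seq.int(n_coupled + 1, ng)]
  )
  expression <- expression_matrix(counts, gene_sets)

  # --- clinical table (monotone in group, latent-coupled) ---
  gidx <- match(groups, config$group_labels)
  mix <- function() rho * z + sqrt(1 - rho^2) * rnorm(n_total)
  age <- round(25 + 18 * (gidx - 1) + runif(n_total, -5, 5))
  mmse <- pmin(30, pmax(0, round(29 - 1.2 * (gidx - 1) - 3 * mix() + rnorm(n_total, 0, 1))))
  braak <- pmin(6, pmax(0, round(1.5 + 0.7 * (gidx - 1) + 1.5 * mix() + rnorm(n_total, 0, 0.5))))
  cerad <- pmin(3, pmax(0, round(0.8 + 0.5 * (gidx - 1) + 0.8 * mix() + rnorm(n_total, 0, 0.4))))
  p4 <- pmin(0.5, 0.15 + 0.08 * (gidx - 1))
  draw_allele <- function(p_e4) {
    sample(c("e2", "e3", "e4"), 1, prob = c(0.08, 1 - 0.08 - p_e4, p_e4))
  }
  apoe <- vapply(p4, function(p) {
    paste(sort(c(draw_allele(p), draw_allele(p))), collapse = "/")
  }, "")
  clinical <- data.frame(
    sample_id = sample_ids, group = groups, age = age, mmse = mmse,
    braak = braak, cerad = cerad, apoe = apoe, stringsAsFactors = FALSE
  )

  truth <- list(
    edit_sites = {
      es <- as.data.frame(edit_sites[, .(pos, strand, gene)])
      for (gl in config$group_labels) {
        es[[paste0("rate_", gl)]] <- rep(
          pmin(1, config$base_edit_rate * config$group_edit_multiplier[[gl]]),
          nrow(es)
        )
      }
      es
    },
    snv_sites = as.data.frame(snv_sites),
    per_sample = data.frame(
      sample_id = sample_ids, group = groups,
      true_depth = depths, propensity = propensity,
      latent_z = z,
      true_signature = exp_detect_sites,
      true_edit_burden = exp_edited_reads,
      stringsAsFactors = FALSE
    )
  )

  list(
    annotation = ann, pileups = pileups, expression = expression,
    clinical = clinical, truth = truth, config = config
  )
}
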