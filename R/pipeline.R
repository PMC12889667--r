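#' Pipeline run configuration
#'
#' Exactly one of simulate mode (a [simulation_config()]) or input paths
#' must be active. Every analysis choice (counting mode, percentile bounds,
#' adjustment method, alpha, reference group) is part of the configuration
#' and is echoed into the run manifest so runs are auditable.
#'
#' @param sim_config A [simulation_config()] for simulate mode, or `NULL`.
#' @param paths Named list of input paths (`annotation`, `pileup_dir`,
#'   `expression`, `gene_sets`, `clinical`) for file mode, or `NULL`.
#' @param caller A [caller_params()].
#' @param recurrence_filter Enable the cohort recurrence filter.
#' @param counting_mode `"sites"` or `"edited_reads"` for the signature.
#'   The pipeline defaults to `"edited_reads"`: read-weighted counts stay
#'   proportional to the underlying editing rate even when per-site
#'   detection saturates at high coverage.
#' @param qc_lower,qc_upper Percentile QC bounds.
#' @param adjustment Multiplicity adjustment for correlation panels.
#' @param alpha Significance level.
#' @param intersection_rule `"raw"` or `"adjusted"` significance rule for
#'   the intersectional analysis.
#' @param reference_group Reference group label for relative expression;
#'   defaults to the first group.
#' @param seed Integer seed (overrides the sim_config seed when supplied).
#' @return A list of class `run_config`.
#' @export
run_config <- function(sim_config = NULL, paths = NULL,
                       caller = caller_params(),
                       recurrence_filter = FALSE,
                       counting_mode = c("edited_reads", "sites"),
                       qc_lower = 5, qc_upper = 95,
                       adjustment = c("BH", "bonferroni", "none"),
                       alpha = 0.05,
                       intersection_rule = c("raw", "adjusted"),
                       reference_group = NULL,
                       seed = NULL) {
  counting_mode <- match.arg(counting_mode)
  adjustment <- match.arg(adjustment)
  intersection_rule <- match.arg(intersection_rule)
  if (is.null(sim_config) == is.null(paths)) {
    stop("exactly one of sim_config or paths must be supplied")
  }
  if (!is.null(paths)) {
    # clinical is optional at configuration time; the association stage
    # aborts if it is requested without one
    required <- c("annotation", "pileup_dir", "expression")
    for (nm in required) {
      if (is.null(paths[[nm]])) stop("paths$", nm, " is required")
    }
    for (nm in names(paths)) {
      if (!file.exists(paths[[nm]])) stop("input path does not exist: ", paths[[nm]])
    }
  }
  if (!is.null(seed) && !is.null(sim_config)) {
    sim_config$seed <- as.integer(seed)
  }
  structure(list(
    sim_config = sim_config, paths = paths, caller = caller,
    recurrence_filter = recurrence_filter,
    counting_mode = counting_mode,
    qc_lower = qc_lower, qc_upper = qc_upper,
    adjustment = adjustment, alpha = alpha,
    intersection_rule = intersection_rule,
    reference_group = reference_group,
    seed = if (!is.null(seed)) as.integer(seed)
           else if (!is.null(sim_config)) sim_config$seed else NA_integer_
  ), class = "run_config")
}

stage_fail <- function(stage_no, stage_name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("stage %d (%s) failed: %s", stage_no, stage_name,
                 conditionMessage(e)), call. = FALSE)
  })
}

checksums <- function(files) {
  files <- files[file.exists(files)]
  sums <- tools::md5sum(files)
  setNames(unname(sums), basename(files))
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or simulate the cohort, (2) call edits per sample and
#' apply cohort filters, (3) scaling factors + percentile QC + signatures,
#' (4) editing landscape, (5) group statistics, (6) association suite
#' (correlation panels, intersection, gene-set overlap). Every stage
#' writes fixed-name outputs under `outdir` and the run closes with a JSON
#' manifest carrying the resolved configuration, package version and
#' per-stage file checksums. Deterministic given config + seed. Any stage
#' error aborts with the stage name.
#'
#' @param config A [run_config()].
#' @param outdir Output directory.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config, outdir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(schema_version = "1.0", seed = config$seed,
                   package_version = as.character(utils::packageVersion("mtdsrna")),
                   stages = list())
  log_stage <- function(name, files) {
    manifest$stages[[name]] <<- list(outputs = as.list(checksums(files)))
    message(sprintf("[%s] %d output file(s)", name, length(files)))
  }

  # stage 1: load/simulate
  cohort <- stage_fail(1, "load", {
    if (!is.null(config$sim_config)) {
      co <- simulate_cohort(config$sim_config)
      write_cohort(co, file.path(outdir, "cohort"))
      co
    } else {
      ann <- read_annotation(config$paths$annotation)
      pfiles <- list.files(config$paths$pileup_dir, pattern = "\\.tsv$",
                           full.names = TRUE)
      if (length(pfiles) == 0) stop("no pileup files found")
      pileups <- lapply(pfiles, read_pileup, annotation = ann)
      names(pileups) <- vapply(pileups, function(p) p$sample_id[1], "")
      expr <- read_expression(config$paths$expression, config$paths$gene_sets)
      clin <- if (!is.null(config$paths$clinical)) {
        read_clinical(config$paths$clinical)
      } else {
        NULL
      }
      list(annotation = ann, pileups = pileups, expression = expr,
           clinical = clin, truth = NULL, config = NULL)
    }
  })
  stage1_files <- if (!is.null(config$sim_config)) {
    list.files(file.path(outdir, "cohort"), recursive = TRUE, full.names = TRUE)
  } else {
    character(0)
  }
  log_stage("load", stage1_files)

  # stage 2: edit calling + cohort filters
  callsets <- stage_fail(2, "call_edits", {
    cs <- lapply(cohort$pileups, call_sample, annotation = cohort$annotation,
                 params = config$caller)
    apply_cohort_filters(cs, config$caller,
                         recurrence = config$recurrence_filter)
  })
  calls_path <- file.path(outdir, "calls.tsv")
  write_calls(callsets, calls_path)
  log_stage("call_edits", calls_path)

  # stage 3: scaling factors, QC, signatures
  sig <- stage_fail(3, "signature", {
    chrm_reads <- vapply(cohort$pileups, chrm_read_total, numeric(1))
    library_size <- chrm_reads + colSums(cohort$expression$counts)[names(chrm_reads)]
    groups <- if (!is.null(cohort$clinical)) {
      setNames(cohort$clinical$group, cohort$clinical$sample_id)
    } else {
      NULL
    }
    build_signature_table(
      callsets, chrm_reads, groups = groups, library_size = library_size,
      counting_mode = config$counting_mode,
      lower = config$qc_lower, upper = config$qc_upper
    )
  })
  sig_path <- file.path(outdir, "signature.tsv")
  data.table::fwrite(sig, sig_path, sep = "\t", quote = FALSE)
  log_stage("signature", sig_path)

  # stage 4: landscape
  landscape <- stage_fail(4, "landscape", {
    list(
      bins = bin_edits(callsets, cohort$annotation, bin_size = 200),
      per_gene = per_gene_edit_share(callsets, cohort$annotation),
      antisense = antisense_fraction(cohort$pileups, cohort$annotation)
    )
  })
  land_files <- file.path(outdir, c("landscape_bins.tsv", "landscape_per_gene.tsv",
                                    "landscape_antisense.tsv"))
  data.table::fwrite(landscape$bins, land_files[1], sep = "\t", quote = FALSE)
  data.table::fwrite(landscape$per_gene, land_files[2], sep = "\t", quote = FALSE)
  data.table::fwrite(landscape$antisense, land_files[3], sep = "\t", quote = FALSE)
  log_stage("landscape", land_files)

  # stage 5: group statistics on QC-passing samples
  group_stats <- stage_fail(5, "group_stats", {
    kept <- sig[sig$qc_pass, ]
    if (!all(is.na(kept$group)) && length(unique(kept$group)) >= 2) {
      ref <- config$reference_group %||% unique(kept$group)[1]
      cmp <- group_comparison(kept$signature, kept$group)
      rel <- relative_expression(
        cohort$expression$counts[, kept$sample_id, drop = FALSE],
        setNames(kept$group, kept$sample_id), ref
      )
      list(comparison = cmp, relative = rel)
    } else {
      list(comparison = NULL, relative = NULL)
    }
  })
  gs_files <- character(0)
  if (!is.null(group_stats$comparison)) {
    gs_files <- file.path(outdir, c("group_comparison.json", "relative_expression.tsv"))
    cmp <- group_stats$comparison
    jsonlite::write_json(
      list(groups = cmp$groups, normality = cmp$normality,
           omnibus = cmp$omnibus, posthoc_method = cmp$posthoc_method,
           posthoc = cmp$posthoc),
      gs_files[1], pretty = TRUE, auto_unbox = TRUE, digits = NA
    )
    data.table::fwrite(group_stats$relative, gs_files[2], sep = "\t", quote = FALSE)
  }
  log_stage("group_stats", gs_files)

  # stage 6: association suite
  assoc <- stage_fail(6, "association", {
    if (is.null(cohort$clinical)) stop("clinical table required")
    kept <- sig[sig$qc_pass, ]
    clin <- cohort$clinical[match(kept$sample_id, cohort$clinical$sample_id), ]
    universe <- retain_genes(cohort$expression, samples = kept$sample_id)
    counts <- cohort$expression$counts[, kept$sample_id, drop = FALSE]
    target_sig <- setNames(kept$signature, kept$sample_id)
    target_mmse <- setNames(as.numeric(clin$mmse), kept$sample_id)
    target_braak <- setNames(as.numeric(clin$braak), kept$sample_id)
    panels <- list(
      signature = correlate_panel(target_sig, counts, universe,
                                  adjustment = config$adjustment,
                                  alpha = config$alpha),
      mmse = correlate_panel(target_mmse, counts, universe,
                             adjustment = config$adjustment,
                             alpha = config$alpha),
      braak = correlate_panel(target_braak, counts, universe,
                              adjustment = config$adjustment,
                              alpha = config$alpha)
    )
    inter <- intersect_criteria(panels[c("mmse", "braak", "signature")],
                                rule = config$intersection_rule,
                                alpha = config$alpha)
    overlap <- if ("mito_like" %in% names(cohort$expression$gene_sets)) {
      sig_genes <- panel_significant(panels$signature,
                                     rule = config$intersection_rule,
                                     alpha = config$alpha)
      hypergeom_overlap(universe,
                        intersect(cohort$expression$gene_sets$mito_like, universe),
                        sig_genes)
    } else {
      NULL
    }
    list(panels = panels, intersection = inter, overlap = overlap)
  })
  assoc_files <- file.path(outdir, c(
    "correlation_signature.tsv", "correlation_mmse.tsv",
    "correlation_braak.tsv", "intersection.json", "overlap.json"
  ))
  data.table::fwrite(assoc$panels$signature, assoc_files[1], sep = "\t", quote = FALSE)
  data.table::fwrite(assoc$panels$mmse, assoc_files[2], sep = "\t", quote = FALSE)
  data.table::fwrite(assoc$panels$braak, assoc_files[3], sep = "\t", quote = FALSE)
  jsonlite::write_json(
    list(regions = as.list(assoc$intersection$regions),
         triple = assoc$intersection$triple,
         rule = assoc$intersection$rule, alpha = assoc$intersection$alpha),
    assoc_files[4], pretty = TRUE, auto_unbox = TRUE, digits = NA
  )
  if (!is.null(assoc$overlap)) {
    jsonlite::write_json(assoc$overlap, assoc_files[5], pretty = TRUE,
                         auto_unbox = TRUE, digits = NA)
  }
  log_stage("association", assoc_files[file.exists(assoc_files)])

  # resolved config echo + manifest
  cfg_echo <- unclass(config)
  cfg_echo$caller <- unclass(cfg_echo$caller)
  if (!is.null(cfg_echo$sim_config)) {
    sc <- unclass(cfg_echo$sim_config)
    cfg_echo$sim_config <- sc[setdiff(names(sc), "annotation")]
    cfg_echo$sim_config$genome_length <- sc$annotation$length
  }
  manifest$config <- cfg_echo
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, pretty = TRUE,
                       auto_unbox = TRUE, digits = NA)
  invisible(list(
    cohort = cohort, callsets = callsets, signature = sig,
    landscape = landscape, group_stats = group_stats, association = assoc,
    manifest = manifest
  ))
}
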