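PILEUP_HEADER <- c(
  "sample_id", "chrom", "pos", "ref", "strand",
  "count_A", "count_C", "count_G", "count_T", "mean_baseq"
)

#' Read a gene annotation (BED6 or GFF3)
#'
#' Parses a circular-chromosome gene annotation through rtracklayer and
#' normalizes coordinates to the internal 1-based inclusive convention
#' (BED's 0-based half-open intervals are converted exactly).
#'
#' @param path File path.
#' @param dialect `"bed"` or `"gff3"`; `"auto"` guesses from the extension.
#' @param length Chromosome length. Required for BED (which cannot carry
#'   it); for GFF3 it is taken from the `##sequence-region` directive when
#'   omitted.
#' @return A [mito_annotation()].
#' @export
read_annotation <- function(path, dialect = c("auto", "bed", "gff3"),
                            length = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (dialect == "auto") {
    dialect <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "bed") "BED" else "GFF3"),
    error = function(e) stop("parse error in ", path, ": ", conditionMessage(e))
  )
  if (base::length(gr) == 0) stop("annotation contains no genes: ", path)
  chrom <- as.character(GenomeInfoDb::seqnames(gr))[1]
  if (is.null(length)) {
    sl <- GenomeInfoDb::seqlengths(gr)[chrom]
    if (is.na(sl) && dialect == "gff3") {
      # fall back to the ##sequence-region directive
      hdr <- readLines(path, n = 50)
      rx <- paste0("^##sequence-region\\s+", chrom, "\\s+\\d+\\s+(\\d+)")
      hit <- regmatches(hdr, regexec(rx, hdr))
      hit <- hit[vapply(hit, base::length, 1L) == 2]
      if (base::length(hit) > 0) sl <- as.numeric(hit[[1]][2])
    }
    if (is.na(sl)) {
      stop("chromosome length unavailable; pass 'length' explicitly")
    }
    length <- as.integer(sl)
  }
  name <- if (!is.null(gr$Name)) as.character(gr$Name) else as.character(gr$name)
  cls <- if (!is.null(gr$class)) as.character(gr$class) else "unspecified"
  genes <- data.frame(
    name = name,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    class = cls,
    stringsAsFactors = FALSE
  )
  if (any(!genes$strand %in% c("+", "-"))) {
    stop("validation error: every gene needs an explicit +/- strand")
  }
  if (any(genes$end > length)) {
    stop("validation error: gene end beyond declared chromosome length ", length)
  }
  mito_annotation(genes, length = length, chrom = chrom)
}

#' Write a gene annotation as BED6 or GFF3
#'
#' @param annotation A [mito_annotation()].
#' @param path Output path.
#' @param dialect `"bed"` (0-based half-open, class not representable) or
#'   `"gff3"` (1-based closed; carries the chromosome length as a
#'   `##sequence-region` directive and the gene class as an attribute).
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, dialect = c("bed", "gff3")) {
  dialect <- match.arg(dialect)
  g <- annotation$genes
  if (any(g$start > g$end)) {
    stop("origin-wrapping genes cannot be represented in ", dialect)
  }
  si <- GenomeInfoDb::Seqinfo(
    seqnames = annotation$chrom,
    seqlengths = annotation$length,
    isCircular = TRUE
  )
  gr <- GenomicRanges::GRanges(
    seqnames = annotation$chrom,
    ranges = IRanges::IRanges(start = g$start, end = g$end),
    strand = g$strand,
    seqinfo = si
  )
  if (dialect == "bed") {
    gr$name <- g$name
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "BED")
  } else {
    gr$source <- "mtdsrna"
    gr$type <- "gene"
    gr$Name <- g$name
    gr$class <- g$class
    rtracklayer::export(gr, path, format = "GFF3")
    # pin the header: declare the chromosome length and drop the date
    # stamp so identical annotations serialize identically
    lines <- readLines(path)
    lines <- lines[!grepl("^##(date|source-version)", lines)]
    lines <- append(
      lines,
      sprintf("##sequence-region %s 1 %d", annotation$chrom, annotation$length),
      after = 1
    )
    writeLines(lines, path)
  }
  invisible(path)
}

#' Read / write a strand-aware pileup table
#'
#' The pileup TSV dialect is bit-exact: header
#' `sample_id chrom pos ref strand count_A count_C count_G count_T
#' mean_baseq`, tab-separated, UTF-8, no quoting, positions ascending within
#' strand. `write_pileup` then `read_pileup` is the identity on all fields.
#'
#' @param path File path.
#' @param annotation Optional [mito_annotation()]; when supplied, positions
#'   are validated against its length.
#' @return `read_pileup`: a data.frame in the dialect's column order.
#' @export
read_pileup <- function(path, annotation = NULL) {
  if (!file.exists(path)) stop("pileup file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = list(
    character = c("sample_id", "chrom", "ref", "strand"),
    integer = c("pos", "count_A", "count_C", "count_G", "count_T"),
    numeric = "mean_baseq"
  ))
  if (!identical(names(dt), PILEUP_HEADER)) {
    stop("validation error: pileup header must be exactly: ",
         paste(PILEUP_HEADER, collapse = " "))
  }
  validate_pileup(as.data.frame(dt), annotation)
}

#' @rdname read_pileup
#' @param pileup A pileup data.frame.
#' @export
write_pileup <- function(pileup, path) {
  pileup <- validate_pileup(pileup)
  dt <- as.data.table(pileup)[order(strand, pos)]
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Validate a pileup table against its invariants
#'
#' @param pileup data.frame with the dialect's columns.
#' @param annotation Optional [mito_annotation()] for the position bound.
#' @return The validated data.frame (column-ordered).
#' @export
validate_pileup <- function(pileup, annotation = NULL) {
  if (!all(PILEUP_HEADER %in% names(pileup))) {
    stop("validation error: pileup missing column(s): ",
         paste(setdiff(PILEUP_HEADER, names(pileup)), collapse = ", "))
  }
  pileup <- as.data.frame(pileup)[PILEUP_HEADER]
  cnt <- as.matrix(pileup[c("count_A", "count_C", "count_G", "count_T")])
  if (nrow(pileup) > 0) {
    if (any(!pileup$ref %in% BASES)) stop("validation error: ref base outside {A,C,G,T}")
    if (any(!pileup$strand %in% c("+", "-"))) stop("validation error: strand outside {+,-}")
    if (any(!is.finite(cnt)) || any(cnt < 0)) {
      stop("validation error: negative or non-finite base count")
    }
    if (any(pileup$pos < 1)) stop("validation error: position < 1")
    if (!is.null(annotation) && any(pileup$pos > annotation$length)) {
      stop("validation error: position beyond chromosome length ", annotation$length)
    }
    if (any(pileup$mean_baseq < 0)) stop("validation error: mean_baseq < 0")
    if (anyDuplicated(pileup$pos * 2L + (pileup$strand == "-"))) {
      stop("validation error: duplicate (pos, strand) row")
    }
  }
  pileup
}

#' Expression matrix container
#'
#' @param counts Numeric matrix, genes in rows (named), samples in columns
#'   (named), non-negative counts.
#' @param gene_sets Named list of gene-id character vectors. Members absent
#'   from the matrix are flagged with a warning and recorded in the
#'   `missing` attribute.
#' @return A list of class `expression_matrix` with `counts` and
#'   `gene_sets`.
#' @export
expression_matrix <- function(counts, gene_sets = list()) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("validation error: counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) stop("validation error: duplicate gene identifier")
  if (anyDuplicated(colnames(counts))) stop("validation error: duplicate sample identifier")
  if (any(counts < 0)) stop("validation error: negative expression count")
  missing <- lapply(gene_sets, function(s) setdiff(s, rownames(counts)))
  missing <- missing[vapply(missing, length, 1L) > 0]
  if (length(missing) > 0) {
    warning("gene_sets members missing from matrix: ",
            paste(names(missing), collapse = ", "))
  }
  structure(list(counts = counts, gene_sets = gene_sets, missing = missing),
            class = "expression_matrix")
}

#' Read / write an expression count matrix
#'
#' TSV with a `gene_id` first column; optional gene sets are carried in a
#' JSON sidecar.
#'
#' @param path Matrix TSV path.
#' @param gene_sets_path Optional JSON file of named gene lists.
#' @return An [expression_matrix()].
#' @export
read_expression <- function(path, gene_sets_path = NULL) {
  if (!file.exists(path)) stop("expression file not found: ", path)
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  if (names(dt)[1] != "gene_id") stop("validation error: first column must be gene_id")
  if (anyDuplicated(dt$gene_id)) stop("validation error: duplicate gene identifier")
  m <- as.matrix(dt[, -1])
  rownames(m) <- dt$gene_id
  gene_sets <- if (!is.null(gene_sets_path)) {
    lapply(jsonlite::read_json(gene_sets_path), unlist)
  } else {
    list()
  }
  expression_matrix(m, gene_sets)
}

#' @rdname read_expression
#' @param expr An [expression_matrix()].
#' @export
write_expression <- function(expr, path, gene_sets_path = NULL) {
  dt <- data.table::data.table(gene_id = rownames(expr$counts))
  dt <- cbind(dt, as.data.table(expr$counts))
  data.table::fwrite(dt, path, sep = "\t", quote = FALSE)
  if (!is.null(gene_sets_path)) {
    jsonlite::write_json(expr$gene_sets, gene_sets_path, pretty = TRUE)
  }
  invisible(path)
}

APOE_ALLELES <- c("e2", "e3", "e4")

parse_apoe <- function(x) {
  parts <- strsplit(x, "/", fixed = TRUE)
  vapply(parts, function(p) {
    p <- tolower(trimws(p))
    p <- sub("^ε", "e", p) # accept epsilon notation
    if (length(p) != 2 || any(!p %in% APOE_ALLELES)) {
      stop("validation error: unknown APOE genotype '", paste(p, collapse = "/"), "'")
    }
    paste(sort(p), collapse = "/")
  }, "")
}

#' Read / write a clinical table
#'
#' TSV with columns `sample_id, group, age, mmse, braak, cerad, apoe`.
#' Validation: MMSE in `[0, 30]`, Braak in `{0..6}`, CERAD in `{0..3}`,
#' APOE genotype a pair of alleles from `{e2, e3, e4}` (epsilon notation
#' accepted, normalized to `eN/eN` with sorted alleles).
#'
#' @param path File path.
#' @param groups Optional declared set of group labels to validate against.
#' @return A validated data.frame.
#' @export
read_clinical <- function(path, groups = NULL) {
  if (!file.exists(path)) stop("clinical file not found: ", path)
  df <- as.data.frame(data.table::fread(path, sep = "\t", header = TRUE))
  validate_clinical(df, groups)
}

#' @rdname read_clinical
#' @param clinical A clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  clinical <- validate_clinical(clinical)
  data.table::fwrite(clinical, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname read_clinical
#' @export
validate_clinical <- function(clinical, groups = NULL) {
  required <- c("sample_id", "group", "age", "mmse", "braak", "cerad", "apoe")
  if (!all(required %in% names(clinical))) {
    stop("validation error: clinical table missing column(s): ",
         paste(setdiff(required, names(clinical)), collapse = ", "))
  }
  if (anyDuplicated(clinical$sample_id)) stop("validation error: duplicate sample_id")
  if (any(clinical$mmse < 0 | clinical$mmse > 30, na.rm = TRUE)) {
    stop("validation error: MMSE outside [0, 30]")
  }
  if (any(!clinical$braak %in% c(0:6, NA))) {
    stop("validation error: Braak outside {0..6}")
  }
  if (any(!clinical$cerad %in% c(0:3, NA))) {
    stop("validation error: CERAD outside {0..3}")
  }
  if (!is.null(groups) && any(!clinical$group %in% groups)) {
    stop("validation error: group label outside declared set")
  }
  clinical$apoe <- parse_apoe(clinical$apoe)
  clinical
}

#' Write a simulated cohort to disk
#'
#' Emits the annotation (BED6 and GFF3), one pileup TSV per sample, the
#' expression matrix (+ gene-set JSON), the clinical table, the truth
#' tables, and a JSON manifest echoing the configuration and seed.
#'
#' @param cohort Result of [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "pileups"), showWarnings = FALSE)
  write_annotation(cohort$annotation, file.path(dir, "annotation.bed"), "bed")
  write_annotation(cohort$annotation, file.path(dir, "annotation.gff3"), "gff3")
  for (sid in names(cohort$pileups)) {
    write_pileup(cohort$pileups[[sid]], file.path(dir, "pileups", paste0(sid, ".tsv")))
  }
  write_expression(cohort$expression, file.path(dir, "expression.tsv"),
                   file.path(dir, "gene_sets.json"))
  write_clinical(cohort$clinical, file.path(dir, "clinical.tsv"))
  for (nm in names(cohort$truth)) {
    data.table::fwrite(cohort$truth[[nm]],
                       file.path(dir, paste0("truth_", nm, ".tsv")),
                       sep = "\t", quote = FALSE)
  }
  cfg <- cohort$config
  cfg_echo <- cfg[setdiff(names(cfg), "annotation")]
  cfg_echo$genome_length <- cfg$annotation$length
  cfg_echo$genes <- cfg$annotation$genes
  jsonlite::write_json(
    list(schema_version = "1.0", seed = cfg$seed, config = cfg_echo),
    file.path(dir, "manifest.json"),
    pretty = TRUE, auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
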