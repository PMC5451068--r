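#' @name io_formats
#' @title Readers and writers for pipeline tables
#' @description
#' Every table the pipeline touches is plain TSV: expression/count matrices
#' with a header row of sample ids, a sample sheet, a BED-style annotation
#' with a biotype column, a BED-style CNV table with a report-class column,
#' one-id-per-line gene lists and a flat YAML run configuration.  Readers
#' validate and reject rather than silently coerce; writers emit files their
#' readers round-trip exactly.  Interval coordinates are 0-based half-open
#' internally and on disk (BED convention); 1-based inclusive input can be
#' converted at the boundary with `one_based = TRUE`.
NULL

lnc_biotype_levels <- c("protein_coding", "lincRNA", "antisense",
                        "processed_transcript", "sense_intronic",
                        "other_lncRNA")

read_tsv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' Read a gene x sample count matrix with its sample sheet
#'
#' @param path TSV with a `gene_id` column and one integer column per sample.
#' @param sample_sheet data.frame with columns `sample`, `condition`,
#'   `subject`, or a path to such a TSV.
#' @return list with integer `counts` matrix and validated `samples`
#'   data.frame, columns ordered as in the sheet.
#' @export
read_count_matrix <- function(path, sample_sheet) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(is.na(m))) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("malformed count row at line ", bad + 1L, " of ", path)
  }
  if (any(m < 0)) stop("negative counts in ", path)
  if (any(m != round(m))) stop("non-integer counts in ", path)
  storage.mode(m) <- "integer"
  samples <- if (is.character(sample_sheet)) {
    read_tsv_strict(sample_sheet)
  } else {
    sample_sheet
  }
  need <- c("sample", "condition", "subject")
  if (!all(need %in% names(samples))) {
    stop("sample sheet must have columns: ", paste(need, collapse = ", "))
  }
  if (!setequal(colnames(m), samples$sample)) {
    stop("sample ids in matrix header do not match the sample sheet")
  }
  list(counts = m[, samples$sample, drop = FALSE], samples = samples)
}

#' Read a nonnegative gene x sample (or gene x tissue) expression matrix
#'
#' @param path TSV with a `gene_id` column and one numeric column per sample.
#' @param metadata optional data.frame (or TSV path) whose first column names
#'   the samples; checked against the matrix header.
#' @return list with `expr` matrix and `meta` (NULL if none supplied).
#' @export
read_expression_matrix <- function(path, metadata = NULL) {
  df <- read_tsv_strict(path)
  if (names(df)[1] != "gene_id") stop("first column must be gene_id")
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  if (any(is.na(m))) {
    bad <- which(rowSums(is.na(m)) > 0)[1]
    stop("malformed expression row at line ", bad + 1L, " of ", path)
  }
  if (any(m < 0)) stop("negative expression values in ", path)
  meta <- NULL
  if (!is.null(metadata)) {
    meta <- if (is.character(metadata)) read_tsv_strict(metadata) else metadata
    ids <- meta[[1]]
    if (!setequal(colnames(m), ids)) {
      stop("sample ids in matrix header do not match the metadata")
    }
    m <- m[, ids, drop = FALSE]
  }
  list(expr = m, meta = meta)
}

#' Read the gene annotation table
#'
#' BED-style TSV: `chrom`, `start`, `end`, `gene_id`, `symbol`, `strand`
#' plus a `biotype` column from the closed biotype vocabulary.
#'
#' @param path TSV path.
#' @param one_based set TRUE if the file uses 1-based inclusive coordinates;
#'   they are converted to 0-based half-open on ingestion.
#' @return validated annotation data.frame.
#' @export
read_annotation <- function(path, one_based = FALSE) {
  df <- read_tsv_strict(path)
  need <- c("chrom", "start", "end", "gene_id", "symbol", "strand", "biotype")
  if (!all(need %in% names(df))) {
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  }
  if (one_based) df$start <- df$start - 1L
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in annotation")
  bad <- which(!(df$start < df$end))
  if (length(bad)) stop("start >= end at line ", bad[1] + 1L, " of ", path)
  if (!all(df$biotype %in% lnc_biotype_levels)) {
    stop("unknown biotype value(s): ",
         paste(unique(setdiff(df$biotype, lnc_biotype_levels)), collapse = ", "))
  }
  if (!all(df$strand %in% c("+", "-", "."))) stop("strand must be +, - or .")
  df[, c("gene_id", "symbol", "biotype", "chrom", "start", "end", "strand")]
}

#' Is a gene a lncRNA?
#'
#' Any biotype other than `protein_coding` in the closed vocabulary is
#' treated as a lncRNA biotype.
#'
#' @param annotation annotation data.frame (from [read_annotation()] or the
#'   simulator).
#' @return logical vector aligned to the annotation rows.
#' @export
is_lncRNA <- function(annotation) {
  annotation$biotype != "protein_coding"
}

#' Read a one-id-per-line gene list
#'
#' @param path text file, one gene id per line; blank lines ignored.
#' @return character vector of unique ids; empty list is an error.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- readLines(path)
  ids <- ids[nzchar(trimws(ids))]
  if (length(ids) == 0L) stop("empty gene list: ", path)
  unique(trimws(ids))
}

#' Read a CNV table, keeping one report class
#'
#' BED-style TSV with columns `chrom`, `start`, `end`, `cnv_id`,
#' `report_class`.  Records whose `report_class` differs from `class_filter`
#' are dropped (the curated CNV summary is filtered to "Major" reports).
#'
#' @param path TSV path.
#' @param class_filter report class to retain (default `"Major"`);
#'   `NULL` keeps everything.
#' @param one_based convert 1-based inclusive input coordinates.
#' @return data.frame of retained CNV records, 0-based half-open.
#' @export
read_cnvs <- function(path, class_filter = "Major", one_based = FALSE) {
  df <- read_tsv_strict(path)
  need <- c("chrom", "start", "end", "cnv_id", "report_class")
  if (!all(need %in% names(df))) {
    stop("CNV table must have columns: ", paste(need, collapse = ", "))
  }
  if (one_based) df$start <- df$start - 1L
  bad <- which(!(df$start < df$end))
  if (length(bad)) stop("start >= end at line ", bad[1] + 1L, " of ", path)
  if (!is.null(class_filter)) {
    df <- df[df$report_class %in% class_filter, , drop = FALSE]
  }
  rownames(df) <- NULL
  df[, c("cnv_id", "chrom", "start", "end", "report_class")]
}

#' Write a matrix as TSV with a gene_id column
#'
#' @param m matrix with rownames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a data.frame as TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write the annotation table in its on-disk column order
#'
#' @param annotation annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path) {
  cols <- c("chrom", "start", "end", "gene_id", "symbol", "strand", "biotype")
  write_table_tsv(annotation[, cols], path)
}

#' Write a gene list, one id per line
#'
#' @param ids character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Write every simulated input to a directory
#'
#' Emits the full plain-text dataset (counts, sample sheet, developmental
#' and tissue matrices with metadata, annotation, CNVs, gene lists, ground
#' truth) so the pipeline can be run from files alone.
#'
#' @param sim output of [simulate_dataset()].
#' @param outdir directory, created if missing.
#' @return named character vector of file paths, invisibly.
#' @export
write_dataset <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  paths <- c(
    counts = p("counts.tsv"), samples = p("samples.tsv"),
    dev_expr = p("dev_expr.tsv"), dev_meta = p("dev_meta.tsv"),
    tissue_expr = p("tissue_expr.tsv"), tissue_panel = p("tissue_panel.tsv"),
    annotation = p("annotation.tsv"), cnvs = p("cnvs.tsv"),
    truth_modules = p("truth_modules.tsv"), truth_de = p("truth_de.tsv")
  )
  write_matrix_tsv(sim$counts, paths["counts"])
  write_table_tsv(sim$samples, paths["samples"])
  write_matrix_tsv(sim$dev_expr, paths["dev_expr"])
  write_table_tsv(sim$dev_meta, paths["dev_meta"])
  write_matrix_tsv(sim$tissue_expr, paths["tissue_expr"])
  write_table_tsv(sim$tissue_panel, paths["tissue_panel"])
  write_annotation(sim$annotation, paths["annotation"])
  write_table_tsv(sim$cnvs[, c("chrom", "start", "end", "cnv_id",
                               "report_class")], paths["cnvs"])
  write_table_tsv(data.frame(gene_id = names(sim$truth$module_labels),
                             module = unname(sim$truth$module_labels)),
                  paths["truth_modules"])
  write_table_tsv(sim$truth$de_genes, paths["truth_de"])
  for (nm in names(sim$gene_lists)) {
    f <- p(paste0(nm, ".txt"))
    write_gene_list(sim$gene_lists[[nm]], f)
    paths[nm] <- f
  }
  invisible(paths)
}

#' Default run configuration
#'
#' All pipeline thresholds and parameters with their standard defaults:
#' DE significance `alpha = 0.05` and minimum absolute log2 fold change 1;
#' signed-network soft power 12; 10,000 permutations; tissue panel minimum
#' of 50 samples; 50 percent fractional-brain-expression selectivity
#' threshold; minimum module size 30.  Every value can be overridden from a
#' flat YAML file or an override list.
#'
#' @return named list of parameters.
#' @export
default_run_config <- function() {
  list(
    alpha = 0.05,
    lfc_min = 1,
    beta = 12,
    n_perm = 10000L,
    tissue_min_samples = 50L,
    specificity_threshold = 50,
    min_module_size = 30L,
    cut_quantile = 0.99,
    dispersion_mom_weight = 0.25,
    cor_method = "bicor",
    seed = 1L
  )
}

#' Read a run configuration from flat YAML, filling in defaults
#'
#' @param path YAML file of scalar key/value pairs, or NULL for defaults.
#' @param overrides optional named list applied after the file.
#' @return resolved configuration list.
#' @export
read_run_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(user)] <- user
  }
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(cfg))
    if (length(unknown)) {
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    }
    cfg[names(overrides)] <- overrides
  }
  stopifnot(cfg$alpha > 0, cfg$alpha < 1, cfg$lfc_min >= 0, cfg$beta >= 1,
            cfg$n_perm >= 1, cfg$tissue_min_samples >= 0,
            cfg$min_module_size >= 3)
  cfg
}
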