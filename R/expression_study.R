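#' Assemble an expression study
#'
#' Bundles a sparse cells-by-genes count matrix with cell- and gene-level
#' metadata into the container used by every downstream stage.
#'
#' @param counts non-negative integer matrix or sparse Matrix, cells in rows,
#'   genes in columns; dimnames are taken as cell and gene ids.
#' @param cell_meta data.frame with one row per cell. Required columns:
#'   `cell_id`, `donor`, `region` (one of `"macula"`, `"periphery"`),
#'   `condition` (one of `"control"`, `"stress"`). An optional `type` column
#'   carries cell-type labels.
#' @param gene_meta data.frame with one row per gene. Required columns:
#'   `gene_id`, `is_mito`, `is_hemoglobin` (logical flags).
#' @return An object of class `expression_study`: a list with elements
#'   `counts` (dgCMatrix), `cell_meta` and `gene_meta`.
#' @export
expression_study <- function(counts, cell_meta, gene_meta) {
  counts <- as_dgc(counts)
  if (nrow(counts) != nrow(cell_meta))
    stop_regioglia("counts has %d rows but cell_meta has %d rows",
                   nrow(counts), nrow(cell_meta))
  if (ncol(counts) != nrow(gene_meta))
    stop_regioglia("counts has %d columns but gene_meta has %d rows",
                   ncol(counts), nrow(gene_meta))
  need_cell <- c("cell_id", "donor", "region", "condition")
  miss <- setdiff(need_cell, names(cell_meta))
  if (length(miss)) stop_regioglia("cell_meta lacks column(s): %s",
                                   paste(miss, collapse = ", "))
  need_gene <- c("gene_id", "is_mito", "is_hemoglobin")
  miss <- setdiff(need_gene, names(gene_meta))
  if (length(miss)) stop_regioglia("gene_meta lacks column(s): %s",
                                   paste(miss, collapse = ", "))
  if (any(counts@x < 0)) stop_regioglia("counts must be non-negative")
  if (any(counts@x != round(counts@x)))
    stop_regioglia("counts must be integral")
  bad <- setdiff(unique(cell_meta$region), c("macula", "periphery"))
  if (length(bad)) stop_regioglia("unknown region label(s): %s",
                                  paste(bad, collapse = ", "))
  bad <- setdiff(unique(cell_meta$condition), c("control", "stress"))
  if (length(bad)) stop_regioglia("unknown condition label(s): %s",
                                  paste(bad, collapse = ", "))
  rownames(counts) <- cell_meta$cell_id
  colnames(counts) <- gene_meta$gene_id
  rownames(cell_meta) <- NULL
  rownames(gene_meta) <- NULL
  structure(list(counts = counts, cell_meta = cell_meta,
                 gene_meta = gene_meta),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d cells x %d genes\n",
              nrow(x$counts), ncol(x$counts)))
  tab <- table(group_code(x$cell_meta))
  cat("groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
dim.expression_study <- function(x) dim(x$counts)

#' Group codes for region/condition combinations
#'
#' Maps (region, condition) pairs to the two-letter codes used throughout:
#' LM (stressed macula), CM (control macula), LP (stressed periphery),
#' CP (control periphery).
#'
#' @param cell_meta cell metadata with `region` and `condition` columns.
#' @return character vector of group codes, one per cell.
#' @export
group_code <- function(cell_meta) {
  paste0(ifelse(cell_meta$condition == "stress", "L", "C"),
         ifelse(cell_meta$region == "macula", "M", "P"))
}

#' Subset an expression study by cells
#'
#' @param study an `expression_study`.
#' @param cells logical/integer index or character vector of cell ids.
#' @return the subsetted `expression_study`.
#' @export
subset_cells <- function(study, cells) {
  if (is.character(cells)) cells <- match(cells, study$cell_meta$cell_id)
  expression_study(study$counts[cells, , drop = FALSE],
                   study$cell_meta[cells, , drop = FALSE],
                   study$gene_meta)
}

#' Write a study as a 10x-style Matrix Market directory
#'
#' Writes `matrix.mtx` (genes as rows, the 10x dialect), `features.tsv`
#' (gene id, symbol, feature type, mito flag, hemoglobin flag),
#' `barcodes.tsv`, and `cell_meta.tsv`.
#'
#' @param study an `expression_study`.
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_study_10x <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(study$counts), file.path(dir, "matrix.mtx"))
  feats <- data.frame(study$gene_meta$gene_id, study$gene_meta$gene_id,
                      "Gene Expression",
                      as.integer(study$gene_meta$is_mito),
                      as.integer(study$gene_meta$is_hemoglobin))
  utils::write.table(feats, file.path(dir, "features.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  writeLines(study$cell_meta$cell_id, file.path(dir, "barcodes.tsv"))
  utils::write.table(study$cell_meta, file.path(dir, "cell_meta.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style Matrix Market directory
#'
#' Inverse of [write_study_10x()]. Plain 10x triples (three-column
#' `features.tsv`, no `cell_meta.tsv`) are accepted: mito and hemoglobin
#' flags are then inferred from `MT-` / `HB` symbol prefixes and region,
#' condition and donor default to placeholders unless `cell_meta.tsv`
#' exists.
#'
#' @param dir directory holding `matrix.mtx`, `features.tsv`, `barcodes.tsv`
#'   and optionally `cell_meta.tsv`.
#' @return an `expression_study`.
#' @export
read_study_10x <- function(dir) {
  counts <- Matrix::t(Matrix::readMM(file.path(dir, "matrix.mtx")))
  feats <- utils::read.delim(file.path(dir, "features.tsv"), header = FALSE,
                             stringsAsFactors = FALSE)
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  gene_meta <- data.frame(gene_id = feats[[1]], stringsAsFactors = FALSE)
  if (ncol(feats) >= 5) {
    gene_meta$is_mito <- as.logical(feats[[4]])
    gene_meta$is_hemoglobin <- as.logical(feats[[5]])
  } else {
    sym <- if (ncol(feats) >= 2) feats[[2]] else feats[[1]]
    gene_meta$is_mito <- grepl("^MT-", sym)
    gene_meta$is_hemoglobin <- grepl("^HB[AB]", sym)
  }
  meta_path <- file.path(dir, "cell_meta.tsv")
  if (file.exists(meta_path)) {
    cell_meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  } else {
    cell_meta <- data.frame(cell_id = barcodes, donor = "d1",
                            region = "macula", condition = "control",
                            stringsAsFactors = FALSE)
  }
  expression_study(counts, cell_meta, gene_meta)
}
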