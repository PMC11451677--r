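#' Expression matrix container
#'
#' A validated cells x genes numeric matrix carrying either raw counts or
#' log-normalized values. Gene symbols are uppercased on construction so that
#' human/mouse case differences are erased deliberately.
#'
#' @param values Numeric matrix, cells in rows, genes in columns.
#' @param cell_ids Character vector of unique cell identifiers (rows).
#' @param gene_ids Character vector of unique gene symbols (columns).
#' @param layer_tag `"counts"` (integer-valued) or `"lognorm"`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `cell_ids`, `gene_ids`, `layer_tag`.
#' @export
expression_matrix <- function(values, cell_ids = rownames(values),
                              gene_ids = colnames(values),
                              layer_tag = c("counts", "lognorm")) {
  layer_tag <- match.arg(layer_tag)
  values <- as.matrix(values)
  storage.mode(values) <- "double" # one storage mode regardless of source
  if (is.null(cell_ids) || is.null(gene_ids)) {
    abort("cell_ids and gene_ids are required")
  }
  gene_ids <- toupper(as.character(gene_ids))
  cell_ids <- as.character(cell_ids)
  if (nrow(values) != length(cell_ids) || ncol(values) != length(gene_ids)) {
    abort("dimensions of values do not match id lists", class = "trtniche_format_error")
  }
  if (anyDuplicated(cell_ids)) {
    abort("duplicate cell ids", class = "trtniche_validation_error")
  }
  if (anyDuplicated(gene_ids)) {
    abort("duplicate gene ids", class = "trtniche_validation_error")
  }
  if (!all(is.finite(values))) {
    abort("expression values must be finite", class = "trtniche_validation_error")
  }
  if (any(values < 0)) {
    abort("expression values must be nonnegative", class = "trtniche_validation_error")
  }
  if (layer_tag == "counts" && any(values != round(values))) {
    abort("counts layer must be integer-valued", class = "trtniche_validation_error")
  }
  dimnames(values) <- list(cell_ids, gene_ids)
  structure(
    list(values = values, cell_ids = cell_ids, gene_ids = gene_ids,
         layer_tag = layer_tag),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, layer '%s'\n",
              length(x$cell_ids), length(x$gene_ids), x$layer_tag))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Subset an expression matrix by cells and/or genes
#'
#' @param expr An `expr_matrix`.
#' @param cells,genes Character vectors of ids to keep (`NULL` keeps all).
#' @return An `expr_matrix`.
#' @export
subset_expression <- function(expr, cells = NULL, genes = NULL) {
  stopifnot(inherits(expr, "expr_matrix"))
  v <- expr$values
  if (!is.null(cells)) {
    missing <- setdiff(cells, expr$cell_ids)
    if (length(missing)) abort(paste("unknown cell ids:", paste(head(missing), collapse = ", ")))
    v <- v[cells, , drop = FALSE]
  }
  if (!is.null(genes)) {
    genes <- toupper(genes)
    missing <- setdiff(genes, expr$gene_ids)
    if (length(missing)) abort(paste("unknown gene ids:", paste(head(missing), collapse = ", ")))
    v <- v[, genes, drop = FALSE]
  }
  expression_matrix(v, rownames(v), colnames(v), expr$layer_tag)
}

#' Library-size log-normalization
#'
#' Scales each cell to a common library size and applies `log1p`, the standard
#' single-cell normalization. Cells with zero total counts are kept (all-zero
#' rows) and reported.
#'
#' @param expr An `expr_matrix` with a counts layer.
#' @param scale_factor Target library size (default 1e4).
#' @return An `expr_matrix` with `layer_tag = "lognorm"`.
#' @export
normalize_expression <- function(expr, scale_factor = 1e4) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (expr$layer_tag != "counts") abort("normalize_expression expects a counts layer")
  lib <- rowSums(expr$values)
  zero <- lib == 0
  if (any(zero)) {
    inform(sprintf("%d cells have zero library size; left as all-zero rows", sum(zero)))
    lib[zero] <- 1
  }
  v <- log1p(expr$values / lib * scale_factor)
  expression_matrix(v, expr$cell_ids, expr$gene_ids, "lognorm")
}

#' Read an expression matrix from Matrix Market + TSV sidecars
#'
#' Reads an MTX file with one-column gene and cell id sidecars. The on-disk
#' orientation is autodetected: if the stored dimensions match (genes, cells)
#' rather than (cells, genes) the matrix is transposed, so both conventions
#' load to the same cells x genes object.
#'
#' @param matrix_path Path to the `.mtx` file (1-based indices on disk).
#' @param genes_path,cells_path Paths to headerless single-column TSV files.
#' @param layer_tag `"counts"` or `"lognorm"`.
#' @return An `expr_matrix`.
#' @export
load_expression <- function(matrix_path, genes_path, cells_path,
                            layer_tag = c("counts", "lognorm")) {
  layer_tag <- match.arg(layer_tag)
  m <- Matrix::readMM(matrix_path)
  genes <- readLines(genes_path)
  genes <- genes[nzchar(genes)]
  cells <- readLines(cells_path)
  cells <- cells[nzchar(cells)]
  if (nrow(m) == length(cells) && ncol(m) == length(genes)) {
    # already cells x genes
  } else if (nrow(m) == length(genes) && ncol(m) == length(cells)) {
    m <- Matrix::t(m)
  } else {
    abort(sprintf("matrix is %d x %d but sidecars list %d cells and %d genes",
                  nrow(m), ncol(m), length(cells), length(genes)),
          class = "trtniche_format_error")
  }
  expression_matrix(as.matrix(m), cells, genes, layer_tag)
}

#' Write an expression matrix to Matrix Market + TSV sidecars
#'
#' @param expr An `expr_matrix`.
#' @param matrix_path,genes_path,cells_path Output paths.
#' @return Invisibly, the input.
#' @export
write_expression <- function(expr, matrix_path, genes_path, cells_path) {
  stopifnot(inherits(expr, "expr_matrix"))
  m <- Matrix::Matrix(expr$values, sparse = TRUE)
  Matrix::writeMM(m, matrix_path)
  writeLines(expr$gene_ids, genes_path)
  writeLines(expr$cell_ids, cells_path)
  invisible(expr)
}

#' Validate a cell annotation table against an expression matrix
#'
#' Checks the annotation contract: one row per cell of the companion matrix,
#' tissue and coarse type drawn from their controlled vocabularies.
#'
#' @param annotation Tibble with columns `cell_id`, `patient`, `tissue`,
#'   `cluster`, `coarse_type`.
#' @param expr Optional `expr_matrix` the annotation must cover.
#' @return The annotation, invisibly, after validation.
#' @export
validate_annotation <- function(annotation, expr = NULL) {
  need <- c("cell_id", "patient", "tissue", "cluster", "coarse_type")
  missing <- setdiff(need, names(annotation))
  if (length(missing)) {
    abort(paste("annotation missing columns:", paste(missing, collapse = ", ")),
          class = "trtniche_format_error")
  }
  if (!all(annotation$tissue %in% TISSUES)) {
    abort("tissue values outside {MT, MN, PT, PN, PBMC, LN}",
          class = "trtniche_validation_error")
  }
  if (!all(annotation$coarse_type %in% COARSE_TYPES)) {
    abort("coarse_type values outside the allowed vocabulary",
          class = "trtniche_validation_error")
  }
  if (!is.null(expr) && !all(annotation$cell_id %in% expr$cell_ids)) {
    abort("annotation refers to cells absent from the expression matrix",
          class = "trtniche_validation_error")
  }
  invisible(annotation)
}
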