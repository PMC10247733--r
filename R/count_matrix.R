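#' Construct a cells-by-genes count matrix container
#'
#' Lightweight container for UMI counts: a sparse (or dense) non-negative
#' integer matrix oriented cells x genes, plus a per-cell metadata table
#' (group/ploidy label, sample, ground-truth columns when simulated).
#'
#' @param counts Matrix or sparse Matrix, cells in rows, genes in columns,
#'   with unique row (cell) and column (gene) names.
#' @param cell_meta Optional data.frame with one row per cell; must contain a
#'   `cell_id` column covering every cell, or have rownames equal to the cell
#'   ids. A minimal one is created if omitted.
#' @return An object of class `CountMatrix`: list with elements `counts`
#'   (dgCMatrix), `cell_meta` (data.frame keyed by `cell_id`).
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have cell (row) and gene (column) names")
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix"), "generalMatrix")
  if (any(m@x < 0)) stop("negative counts are not allowed")
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(cell_id = rownames(m), stringsAsFactors = FALSE)
  }
  if (!"cell_id" %in% names(cell_meta)) {
    cell_meta <- cbind(cell_id = rownames(cell_meta), cell_meta)
  }
  if (!setequal(cell_meta$cell_id, rownames(m)) ||
      nrow(cell_meta) != nrow(m))
    stop("cell_meta must cover every cell exactly once")
  cell_meta <- cell_meta[match(rownames(m), cell_meta$cell_id), , drop = FALSE]
  rownames(cell_meta) <- NULL
  structure(list(counts = m, cell_meta = cell_meta), class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$counts)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("CountMatrix: %d cells x %d genes (%.2f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  if (!is.null(x$cell_meta$group))
    print(table(group = x$cell_meta$group))
  invisible(x)
}

#' Cell identifiers of a CountMatrix
#' @param x A `CountMatrix`.
#' @return Character vector of cell ids (row order of the matrix).
#' @export
cell_ids <- function(x) rownames(x$counts)

#' Gene identifiers of a CountMatrix
#' @param x A `CountMatrix`.
#' @return Character vector of gene ids (column order of the matrix).
#' @export
gene_ids <- function(x) colnames(x$counts)
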