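## Readers/writers for the on-disk formats: 10x-style MTX triplets, GMT gene
## sets, CSV tables. Writers are loss-free for their readers.

#' Write a CountMatrix as a 10x-style MatrixMarket triplet
#'
#' Writes `matrix.mtx` (genes x cells, 1-based coordinate indices, the usual
#' on-disk orientation), `barcodes.tsv` and `features.tsv` into a directory,
#' plus `cell_meta.csv` when metadata is present.
#'
#' @param cm A [count_matrix()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mtx <- function(cm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  Matrix::writeMM(Matrix::t(cm$counts), file.path(dir, "matrix.mtx"))
  writeLines(cell_ids(cm), file.path(dir, "barcodes.tsv"))
  writeLines(gene_ids(cm), file.path(dir, "features.tsv"))
  if (ncol(cm$cell_meta) > 1L)
    write.csv(cm$cell_meta, file.path(dir, "cell_meta.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Read a 10x-style MatrixMarket triplet into a CountMatrix
#'
#' Accepts either on-disk orientation (genes x cells or cells x genes); the
#' orientation is detected by matching the header dimensions against the
#' barcode and feature counts. Features files may have extra tab-separated
#' columns (only the first is used as the gene id).
#'
#' @param dir Directory containing `matrix.mtx`, `barcodes.tsv`,
#'   `features.tsv` (or `genes.tsv`), optionally `cell_meta.csv`.
#' @return A [count_matrix()].
#' @export
read_mtx <- function(dir) {
  mtx_path <- file.path(dir, "matrix.mtx")
  bc_path <- file.path(dir, "barcodes.tsv")
  ft_path <- file.path(dir, "features.tsv")
  if (!file.exists(ft_path)) ft_path <- file.path(dir, "genes.tsv")
  for (p in c(mtx_path, bc_path, ft_path))
    if (!file.exists(p)) stop("format error: missing file ", p)
  m <- tryCatch(Matrix::readMM(mtx_path),
                error = function(e) stop("format error in ", mtx_path, ": ",
                                         conditionMessage(e)),
                warning = function(w) stop("format error in ", mtx_path,
                                           ": ", conditionMessage(w)))
  barcodes <- readLines(bc_path)
  features <- vapply(strsplit(readLines(ft_path), "\t"), `[[`, "", 1L)
  if (anyDuplicated(barcodes))
    stop("format error: duplicate barcode in ", bc_path, " (line ",
         which(duplicated(barcodes))[1L], ")")
  if (nrow(m) == length(features) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)
  } else if (!(nrow(m) == length(barcodes) && ncol(m) == length(features))) {
    stop(sprintf(
      "format error: matrix is %d x %d but there are %d barcodes and %d features",
      nrow(m), ncol(m), length(barcodes), length(features)))
  }
  dimnames(m) <- list(barcodes, features)
  meta_path <- file.path(dir, "cell_meta.csv")
  meta <- if (file.exists(meta_path)) {
    read.csv(meta_path, stringsAsFactors = FALSE)
  } else NULL
  count_matrix(as.matrix(m), meta)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated GMT dialect: field 1 set name, field 2 description
#' (ignored), fields 3+ member gene ids. Duplicated members are collapsed
#' with a warning; an empty member list is a format error.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (set name -> members).
#' @export
read_gene_sets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("format error: ", path, " line ", i, ": no members in set '",
           f[1], "'")
    members <- f[-c(1, 2)]
    members <- members[nzchar(members)]
    if (!length(members))
      stop("format error: ", path, " line ", i, ": no members in set '",
           f[1], "'")
    if (anyDuplicated(members)) {
      warning("duplicated members collapsed in set '", f[1], "'")
      members <- unique(members)
    }
    sets[[f[1]]] <- members
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gene_sets <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Load the bundled curated cell-cycle phase signatures
#'
#' Five phase marker sets (G1S, S, G2, G2M, MG1) curated from canonical
#' human cell-cycle genes in the style of the Whitfield et al. (2002,
#' Mol. Biol. Cell) periodic-expression phase lists. Intended for real
#' datasets keyed by HGNC symbols; synthetic analyses use generator-truth
#' sets instead.
#'
#' @return Named list of five character vectors.
#' @export
bundled_phase_signatures <- function() {
  read_gene_sets(system.file("extdata", "cell_cycle_signatures.gmt",
                             package = "hapcycle", mustWork = TRUE))
}
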