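#' Read a cell-by-gene expression matrix
#'
#' Dense TSV (cells in rows by default: first column holds cell ids, header
#' holds gene names) or MatrixMarket triplets with the 10x convention (genes
#' in rows by default, plus features/barcodes files).
#'
#' @param path matrix file.
#' @param format `"dense_tsv"` or `"mtx_triplet"`.
#' @param features,barcodes id files for `mtx_triplet`; default to
#'   `features.tsv` / `barcodes.tsv` next to `path`.
#' @param genes_in_rows orientation flag; default `FALSE` for TSV, `TRUE`
#'   for MTX.
#' @param cell_type population label attached to the result.
#' @return an [expression_matrix] (dense).
#' @export
read_expression <- function(path, format = c("dense_tsv", "mtx_triplet"),
                            features = NULL, barcodes = NULL,
                            genes_in_rows = NULL, cell_type = "unknown") {
  format <- match.arg(format)
  if (format == "dense_tsv") {
    genes_in_rows <- genes_in_rows %||% FALSE
    df <- utils::read.delim(path, check.names = FALSE, row.names = 1L)
    m <- as.matrix(df)
    if (genes_in_rows) m <- t(m)
  } else {
    genes_in_rows <- genes_in_rows %||% TRUE
    dir <- dirname(path)
    features <- features %||% file.path(dir, "features.tsv")
    barcodes <- barcodes %||% file.path(dir, "barcodes.tsv")
    mm <- as.matrix(Matrix::readMM(path))
    feat <- utils::read.table(features, sep = "\t", stringsAsFactors = FALSE)[[1]]
    bc <- utils::read.table(barcodes, sep = "\t", stringsAsFactors = FALSE)[[1]]
    if (genes_in_rows) {
      if (nrow(mm) != length(feat))
        stop("feature count (", length(feat), ") != matrix rows (", nrow(mm), ")")
      if (ncol(mm) != length(bc))
        stop("barcode count (", length(bc), ") != matrix columns (", ncol(mm), ")")
      dimnames(mm) <- list(feat, bc)
      m <- t(mm)
    } else {
      if (nrow(mm) != length(bc))
        stop("barcode count (", length(bc), ") != matrix rows (", nrow(mm), ")")
      if (ncol(mm) != length(feat))
        stop("feature count (", length(feat), ") != matrix columns (", ncol(mm), ")")
      dimnames(mm) <- list(bc, feat)
      m <- mm
    }
  }
  # deduplicate gene ids with a numeric suffix policy
  if (anyDuplicated(colnames(m)))
    colnames(m) <- make.unique(colnames(m), sep = ".")
  expression_matrix(m, cell_type = cell_type)
}

#' Write an expression matrix as dense TSV (cells in rows)
#'
#' Values are written with full (repr-faithful) precision so a read/write
#' round trip is exact.
#'
#' @param mat matrix with dimnames.
#' @param path output file.
#' @export
write_expression <- function(mat, path) {
  df <- data.frame(cell_id = rownames(mat), as.data.frame(unclass(mat)),
                   check.names = FALSE)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell annotation table
#'
#' @param path TSV with columns `cell_id` and `cell_type` (header required).
#' @return data.frame with unique `cell_id` and non-empty `cell_type`.
#' @export
read_cell_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("cell_id", "cell_type") %in% names(df)))
    stop("annotation must have columns cell_id and cell_type")
  if (anyDuplicated(df$cell_id)) stop("duplicate cell ids in annotation")
  if (any(!nzchar(df$cell_type))) stop("empty cell_type labels")
  df
}

#' Split a matrix into two cell-type submatrices
#'
#' @param matrix cell-by-gene matrix with cell ids as rownames.
#' @param annotation data.frame with `cell_id`, `cell_type`.
#' @param type_a,type_b labels of the sender and receiver populations.
#' @return list with `X_A` and `X_B` ([expression_matrix]s); cells absent
#'   from the annotation are dropped with a message.
#' @export
split_by_cell_type <- function(matrix, annotation, type_a, type_b) {
  matrix <- as.matrix(matrix)
  for (ty in c(type_a, type_b)) {
    if (!ty %in% annotation$cell_type) stop("unknown cell type label: ", ty)
  }
  unannotated <- setdiff(rownames(matrix), annotation$cell_id)
  if (length(unannotated))
    message(length(unannotated), " cells absent from annotation were dropped")
  take <- function(ty) {
    ids <- intersect(rownames(matrix),
                     annotation$cell_id[annotation$cell_type == ty])
    if (length(ids) < 2L) stop("cell type ", ty, " has fewer than 2 cells")
    expression_matrix(matrix[ids, , drop = FALSE], cell_type = ty)
  }
  list(X_A = take(type_a), X_B = take(type_b))
}

#' Basic library-size log-normalization
#'
#' Convenience helper for raw counts: scales every cell to a common total,
#' then applies `log(1 + x)`. (Dedicated single-cell normalization tools are
#' the intended upstream; the method itself consumes normalized input.)
#'
#' @param matrix nonnegative cell-by-gene matrix.
#' @param scale per-cell total after scaling (default 1e4).
#' @return normalized matrix of the same shape.
#' @export
log_normalize <- function(matrix, scale = 1e4) {
  matrix <- as.matrix(matrix)
  if (any(matrix < 0)) stop("counts must be nonnegative")
  tot <- rowSums(matrix)
  if (any(tot == 0)) {
    bad <- rownames(matrix)[tot == 0] %||% which(tot == 0)
    stop("cell(s) with zero total counts: ", paste(bad, collapse = ", "))
  }
  log1p(matrix / tot * scale)
}
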