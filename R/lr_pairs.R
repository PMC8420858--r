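#' Construct a ligand-receptor pair table
#'
#' The unit of analysis is a single-gene ligand paired with a single-gene
#' receptor. Multi-subunit complexes are outside the model and are dropped at
#' load time.
#'
#' @param ligand,receptor character vectors of gene symbols.
#' @param source_tag free-text provenance label.
#' @param case case normalization applied once, here at construction:
#'   `"none"` (default; mouse/human symbol case conveys species), `"upper"`,
#'   or `"lower"`.
#' @return An object of class `lr_pair_table`: a data.frame with columns
#'   `ligand` and `receptor`, deduplicated, with attributes `source_tag` and
#'   `n_dropped_complex` / `n_dropped_unmapped` bookkeeping counters.
#' @export
lr_pair_table <- function(ligand, receptor, source_tag = "user",
                          case = c("none", "upper", "lower")) {
  case <- match.arg(case)
  ligand <- as.character(ligand)
  receptor <- as.character(receptor)
  if (length(ligand) != length(receptor))
    stop("ligand and receptor must have equal length")
  if (case == "upper") { ligand <- toupper(ligand); receptor <- toupper(receptor) }
  if (case == "lower") { ligand <- tolower(ligand); receptor <- tolower(receptor) }
  keep <- !is.na(ligand) & !is.na(receptor) & nzchar(ligand) & nzchar(receptor)
  df <- data.frame(ligand = ligand[keep], receptor = receptor[keep],
                   stringsAsFactors = FALSE)
  df <- df[!duplicated(df), , drop = FALSE]
  rownames(df) <- NULL
  if (nrow(df) == 0L) stop("no usable pairs")
  structure(df, source_tag = source_tag, n_dropped_complex = 0L,
            n_dropped_unmapped = 0L,
            class = c("lr_pair_table", "data.frame"))
}

#' @export
print.lr_pair_table <- function(x, ...) {
  cat(sprintf("LR pair table (%d pairs, source: %s)\n", nrow(x),
              attr(x, "source_tag")))
  nc <- attr(x, "n_dropped_complex")
  if (!is.null(nc) && nc > 0) cat(sprintf("  %d complex rows dropped\n", nc))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("  ... and %d more\n", nrow(x) - 10L))
  invisible(x)
}

#' Load ligand-receptor pairs from a CSV file
#'
#' Reads a two-column ligand/receptor CSV or a CellPhoneDB-style interaction
#' CSV. Rows whose ligand or receptor field encodes a multi-subunit complex
#' (contains one of `complex_sep`) are dropped and counted in the
#' `n_dropped_complex` attribute; pairs are deduplicated after the single
#' case-normalization step.
#'
#' @param path path to the CSV file (a header is required).
#' @param format `"two_column_csv"` (columns `ligand`,`receptor` by default)
#'   or `"cellphonedb_csv"` (columns `gene_a`,`gene_b` by default).
#' @param ligand_col,receptor_col column names holding the two gene symbols;
#'   defaults depend on `format`.
#' @param complex_sep characters whose presence in a symbol marks a complex.
#' @param sep field separator of the file.
#' @inheritParams lr_pair_table
#' @return An [lr_pair_table].
#' @export
load_lr_pairs <- function(path,
                          format = c("two_column_csv", "cellphonedb_csv"),
                          ligand_col = NULL, receptor_col = NULL,
                          complex_sep = c("_", ","), sep = ",",
                          case = c("none", "upper", "lower")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  ligand_col <- ligand_col %||%
    if (format == "cellphonedb_csv") "gene_a" else "ligand"
  receptor_col <- receptor_col %||%
    if (format == "cellphonedb_csv") "gene_b" else "receptor"
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", fill = TRUE)
  missing_cols <- setdiff(c(ligand_col, receptor_col), names(df))
  if (length(missing_cols))
    stop("format error: expected columns ", ligand_col, " and ", receptor_col,
         "; missing: ", paste(missing_cols, collapse = ", "))
  lig <- as.character(df[[ligand_col]])
  rec <- as.character(df[[receptor_col]])
  is_complex <- function(x) {
    hit <- rep(FALSE, length(x))
    for (s in complex_sep) hit <- hit | grepl(s, x, fixed = TRUE)
    hit
  }
  cx <- is_complex(lig) | is_complex(rec)
  n_complex <- sum(cx, na.rm = TRUE)
  lig <- lig[!cx]; rec <- rec[!cx]
  ok <- !is.na(lig) & !is.na(rec) & nzchar(lig) & nzchar(rec)
  if (!any(ok)) stop("no usable pairs in ", path)
  tab <- lr_pair_table(lig[ok], rec[ok], source_tag = basename(path),
                       case = case)
  attr(tab, "n_dropped_complex") <- as.integer(n_complex)
  tab
}

#' Restrict pairs to genes present in both expression matrices
#'
#' @param pairs an [lr_pair_table].
#' @param ligand_genes,receptor_genes gene symbols available in the sender
#'   and receiver matrices.
#' @return The subset of `pairs` whose ligand is in `ligand_genes` and whose
#'   receptor is in `receptor_genes`.
#' @export
filter_to_expressed <- function(pairs, ligand_genes, receptor_genes) {
  stopifnot(inherits(pairs, "lr_pair_table"))
  if (length(ligand_genes) == 0L || length(receptor_genes) == 0L)
    stop("gene sets must be non-empty")
  keep <- pairs$ligand %in% ligand_genes & pairs$receptor %in% receptor_genes
  if (!any(keep))
    stop("no LR pair survives expression filtering; cannot proceed")
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map pair gene symbols through an ortholog table
#'
#' Both sides of every pair are mapped through a user-supplied symbol mapping
#' (e.g. mouse-to-human orthologs). Pairs with an unmapped side are dropped
#' and counted in `n_dropped_unmapped`; one-to-many mappings expand a pair
#' combinatorially (one output row per mapped combination).
#'
#' @param pairs an [lr_pair_table].
#' @param mapping a data.frame with columns `from` and `to`, or a path to a
#'   TSV read via [read_ortholog_map].
#' @return An [lr_pair_table] on the target symbol space.
#' @export
map_orthologs <- function(pairs, mapping) {
  stopifnot(inherits(pairs, "lr_pair_table"))
  if (is.character(mapping) && length(mapping) == 1L)
    mapping <- read_ortholog_map(mapping)
  if (!is.data.frame(mapping) || !all(c("from", "to") %in% names(mapping)))
    stop("mapping must have columns 'from' and 'to'")
  if (nrow(mapping) == 0L) stop("empty mapping")
  map_one <- function(sym) mapping$to[mapping$from == sym]
  lig_out <- character(0); rec_out <- character(0)
  n_drop <- 0L
  for (i in seq_len(nrow(pairs))) {
    l <- map_one(pairs$ligand[i])
    r <- map_one(pairs$receptor[i])
    if (length(l) == 0L || length(r) == 0L) { n_drop <- n_drop + 1L; next }
    grid <- expand.grid(l = l, r = r, stringsAsFactors = FALSE)
    lig_out <- c(lig_out, grid$l)
    rec_out <- c(rec_out, grid$r)
  }
  if (length(lig_out) == 0L) stop("no pair survives ortholog mapping")
  out <- lr_pair_table(lig_out, rec_out,
                       source_tag = attr(pairs, "source_tag"))
  attr(out, "n_dropped_unmapped") <- n_drop
  attr(out, "n_dropped_complex") <- attr(pairs, "n_dropped_complex")
  out
}

#' Read an ortholog mapping TSV
#'
#' @param path TSV with two columns, source symbol then target symbol.
#' @param header whether the file has a header row.
#' @return data.frame with columns `from`, `to`.
#' @export
read_ortholog_map <- function(path, header = TRUE) {
  df <- utils::read.table(path, header = header, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 2L) stop("mapping TSV needs two columns")
  df <- df[, 1:2]
  names(df) <- c("from", "to")
  df
}
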