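#' Construct a cell-by-gene expression matrix
#'
#' Light validating wrapper around a numeric matrix: rows are cells, columns
#' are genes, both uniquely named, values finite (normalized expression).
#'
#' @param values numeric matrix, cells in rows, genes in columns, with
#'   dimnames.
#' @param cell_type label of the cell population.
#' @return the matrix with class `expression_matrix` and a `cell_type`
#'   attribute.
#' @export
expression_matrix <- function(values, cell_type = "unknown") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have cell (row) and gene (column) names")
  if (anyDuplicated(rownames(values))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(values))) stop("duplicate gene ids")
  if (!all(is.finite(values))) stop("expression values must be finite")
  structure(values, cell_type = cell_type,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d cells x %d genes (cell type: %s)\n",
              nrow(x), ncol(x), attr(x, "cell_type") %||% "unknown"))
  invisible(x)
}

#' Assemble the block-missing interaction-space matrix
#'
#' Stacks sender cells (type A, supplying ligand columns) over receiver cells
#' (type B, supplying receptor columns) into an
#' `(n_A + n_B) x (p_A + p_B)` matrix. Ligand expression is unobserved in B
#' cells and receptor expression in A cells, so exactly those two off-blocks
#' are missing (`NA`). A gene serving as both ligand and receptor keeps two
#' role-suffixed columns (`gene.L`, `gene.R`); roles are never merged.
#'
#' Rows are ordered by cell id within each block, which makes downstream
#' results invariant to the input row order.
#'
#' @param X_A sender expression matrix (must contain every pair's ligand).
#' @param X_B receiver expression matrix (must contain every pair's receptor).
#' @param pairs an [lr_pair_table] (after [filter_to_expressed]).
#' @return object of class `interaction_space`: list with `values` (NA in the
#'   missing blocks), `missing_mask`, `row_block` ("A"/"B"), `col_role`
#'   ("ligand"/"receptor"), `col_gene`, `ligand_col`/`receptor_col` maps from
#'   gene to column name, `cell_ids`, and the truth-free dimensions.
#' @export
assemble_interaction_space <- function(X_A, X_B, pairs) {
  stopifnot(inherits(pairs, "lr_pair_table"))
  X_A <- as.matrix(X_A); X_B <- as.matrix(X_B)
  ligands <- unique(pairs$ligand)
  receptors <- unique(pairs$receptor)
  missA <- setdiff(ligands, colnames(X_A))
  if (length(missA)) stop("ligand genes absent from sender matrix: ",
                          paste(missA, collapse = ", "))
  missB <- setdiff(receptors, colnames(X_B))
  if (length(missB)) stop("receptor genes absent from receiver matrix: ",
                          paste(missB, collapse = ", "))
  ordA <- order(rownames(X_A)); ordB <- order(rownames(X_B))
  A <- X_A[ordA, ligands, drop = FALSE]
  B <- X_B[ordB, receptors, drop = FALSE]
  n_A <- nrow(A); n_B <- nrow(B); p_A <- ncol(A); p_B <- ncol(B)
  stopifnot(n_A >= 1L, n_B >= 1L, p_A >= 1L, p_B >= 1L)

  clash <- intersect(ligands, receptors)
  lig_names <- ifelse(ligands %in% clash, paste0(ligands, ".L"), ligands)
  rec_names <- ifelse(receptors %in% clash, paste0(receptors, ".R"), receptors)

  values <- matrix(NA_real_, n_A + n_B, p_A + p_B,
                   dimnames = list(c(rownames(A), rownames(B)),
                                   c(lig_names, rec_names)))
  values[seq_len(n_A), seq_len(p_A)] <- A
  values[n_A + seq_len(n_B), p_A + seq_len(p_B)] <- B
  structure(list(values = values,
                 missing_mask = is.na(values),
                 row_block = rep(c("A", "B"), c(n_A, n_B)),
                 col_role = rep(c("ligand", "receptor"), c(p_A, p_B)),
                 col_gene = c(ligands, receptors),
                 ligand_col = stats::setNames(lig_names, ligands),
                 receptor_col = stats::setNames(rec_names, receptors),
                 cell_ids = c(rownames(A), rownames(B)),
                 n_A = n_A, n_B = n_B, p_A = p_A, p_B = p_B),
            class = "interaction_space")
}

#' @export
print.interaction_space <- function(x, ...) {
  cat(sprintf(
    "interaction space: (%d+%d) cells x (%d+%d) genes, %d missing entries\n",
    x$n_A, x$n_B, x$p_A, x$p_B, sum(x$missing_mask)))
  invisible(x)
}

#' Complete the interaction space with one random-forest imputation
#'
#' Grows an unsupervised forest on the incomplete matrix (missing values are
#' discarded from the split statistic; a case missing its split-variable
#' value is routed by a random in-node draw), then imputes each missing entry
#' `(cell, gene)` as the average over trees of the mean of OOB non-missing
#' values of that gene in the cell's terminal node, falling back per tree to
#' in-bag terminal values, then to the gene's overall observed mean. Observed
#' entries pass through unchanged, so every imputed value lies within the
#' gene's observed range.
#'
#' @param ism an [assemble_interaction_space] result (or any list with
#'   `values` + `missing_mask`).
#' @param params [forest_params]; `params$seed` (possibly overridden by
#'   `seed`) drives all randomness.
#' @param seed optional seed overriding `params$seed`.
#' @return object of class `imputed_dataset`: list with completed `values`,
#'   `seed`, `m` (imputation index, settable by the caller) and fallback
#'   counters.
#' @export
rf_impute <- function(ism, params = forest_params(), seed = NULL) {
  values <- ism$values
  mask <- ism$missing_mask
  n <- nrow(values); p <- ncol(values)
  if (any(colSums(!mask) == 0L)) stop("column with zero observed values")
  if (any(rowSums(!mask) == 0L)) stop("row with zero observed values")
  if (!is.null(seed)) params$seed <- as.integer(seed)
  params <- resolve_params(params, p)
  col_mean <- colMeans(values, na.rm = TRUE)
  acc <- matrix(0, n, p)
  fb_in <- 0L; fb_cm <- 0L
  for (t in seq_len(params$n_trees)) {
    set.seed(derive_seed(params$seed, "impute_tree", t))
    bs <- draw_bootstrap(n)
    raw <- cpp_grow_tree(values, values, as.integer(bs$inbag_count),
                         params$mtry, params$q_pseudo, params$nodesize,
                         params$max_depth_int, TRUE, acc, col_mean)
    fb_in <- fb_in + raw$n_fallback_inbag
    fb_cm <- fb_cm + raw$n_fallback_colmean
  }
  completed <- values
  completed[mask] <- acc[mask] / params$n_trees
  structure(list(values = completed, seed = params$seed, m = 1L,
                 n_fallback_inbag = fb_in, n_fallback_colmean = fb_cm),
            class = "imputed_dataset")
}

#' Multiple imputation of the interaction space
#'
#' `M` independent [rf_impute] runs with seeds derived deterministically from
#' `base_seed`; the datasets differ only in the imputed entries. The method's
#' default is `M = 20`, past which the aggregated index is stable.
#'
#' @inheritParams rf_impute
#' @param M number of imputations.
#' @param base_seed master seed for the M runs.
#' @return list of `M` `imputed_dataset` objects.
#' @export
multiple_impute <- function(ism, M = 20L, params = forest_params(),
                            base_seed = params$seed) {
  if (M < 1L) stop("M must be >= 1")
  lapply(seq_len(M), function(m) {
    out <- rf_impute(ism, params, seed = derive_seed(base_seed, "imputation", m))
    out$m <- m
    out
  })
}
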