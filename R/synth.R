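#' Synthetic two-population data configuration
#'
#' The generator emulates post-normalization expression of two cell
#' populations that share latent activity factors: each planted LR pair k has
#' a latent factor with one realization per cell in both populations; the
#' planted ligand gene (sender side) and receptor gene (receiver side) load
#' on it, and `n_context` context genes per block load on the same factors.
#' Context genes are essential: without cross-block informative columns,
#' completing the block-missing interaction space carries no structure at
#' all. Remaining genes are independent noise.
#'
#' @param n_A,n_B cells per population (default 200 each).
#' @param p_A,p_B genes per population (default 20 each).
#' @param n_planted number of planted LR pairs (default 5).
#' @param n_context context genes per block loading on the factors (default 5).
#' @param effect loading strength beta (default 2; 0 = pure null).
#' @param noise_sd residual standard deviation sigma (default 1).
#' @param count_model `"gaussian"` (default; values emulate normalized
#'   log-expression directly) or `"lognormal_counts"` (Poisson counts with
#'   log-normal rates, then library-size log-normalization).
#' @param candidate_mode `"all"` (default: the candidate LR table is the full
#'   p_A x p_B cross product) or `"sampled"` (planted pairs plus
#'   `n_null_pairs` random null pairs).
#' @param n_null_pairs null pairs when `candidate_mode = "sampled"`.
#' @param seed integer seed.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_A = 200L, n_B = 200L, p_A = 20L, p_B = 20L,
                         n_planted = 5L, n_context = 5L, effect = 2,
                         noise_sd = 1,
                         count_model = c("gaussian", "lognormal_counts"),
                         candidate_mode = c("all", "sampled"),
                         n_null_pairs = 50L, seed = 1L) {
  count_model <- match.arg(count_model)
  candidate_mode <- match.arg(candidate_mode)
  stopifnot(n_A >= 1L, n_B >= 1L, p_A >= 1L, p_B >= 1L,
            n_planted <= min(p_A, p_B),
            n_planted + n_context <= min(p_A, p_B),
            effect >= 0, noise_sd > 0)
  structure(list(n_A = as.integer(n_A), n_B = as.integer(n_B),
                 p_A = as.integer(p_A), p_B = as.integer(p_B),
                 n_planted = as.integer(n_planted),
                 n_context = as.integer(n_context),
                 effect = effect, noise_sd = noise_sd,
                 count_model = count_model, candidate_mode = candidate_mode,
                 n_null_pairs = as.integer(n_null_pairs),
                 seed = as.integer(seed)),
            class = "synth_config")
}

synth_block <- function(n, p, prefix, z, config) {
  K <- config$n_planted
  x <- matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
  genes <- character(p)
  # planted genes: gene k loads factor k
  for (k in seq_len(K)) {
    x[, k] <- x[, k] + config$effect * z[, k]
    genes[k] <- sprintf("%s%d", prefix, k)
  }
  # context genes: gene j loads factor ((j-1) mod K) + 1
  for (j in seq_len(config$n_context)) {
    col <- K + j
    x[, col] <- x[, col] + config$effect * z[, ((j - 1L) %% K) + 1L]
    genes[col] <- sprintf("CTX%s%d", prefix, j)
  }
  rest <- seq_len(p)[-(seq_len(K + config$n_context))]
  genes[rest] <- sprintf("NS%s%d", prefix, seq_along(rest))
  colnames(x) <- genes
  if (config$count_model == "lognormal_counts") {
    counts <- matrix(stats::rpois(length(x), lambda = exp(x)), n, p,
                     dimnames = dimnames(x))
    tot <- rowSums(counts)
    tot[tot == 0] <- 1
    x <- log1p(counts / tot * 1e4)
  }
  x
}

#' Generate a synthetic two-cell-type dataset with planted LR pairs
#'
#' @param config a [synth_config].
#' @return list with `X_A`, `X_B` ([expression_matrix]s), `pairs` (candidate
#'   [lr_pair_table]) and `truth` (list with `planted` pair data.frame, the
#'   latent factors and the generative parameters).
#' @export
generate_dataset <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  K <- config$n_planted
  z_A <- matrix(stats::rnorm(config$n_A * K), config$n_A, K)
  z_B <- matrix(stats::rnorm(config$n_B * K), config$n_B, K)
  XA <- synth_block(config$n_A, config$p_A, "LG", z_A, config)
  XB <- synth_block(config$n_B, config$p_B, "RC", z_B, config)
  rownames(XA) <- sprintf("A%03d", seq_len(config$n_A))
  rownames(XB) <- sprintf("B%03d", seq_len(config$n_B))
  planted <- data.frame(ligand = sprintf("LG%d", seq_len(K)),
                        receptor = sprintf("RC%d", seq_len(K)),
                        stringsAsFactors = FALSE)
  if (config$candidate_mode == "all") {
    grid <- expand.grid(ligand = colnames(XA), receptor = colnames(XB),
                        stringsAsFactors = FALSE)
    pairs <- lr_pair_table(grid$ligand, grid$receptor, source_tag = "synthetic")
  } else {
    null_l <- sample(colnames(XA), config$n_null_pairs, replace = TRUE)
    null_r <- sample(colnames(XB), config$n_null_pairs, replace = TRUE)
    pairs <- lr_pair_table(c(planted$ligand, null_l),
                           c(planted$receptor, null_r),
                           source_tag = "synthetic")
  }
  list(X_A = expression_matrix(XA, cell_type = "sender"),
       X_B = expression_matrix(XB, cell_type = "receiver"),
       pairs = pairs,
       truth = list(planted = planted, z_A = z_A, z_B = z_B, config = config))
}

#' Mask a complete matrix to the two-block missingness pattern
#'
#' Test helper: takes a complete `(n_A + n_B) x (p_A + p_B)` matrix (sender
#' rows first, ligand columns first), masks rows `1..n_A` on the receptor
#' columns and the remaining rows on the ligand columns, and keeps the hidden
#' truth so imputation accuracy is measurable against withheld entries.
#'
#' @param complete_matrix numeric matrix with dimnames.
#' @param n_A number of sender rows.
#' @param p_A number of ligand columns.
#' @return `interaction_space` object with a `truth` attribute holding the
#'   unmasked matrix.
#' @export
generate_block_missing <- function(complete_matrix, n_A, p_A) {
  complete_matrix <- as.matrix(complete_matrix)
  n <- nrow(complete_matrix); p <- ncol(complete_matrix)
  stopifnot(n_A >= 1L, p_A >= 1L, n_A < n, p_A < p)
  n_B <- n - n_A; p_B <- p - p_A
  values <- complete_matrix
  values[seq_len(n_A), p_A + seq_len(p_B)] <- NA_real_
  values[n_A + seq_len(n_B), seq_len(p_A)] <- NA_real_
  lig <- colnames(values)[seq_len(p_A)]
  rec <- colnames(values)[p_A + seq_len(p_B)]
  structure(list(values = values, missing_mask = is.na(values),
                 row_block = rep(c("A", "B"), c(n_A, n_B)),
                 col_role = rep(c("ligand", "receptor"), c(p_A, p_B)),
                 col_gene = colnames(values),
                 ligand_col = stats::setNames(lig, lig),
                 receptor_col = stats::setNames(rec, rec),
                 cell_ids = rownames(values),
                 n_A = n_A, n_B = n_B, p_A = p_A, p_B = p_B,
                 truth = complete_matrix),
            class = "interaction_space")
}

#' Worked tree fixture for the pairwise minimal-depth statistics
#'
#' A hand-built tree with root splitting on `h`, two maximal `v`-subtrees
#' (one of depth 1 with two terminals and no `w` split; one of depth `m = 3`
#' with four terminals containing a maximal `w`-subtree whose root sits at
#' within-subtree depth `d = 2`), so that the normalized pairwise depth of
#' `w` in the second v-subtree is `d/m = 2/3`, the minimal depth of `v` is 1,
#' and the maximal `h`-subtree is the entire tree.
#'
#' @return an `lr_tree` over variables `h`, `v`, `u`, `w` (no data attached;
#'   terminal memberships empty).
#' @export
make_figure1b_tree <- function() {
  #        1:h
  #      /     \
  #    2:v      3:v
  #   /  \     /   \
  #  4T  5T  6:u    7T
  #          / \
  #        8T   9:w
  #            /  \
  #          10T  11T
  nodes <- data.frame(
    split_var = c(1L, 2L, 2L, NA, NA, 3L, NA, NA, 4L, NA, NA),
    split_value = c(0, 0, 0, NA, NA, 0, NA, NA, 0, NA, NA),
    left  = c(2L, 4L, 6L, NA, NA, 8L, NA, NA, 10L, NA, NA),
    right = c(3L, 5L, 7L, NA, NA, 9L, NA, NA, 11L, NA, NA),
    depth = c(0L, 1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L, 4L, 4L))
  structure(list(split_var = nodes$split_var,
                 split_value = nodes$split_value,
                 left = nodes$left, right = nodes$right, depth = nodes$depth,
                 term_of_case = integer(0), inbag_count = integer(0),
                 var_names = c("h", "v", "u", "w")),
            class = "lr_tree")
}
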