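#' Pipeline configuration for LR hunting
#'
#' @param M number of imputations to aggregate over (method default 20; the
#'   aggregated index is stable from about 20 on).
#' @param n_trees trees per forest (imputation and detection stages; method
#'   default 1000).
#' @param mtry,q_pseudo,nodesize,max_depth see [forest_params].
#' @param normalization pairwise-depth normalization, `"dm"` or `"cdf"`
#'   (see [forest_pair_depth]).
#' @param seed master seed; every stage derives its stream from it.
#' @return list of class `lr_config` with per-stage [forest_params].
#' @export
lr_config <- function(M = 20L, n_trees = 1000L, mtry = NULL, q_pseudo = NULL,
                      nodesize = 5L, max_depth = Inf,
                      normalization = c("dm", "cdf"), seed = 1L) {
  normalization <- match.arg(normalization)
  stopifnot(M >= 1L)
  fp <- forest_params(n_trees = n_trees, mtry = mtry, q_pseudo = q_pseudo,
                      nodesize = nodesize, max_depth = max_depth, seed = seed)
  structure(list(M = as.integer(M), impute = fp, detect = fp,
                 normalization = normalization, seed = as.integer(seed)),
            class = "lr_config")
}

pair_key <- function(ligand, receptor) paste(ligand, receptor, sep = "|")

#' Run LR hunting end-to-end
#'
#' Assembles the interaction space from the sender/receiver matrices, imputes
#' it `M` times, grows a detection forest on each completed dataset, scores
#' every candidate LR pair with the normalized pairwise minimal-depth index,
#' aggregates over imputations (aggregated IMDI), and attaches empirical
#' p-values and ranks. Fully deterministic given `config$seed`. Direction
#' matters: ligands are taken from `X_A` and receptors from `X_B`; run again
#' with the roles swapped for the reverse direction.
#'
#' @param X_A sender (ligand-side) expression matrix, cells x genes.
#' @param X_B receiver (receptor-side) expression matrix.
#' @param pairs candidate [lr_pair_table]; pairs not expressed in both
#'   matrices are removed first.
#' @param config an [lr_config].
#' @return `lr_result_table`: data.frame with columns `ligand`, `receptor`,
#'   `imdi`, `pvalue`, `rank`, sorted ascending by `imdi` (small = strong
#'   interaction evidence). Per-imputation indices are kept in the
#'   `per_imputation` attribute.
#' @export
lr_hunting <- function(X_A, X_B, pairs, config = lr_config()) {
  pairs <- tryCatch(
    filter_to_expressed(pairs, colnames(X_A), colnames(X_B)),
    error = function(e) stop("[filter] ", conditionMessage(e), call. = FALSE))
  ism <- tryCatch(assemble_interaction_space(X_A, X_B, pairs),
                  error = function(e) stop("[assemble] ", conditionMessage(e),
                                           call. = FALSE))
  keys <- pair_key(pairs$ligand, pairs$receptor)
  lig_col <- ism$ligand_col[pairs$ligand]
  rec_col <- ism$receptor_col[pairs$receptor]

  per_imp <- vector("list", config$M)
  for (m in seq_len(config$M)) {
    imp_seed <- derive_seed(config$seed, "imputation", m)
    imp <- tryCatch(rf_impute(ism, config$impute, seed = imp_seed),
                    error = function(e) stop("[impute m=", m, "] ",
                                             conditionMessage(e), call. = FALSE))
    det <- config$detect
    det$seed <- derive_seed(config$seed, "detection", m)
    forest <- grow_forest(imp$values, det)
    pdm <- forest_pair_depth(forest, normalization = config$normalization)
    idx <- pdm$values[cbind(lig_col, rec_col)]
    per_imp[[m]] <- stats::setNames(idx, keys)
  }
  imdi <- aggregate_imdi(per_imp)
  pv <- empirical_pvalues(imdi)
  out <- data.frame(ligand = pairs$ligand, receptor = pairs$receptor,
                    imdi = unname(imdi[keys]), pvalue = unname(pv[keys]),
                    stringsAsFactors = FALSE)
  out <- out[order(out$imdi, out$ligand, out$receptor), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  structure(out, per_imputation = per_imp, config = config,
            class = c("lr_result_table", "data.frame"))
}

#' Aggregate per-imputation indices into the aggregated IMDI
#'
#' \deqn{I(S) = \frac{1}{M} \sum_{m=1}^{M} I_{(m)}(S)} for every candidate
#' pair S.
#'
#' @param per_imputation_values list of M named numeric vectors (one value
#'   per pair, identical name sets).
#' @return named numeric vector of aggregated indices in [0, 1].
#' @export
aggregate_imdi <- function(per_imputation_values) {
  stopifnot(length(per_imputation_values) >= 1L)
  keys <- names(per_imputation_values[[1]])
  for (v in per_imputation_values) {
    if (!identical(sort(names(v)), sort(keys)))
      stop("mismatched pair key sets across imputations")
  }
  mat <- vapply(per_imputation_values, function(v) v[keys], numeric(length(keys)))
  mat <- matrix(mat, nrow = length(keys))
  stats::setNames(rowMeans(mat), keys)
}

#' Empirical p-values over the candidate-pair ensemble
#'
#' Left-tail empirical proportion: `p(S) = #(I(S') <= I(S)) / n` over all
#' candidate pairs (smaller index = stronger interaction = smaller p). By
#' construction `p` lies in `[1/n, 1]` and sorting by `p` reproduces the
#' sorting by the index itself.
#'
#' @param imdi named numeric vector of aggregated indices (>= 2 pairs).
#' @return named numeric vector of p-values.
#' @export
empirical_pvalues <- function(imdi) {
  if (length(imdi) < 2L)
    stop("at least 2 pairs are needed for an empirical distribution")
  stats::setNames(rank(imdi, ties.method = "max") / length(imdi), names(imdi))
}

#' Sum pair ranks across samples
#'
#' Cross-sample summary used for drawing interaction (circos) diagrams: for
#' every pair seen in any sample, ranks are summed across samples; a sample
#' not containing the pair contributes its own `max(rank) + 1` as penalty.
#' `frequency` counts the samples actually containing the pair.
#'
#' @param tables list of `lr_result_table`s (one per sample/patient).
#' @return data.frame with `ligand`, `receptor`, `rank_sum`, `frequency`,
#'   sorted ascending by `rank_sum` (small = consistently strong).
#' @export
sum_ranks_across_samples <- function(tables) {
  if (length(tables) == 0L) stop("empty table list")
  keys <- unique(unlist(lapply(tables, function(t) pair_key(t$ligand, t$receptor))))
  rank_sum <- stats::setNames(numeric(length(keys)), keys)
  freq <- stats::setNames(integer(length(keys)), keys)
  for (t in tables) {
    tk <- pair_key(t$ligand, t$receptor)
    penalty <- max(t$rank) + 1
    r <- stats::setNames(rep(penalty, length(keys)), keys)
    r[tk] <- t$rank
    rank_sum <- rank_sum + r
    freq[tk] <- freq[tk] + 1L
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  out <- data.frame(ligand = vapply(parts, `[`, "", 1L),
                    receptor = vapply(parts, `[`, "", 2L),
                    rank_sum = unname(rank_sum),
                    frequency = unname(freq), stringsAsFactors = FALSE)
  out <- out[order(out$rank_sum), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Penalized-product LR score (comparison baseline)
#'
#' The regularized geometric-mean expression score used by product-based LR
#' ranking methods: `sqrt(l * r) / (mu + sqrt(l * r))`, in [0, 1), monotone
#' in the product. Used only to rank pairs for method comparison.
#'
#' @param ligand_mean,receptor_mean mean expression (>= 0) of ligand in the
#'   sender and receptor in the receiver cells (vectorized).
#' @param mu positive scale; conventionally the mean of all nonzero
#'   expression values.
#' @return scores in [0, 1).
#' @export
lr_score <- function(ligand_mean, receptor_mean, mu) {
  if (any(ligand_mean < 0) || any(receptor_mean < 0))
    stop("expression means must be nonnegative")
  if (mu <= 0) stop("mu must be positive")
  g <- sqrt(ligand_mean * receptor_mean)
  g / (mu + g)
}

#' Compare an LR hunting ranking with a score-based ranking
#'
#' @param a an `lr_result_table` (small `imdi` = strong).
#' @param b data.frame with `ligand`, `receptor`, `score` (large = strong).
#' @param k top-k set size for the overlap fraction.
#' @return list with `correlation` (Spearman, over shared pairs, between the
#'   two strength rankings) and `top_k_overlap`.
#' @export
compare_rankings <- function(a, b, k = 25L) {
  ka <- pair_key(a$ligand, a$receptor)
  kb <- pair_key(b$ligand, b$receptor)
  shared <- intersect(ka, kb)
  if (length(shared) == 0L) stop("no shared pairs between the two rankings")
  ra <- rank(a$imdi[match(shared, ka)])           # 1 = strongest
  rb <- rank(-b$score[match(shared, kb)])
  rho <- stats::cor(ra, rb, method = "spearman")
  k <- min(k, length(shared))
  top_a <- shared[order(ra)][seq_len(k)]
  top_b <- shared[order(rb)][seq_len(k)]
  list(correlation = rho,
       top_k_overlap = length(intersect(top_a, top_b)) / k)
}

#' Write an LR result table to TSV
#'
#' @param table an `lr_result_table` (or the [sum_ranks_across_samples]
#'   output).
#' @param path output file.
#' @export
write_lr_results <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
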