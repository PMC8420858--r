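#' Forest hyper-parameters
#'
#' @param n_trees number of trees (the method's default is 1000).
#' @param mtry candidate split variables per node; default `ceiling(sqrt(p))`
#'   resolved when growing.
#' @param q_pseudo number of pseudo-response variables redrawn at every node
#'   for the unsupervised multivariate split statistic; default
#'   `min(p, ceiling(sqrt(p)))`.
#' @param nodesize minimum in-bag size of a terminal node; a node with fewer
#'   than `2 * nodesize` in-bag cases is not split.
#' @param max_depth optional depth cap (`Inf` = none).
#' @param seed integer seed; all tree-level randomness is derived from it.
#' @param unsupervised_mode `"pseudo_response"` (default): per node, a fresh
#'   random set of `q_pseudo` data columns is the multivariate regression
#'   target. `"synthetic_contrast"`: a synthetic dataset is drawn once per
#'   forest from the column marginals and its columns are the targets.
#' @return list of class `forest_params`.
#' @export
forest_params <- function(n_trees = 1000L, mtry = NULL, q_pseudo = NULL,
                          nodesize = 5L, max_depth = Inf, seed = 1L,
                          unsupervised_mode = c("pseudo_response",
                                                "synthetic_contrast")) {
  unsupervised_mode <- match.arg(unsupervised_mode)
  stopifnot(n_trees >= 1L, nodesize >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 q_pseudo = q_pseudo, nodesize = as.integer(nodesize),
                 max_depth = max_depth, seed = as.integer(seed),
                 unsupervised_mode = unsupervised_mode),
            class = "forest_params")
}

resolve_params <- function(params, p) {
  params$mtry <- as.integer(params$mtry %||% ceiling(sqrt(p)))
  params$q_pseudo <- as.integer(params$q_pseudo %||% min(p, ceiling(sqrt(p))))
  if (params$mtry < 1L || params$mtry > p) stop("mtry must be in 1..p")
  if (params$q_pseudo < 1L || params$q_pseudo > p) stop("q_pseudo must be in 1..p")
  params$max_depth_int <-
    if (is.infinite(params$max_depth)) -1L else as.integer(params$max_depth)
  params
}

#' Draw one bootstrap sample
#'
#' Cases are drawn uniformly with replacement; cases never drawn form the
#' out-of-bag (OOB) set, on average a fraction `(1 - 1/n)^n` (about 37%) of
#' the data.
#'
#' @param n number of cases.
#' @return list with `inbag` (case ids with repetition, length `n`),
#'   `inbag_count` (multiplicity per case) and `oob` (case ids never drawn).
#' @export
draw_bootstrap <- function(n) {
  if (n < 1L) stop("n must be >= 1")
  idx <- sample.int(n, n, replace = TRUE)
  cnt <- tabulate(idx, nbins = n)
  list(inbag = idx, inbag_count = cnt, oob = which(cnt == 0L))
}

#' Select pseudo-response variables
#'
#' Uniform sample without replacement of `q` of `p` variable indices; used as
#' the multivariate regression target of the unsupervised splitting rule.
#'
#' @param p number of variables.
#' @param q number of pseudo-responses.
#' @return integer vector of length `q`.
#' @export
select_pseudo_responses <- function(p, q) {
  if (q < 1L || q > p) stop("q must be in 1..p")
  sample.int(p, q)
}

#' Multivariate split statistic
#'
#' Sum over pseudo-response coordinates of within-daughter sums of squared
#' deviations from the daughter means,
#' \deqn{D_q(s,t) = \sum_{k=1}^{q} \Big[ \sum_{j \in t_L} (X_{jk} - \bar X_{t_L k})^2
#'   + \sum_{j \in t_R} (X_{jk} - \bar X_{t_R k})^2 \Big].}
#' The best split minimizes this statistic; it is zero iff every
#' pseudo-response is constant within each daughter. Missing pseudo-response
#' values are discarded coordinate-wise.
#'
#' @param node_values numeric matrix, in-node cases by pseudo-responses.
#' @param split_assignment logical or `"L"`/`"R"` vector; `TRUE`/`"L"` marks
#'   the left daughter.
#' @return non-negative scalar.
#' @export
split_statistic <- function(node_values, split_assignment) {
  node_values <- as.matrix(node_values)
  if (is.character(split_assignment)) split_assignment <- split_assignment == "L"
  split_assignment <- as.logical(split_assignment)
  if (length(split_assignment) != nrow(node_values))
    stop("split_assignment length must match rows of node_values")
  if (!any(split_assignment) || all(split_assignment))
    stop("both daughters must be non-empty")
  ss <- function(x) { x <- x[!is.na(x)]; if (length(x) == 0) 0 else sum((x - mean(x))^2) }
  sum(apply(node_values[split_assignment, , drop = FALSE], 2, ss)) +
    sum(apply(node_values[!split_assignment, , drop = FALSE], 2, ss))
}

#' Best split of a node
#'
#' Minimizes [split_statistic] over every candidate variable and every
#' midpoint between consecutive distinct observed (non-missing) values of
#' that variable among the given cases. Ties are broken by lowest variable
#' index, then lowest split value.
#'
#' @param data full case-by-variable matrix.
#' @param node_ids case ids (rows of `data`) in the node.
#' @param candidate_vars variable indices eligible for splitting.
#' @param response_set variable indices used as pseudo-responses.
#' @param response_data optional matrix supplying the pseudo-response columns
#'   (defaults to `data`).
#' @return `NULL` if no candidate variable has two distinct values, else a
#'   list with `var`, `value` and `stat`.
#' @export
best_split <- function(data, node_ids, candidate_vars, response_set,
                       response_data = data) {
  cpp_best_split(as.matrix(data), as.matrix(response_data),
                 as.integer(node_ids), as.integer(candidate_vars),
                 as.integer(response_set))
}

new_lr_tree <- function(raw, var_names, inbag_count) {
  structure(list(split_var = raw$split_var,
                 split_value = raw$split_value,
                 left = raw$left, right = raw$right, depth = raw$depth,
                 term_of_case = raw$term_of_case,
                 inbag_count = inbag_count,
                 n_fallback_inbag = raw$n_fallback_inbag %||% 0L,
                 n_fallback_colmean = raw$n_fallback_colmean %||% 0L,
                 var_names = var_names),
            class = "lr_tree")
}

#' @export
print.lr_tree <- function(x, ...) {
  cat(sprintf("recursive-partitioning tree: %d nodes (%d terminal), depth %d\n",
              length(x$split_var), sum(is.na(x$split_var)), max(x$depth)))
  invisible(x)
}

response_pool <- function(data, params) {
  if (params$unsupervised_mode == "synthetic_contrast") {
    apply(data, 2, function(col) col[sample.int(length(col), replace = TRUE)])
  } else {
    data
  }
}

#' Grow a single unsupervised tree
#'
#' Recursive partitioning with the multivariate pseudo-response splitting
#' rule: at every node a fresh set of `q_pseudo` pseudo-responses and `mtry`
#' candidate variables is drawn, and the split minimizing [split_statistic]
#' is taken. A case whose split-variable value is missing is routed by a
#' random draw from the in-bag non-missing in-node values of that variable
#' (missing values are discarded from the statistic itself). Out-of-bag cases
#' are dropped down the tree by the same rules, so every case lands in
#' exactly one terminal node.
#'
#' Uses the current RNG state: call `set.seed()` first for reproducibility.
#'
#' @inheritParams best_split
#' @param params [forest_params].
#' @param inbag_count per-case bootstrap multiplicity; drawn via
#'   [draw_bootstrap] when `NULL`.
#' @param response_data optional response pool (see
#'   `forest_params(unsupervised_mode=)`).
#' @return object of class `lr_tree`.
#' @export
grow_tree <- function(data, params = forest_params(), inbag_count = NULL,
                      response_data = NULL) {
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  if (n < 1L || p < 2L) stop("data must have >= 1 case and >= 2 variables")
  params <- resolve_params(params, p)
  if (is.null(inbag_count)) inbag_count <- draw_bootstrap(n)$inbag_count
  if (is.null(response_data)) response_data <- response_pool(data, params)
  dummy <- matrix(0, 1L, 1L)
  raw <- cpp_grow_tree(data, as.matrix(response_data),
                       as.integer(inbag_count),
                       params$mtry, params$q_pseudo, params$nodesize,
                       params$max_depth_int, FALSE, dummy, numeric(1L))
  new_lr_tree(raw, colnames(data), as.integer(inbag_count))
}

#' Grow an unsupervised forest
#'
#' `n_trees` independent trees from independent bootstrap samples; the seed
#' of tree `i` is derived deterministically from `params$seed`, so forests
#' are bit-identical given (data, params).
#'
#' @inheritParams grow_tree
#' @return object of class `lr_forest`.
#' @export
grow_forest <- function(data, params = forest_params()) {
  data <- as.matrix(data)
  p <- ncol(data)
  params <- resolve_params(params, p)
  response_data <- if (params$unsupervised_mode == "synthetic_contrast") {
    set.seed(derive_seed(params$seed, "contrast"))
    response_pool(data, params)
  } else data
  trees <- vector("list", params$n_trees)
  for (t in seq_len(params$n_trees)) {
    set.seed(derive_seed(params$seed, "tree", t))
    trees[[t]] <- grow_tree(data, params, response_data = response_data)
  }
  structure(list(trees = trees, params = params, n = nrow(data),
                 p = p, var_names = colnames(data)),
            class = "lr_forest")
}

#' @export
print.lr_forest <- function(x, ...) {
  cat(sprintf("unsupervised forest: %d trees, %d cases, %d variables\n",
              length(x$trees), x$n, x$p))
  invisible(x)
}

#' Terminal-node membership of a tree
#'
#' @param tree an `lr_tree`.
#' @return data.frame with one row per case: its terminal `node`, bootstrap
#'   multiplicity `inbag_count`, and whether it was `oob` for this tree.
#' @export
terminal_members <- function(tree) {
  data.frame(case = seq_along(tree$term_of_case),
             node = tree$term_of_case,
             inbag_count = tree$inbag_count,
             oob = tree$inbag_count == 0L)
}
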