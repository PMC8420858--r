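# Maximal-subtree minimal-depth statistics.
#
# A v-subtree is a subtree whose root splits on variable v; it is maximal if
# no ancestor of its root splits on v. The minimal depth D_v of v is the
# distance from the tree root to the root of the closest maximal v-subtree.
# Within a maximal v-subtree, the pairwise depth d of variable w is the
# distance from the subtree root to the root of the closest maximal w-subtree
# inside it, normalized by the subtree depth m (longest root-to-terminal path
# within the v-subtree), giving d/m in [0, 1]; small values mean v and w
# split close together, i.e. interact.

var_index <- function(tree, v) {
  if (is.character(v)) {
    i <- match(v, tree$var_names)
    if (is.na(i)) stop("unknown variable: ", v)
    i
  } else as.integer(v)
}

tree_children <- function(tree, node) c(tree$left[node], tree$right[node])

#' Find the maximal v-subtrees of a tree
#'
#' @param tree an `lr_tree` (or the fixture from [make_figure1b_tree]).
#' @param v variable index or name.
#' @return integer vector of subtree root node ids: every node splitting on
#'   `v` with no ancestor splitting on `v` (empty if `v` never splits).
#' @export
find_maximal_subtrees <- function(tree, v) {
  v <- var_index(tree, v)
  roots <- integer(0)
  recurse <- function(node) {
    sv <- tree$split_var[node]
    if (is.na(sv)) return(invisible(NULL))
    if (sv == v) {
      roots[[length(roots) + 1L]] <<- node
      return(invisible(NULL))  # deeper v-nodes belong to this subtree
    }
    recurse(tree$left[node])
    recurse(tree$right[node])
  }
  recurse(1L)
  roots
}

#' Minimal depth of a variable
#'
#' @inheritParams find_maximal_subtrees
#' @return distance from the tree root to the root of the closest maximal
#'   v-subtree (root = depth 0), or `NA` if `v` never splits.
#' @export
minimal_depth <- function(tree, v) {
  roots <- find_maximal_subtrees(tree, v)
  if (length(roots) == 0L) return(NA_integer_)
  min(tree$depth[roots])
}

# All node ids inside the subtree rooted at `root`.
subtree_nodes <- function(tree, root) {
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    out <- c(out, node)
    if (!is.na(tree$split_var[node]))
      stack <- c(stack, tree$left[node], tree$right[node])
  }
  out
}

#' Normalized pairwise minimal depths of w within the maximal v-subtrees
#'
#' For each maximal v-subtree: `d` is the within-subtree depth of the root of
#' the closest maximal w-subtree (subtree root = 0) and `m` the subtree depth
#' (longest root-to-terminal path, in edges). Subtrees containing no w split
#' emit nothing.
#'
#' @inheritParams find_maximal_subtrees
#' @param w second variable index or name.
#' @return numeric vector of `d/m` values, one per maximal v-subtree with a
#'   w split (possibly empty).
#' @export
pair_normalized_depths <- function(tree, v, w) {
  v <- var_index(tree, v); w <- var_index(tree, w)
  out <- numeric(0)
  for (root in find_maximal_subtrees(tree, v)) {
    nodes <- subtree_nodes(tree, root)
    rel <- tree$depth[nodes] - tree$depth[root]
    m <- max(rel[is.na(tree$split_var[nodes])])
    wnodes <- nodes[!is.na(tree$split_var[nodes]) &
                      tree$split_var[nodes] == w]
    if (length(wnodes) == 0L) next
    d <- min(tree$depth[wnodes]) - tree$depth[root]
    out <- c(out, d / m)
  }
  out
}

#' Forest-averaged pairwise minimal-depth matrix
#'
#' For every ordered pair (v, w) of the tracked variables, averages the
#' normalized pairwise depths over all (tree, maximal v-subtree)
#' observations in the forest; a direction with no observation scores the
#' no-co-occurrence penalty 1 (weakest possible interaction evidence). The
#' final index symmetrizes the two directional means, each taken over its own
#' observation count. All entries lie in [0, 1]; the diagonal is 1 by
#' convention; smaller values indicate stronger interaction.
#'
#' @param forest an `lr_forest`.
#' @param variables variable indices or names to track (default: all).
#' @param normalization `"dm"` for d/m (default) or `"cdf"` for the
#'   analytic-CDF normalization `P(D_vw <= d)` of [pair_depth_cdf] evaluated
#'   at the forest's variable count and each tree's depth.
#' @return object of class `pair_depth_matrix`: list with the symmetrized
#'   `values` matrix, per-direction `directional` means, and `counts` of
#'   contributing observations per cell.
#' @export
forest_pair_depth <- function(forest, variables = NULL,
                              normalization = c("dm", "cdf")) {
  normalization <- match.arg(normalization)
  stopifnot(inherits(forest, "lr_forest"), length(forest$trees) >= 1L)
  if (is.null(variables)) variables <- seq_len(forest$p)
  vidx <- vapply(variables, function(v) var_index(forest$trees[[1]], v), 1L)
  k <- length(vidx)
  sum_acc <- matrix(0, k, k)
  cnt_acc <- matrix(0L, k, k)
  for (tree in forest$trees) {
    tab <- NULL
    if (normalization == "cdf") {
      l <- max(tree$depth)
      tab <- pair_depth_cdf(forest$p, 0:l, l)
    }
    cpp_pair_depth(tree$split_var, tree$left, tree$right, tree$depth,
                   as.integer(vidx), forest$p, sum_acc, cnt_acc, tab)
  }
  directional <- ifelse(cnt_acc > 0L, sum_acc / pmax(cnt_acc, 1L), 1)
  values <- (directional + t(directional)) / 2
  diag(values) <- 1
  nm <- if (!is.null(forest$var_names)) forest$var_names[vidx] else
    as.character(vidx)
  dimnames(values) <- dimnames(directional) <- list(nm, nm)
  dimnames(cnt_acc) <- list(nm, nm)
  structure(list(values = values, directional = directional,
                 counts = cnt_acc + t(cnt_acc), normalization = normalization),
            class = "pair_depth_matrix")
}

#' @export
print.pair_depth_matrix <- function(x, ...) {
  cat(sprintf("pairwise minimal-depth matrix (%d variables, %s-normalized)\n",
              nrow(x$values), x$normalization))
  invisible(x)
}

#' Analytic minimal-depth distribution
#'
#' Probability that a weak (uninformative) variable v has minimal depth `s`
#' in a balanced tree where every node splits on one of `p` variables chosen
#' uniformly:
#' \deqn{P(D_v = s) = (1 - 1/p)^{2^s - 1} \big[1 - (1 - 1/p)^{2^s}\big],}
#' i.e. no node in levels `0..s-1` (which hold `2^s - 1` nodes) splits on v
#' while at least one of the `2^s` nodes at level `s` does.
#'
#' @param p number of variables (`p >= 1`).
#' @param s depth (vectorized, `s >= 0`).
#' @return probabilities.
#' @export
minimal_depth_pmf <- function(p, s) {
  stopifnot(p >= 1, all(s >= 0))
  if (p == 1) return(as.numeric(s == 0))
  a <- 1 - 1 / p
  out <- a^(2^s - 1) * (1 - a^(2^s))
  out[s == 0] <- 1 / p  # algebraically exact at the root
  out
}

#' Analytic CDF of the pairwise minimal depth
#'
#' Under the weak-variable independence assumption, the pairwise depth has
#' pmf
#' \deqn{P(D_{v,w} = d) = \sum_{m=d}^{l} P(D_v = l - m)\, P(D_w = l - m + d)}
#' for a tree of depth `l`; this returns the cumulative sum over depths up to
#' `d` (unnormalized total mass, as the weak-variable pmf need not sum to 1
#' at finite `l`). Used as the alternative normalization of the pairwise
#' index.
#'
#' @param p number of variables.
#' @param d pairwise depth (vectorized).
#' @param l tree depth.
#' @return cumulative probabilities, nondecreasing in `d`.
#' @export
pair_depth_cdf <- function(p, d, l) {
  stopifnot(all(d >= 0), all(d <= l), l >= 0)
  pmf_one <- function(dd) {
    m <- dd:l
    sum(minimal_depth_pmf(p, l - m) * minimal_depth_pmf(p, l - m + dd))
  }
  pmf <- vapply(0:l, pmf_one, 1.0)
  cumsum(pmf)[d + 1L]
}
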