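# Independent brute-force oracles and small fixture builders shared by the
# suites. These deliberately avoid the code paths they are used to check.

# Within-daughter sum of squares, computed directly from the definition.
oracle_split_stat <- function(Y, left) {
  Y <- as.matrix(Y)
  ss <- function(x) { x <- x[!is.na(x)]; if (!length(x)) 0 else sum((x - mean(x))^2) }
  sum(apply(Y[left, , drop = FALSE], 2, ss)) +
    sum(apply(Y[!left, , drop = FALSE], 2, ss))
}

# Exhaustive enumeration over all candidate variables and all midpoints
# between consecutive distinct non-missing values; near-ties keep the lowest
# variable index, then the lowest split value.
oracle_best_split <- function(x, cand, resp) {
  best <- NULL
  for (v in sort(cand)) {
    vals <- sort(unique(x[!is.na(x[, v]), v]))
    if (length(vals) < 2) next
    for (i in seq_len(length(vals) - 1)) {
      s <- (vals[i] + vals[i + 1]) / 2
      ok <- !is.na(x[, v])
      D <- oracle_split_stat(x[ok, resp, drop = FALSE], x[ok, v] <= s)
      tol <- if (is.null(best)) 0 else 1e-10 * (1 + abs(best$stat))
      if (is.null(best) || D < best$stat - tol)
        best <- list(var = v, value = s, stat = D)
    }
  }
  best
}

# Random binary tree in the package's node-table layout.
random_tree <- function(p_vars = 4, max_depth = 5, split_prob = 0.7) {
  sv <- integer(0); sval <- numeric(0)
  lft <- integer(0); rgt <- integer(0); dep <- integer(0)
  new_node <- function(d) {
    id <- length(sv) + 1L
    sv[id] <<- NA_integer_; sval[id] <<- NA_real_
    lft[id] <<- NA_integer_; rgt[id] <<- NA_integer_; dep[id] <<- d
    if (d < max_depth && stats::runif(1) < split_prob) {
      sv[id] <<- sample.int(p_vars, 1L)
      sval[id] <<- stats::rnorm(1)
      l <- new_node(d + 1L)
      r <- new_node(d + 1L)
      lft[id] <<- l; rgt[id] <<- r
    }
    id
  }
  new_node(0L)
  structure(list(split_var = sv, split_value = sval, left = lft, right = rgt,
                 depth = dep, term_of_case = integer(0),
                 inbag_count = integer(0),
                 var_names = paste0("V", seq_len(p_vars))),
            class = "lr_tree")
}

# Exhaustive node scan: every node splitting on v with no v-splitting
# ancestor, found via an explicit parent map.
oracle_max_subtrees <- function(tree, v) {
  n <- length(tree$split_var)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    if (!is.na(tree$left[i])) {
      parent[tree$left[i]] <- i
      parent[tree$right[i]] <- i
    }
  }
  out <- integer(0)
  for (i in seq_len(n)) {
    if (is.na(tree$split_var[i]) || tree$split_var[i] != v) next
    a <- parent[i]; shadowed <- FALSE
    while (!is.na(a)) {
      if (!is.na(tree$split_var[a]) && tree$split_var[a] == v) {
        shadowed <- TRUE
        break
      }
      a <- parent[a]
    }
    if (!shadowed) out <- c(out, i)
  }
  out
}

# Exhaustive traversal computing d/m per maximal v-subtree containing a w
# split (relative depths counted in edges from the subtree root).
oracle_pair_depths <- function(tree, v, w) {
  out <- numeric(0)
  for (root in oracle_max_subtrees(tree, v)) {
    queue <- list(list(node = root, rel = 0L))
    m <- 0L; dmin <- Inf
    while (length(queue)) {
      e <- queue[[1]]; queue <- queue[-1]
      svn <- tree$split_var[e$node]
      if (is.na(svn)) {
        m <- max(m, e$rel)
      } else {
        if (svn == w && e$node != root && e$rel < dmin) dmin <- e$rel
        queue <- c(queue,
                   list(list(node = tree$left[e$node], rel = e$rel + 1L)),
                   list(list(node = tree$right[e$node], rel = e$rel + 1L)))
      }
    }
    if (is.finite(dmin)) out <- c(out, dmin / m)
  }
  out
}

# Wrap loose trees into a forest object for forest-level statistics.
as_test_forest <- function(trees, p, var_names = paste0("V", seq_len(p))) {
  structure(list(trees = trees, params = NULL, n = 0L, p = p,
                 var_names = var_names),
            class = "lr_forest")
}

# Probability that a planted pair scores lower (stronger) than a null pair.
rank_auc <- function(idx, is_pos) {
  r <- rank(idx)
  n1 <- sum(is_pos); n0 <- sum(!is_pos)
  (sum(r[!is_pos]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

# Planted-pair recovery AUC of a full pipeline run on synthetic data.
recovery_auc <- function(effect, data_seed, run_seed, M = 5, n_trees = 200,
                         ...) {
  d <- generate_dataset(synth_config(effect = effect, seed = data_seed, ...))
  res <- lr_hunting(d$X_A, d$X_B, d$pairs,
                    lr_config(M = M, n_trees = n_trees, seed = run_seed))
  key <- paste(res$ligand, res$receptor)
  planted <- paste(d$truth$planted$ligand, d$truth$planted$receptor)
  rank_auc(res$imdi, key %in% planted)
}
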