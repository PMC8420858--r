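test_that("the worked fixture tree reproduces its depth statistics", {
  tree <- make_figure1b_tree()
  expect_length(find_maximal_subtrees(tree, "v"), 2L)
  expect_equal(minimal_depth(tree, "v"), 1L)
  expect_equal(pair_normalized_depths(tree, "v", "w"), 2 / 3)
  # the maximal h-subtree is the entire tree
  expect_equal(find_maximal_subtrees(tree, "h"), 1L)
  expect_equal(minimal_depth(tree, "h"), 0L)
  expect_equal(minimal_depth(tree, "u"), 2L)
  # no h split inside the maximal w-subtree
  expect_length(pair_normalized_depths(tree, "w", "h"), 0L)
  # a never-splitting variable has no subtrees and undefined minimal depth
  tiny <- structure(list(split_var = NA_integer_, split_value = NA_real_,
                         left = NA_integer_, right = NA_integer_, depth = 0L,
                         term_of_case = integer(0), inbag_count = integer(0),
                         var_names = c("a", "b")), class = "lr_tree")
  expect_length(find_maximal_subtrees(tiny, "a"), 0L)
  expect_true(is.na(minimal_depth(tiny, "a")))
})

test_that("subtree extraction matches the exhaustive node-scan oracle", {
  set.seed(123)
  for (i in 1:60) {
    tr <- random_tree(p_vars = 4, max_depth = 5, split_prob = 0.75)
    for (v in 1:4) {
      got <- sort(find_maximal_subtrees(tr, v))
      exp <- sort(oracle_max_subtrees(tr, v))
      expect_identical(got, exp)
      # disjointness and coverage: every v-splitting node lies in exactly
      # one maximal v-subtree
      vnodes <- which(!is.na(tr$split_var) & tr$split_var == v)
      covered <- as.integer(unlist(lapply(got, function(r) {
        nodes <- lrhunt:::subtree_nodes(tr, r)
        intersect(nodes, vnodes)
      })))
      expect_setequal(covered, vnodes)
      expect_equal(length(covered), length(vnodes))  # no overlap
      # minimal depth = depth of the closest maximal subtree root
      md <- minimal_depth(tr, v)
      if (length(exp)) expect_equal(md, min(tr$depth[exp]))
      else expect_true(is.na(md))
    }
  }
})

test_that("pairwise depths match the exhaustive traversal oracle", {
  set.seed(321)
  for (i in 1:40) {
    tr <- random_tree(p_vars = 4, max_depth = 5, split_prob = 0.8)
    for (v in 1:4) for (w in setdiff(1:4, v)) {
      expect_equal(sort(pair_normalized_depths(tr, v, w)),
                   sort(oracle_pair_depths(tr, v, w)))
    }
  }
})

test_that("forest-level aggregation matches per-tree statistics", {
  # single-tree forest over the fixture: directional (v,w) mean is 2/3
  tree <- make_figure1b_tree()
  fo <- as_test_forest(list(tree), p = 4, var_names = tree$var_names)
  pd <- forest_pair_depth(fo)
  expect_equal(pd$directional["v", "w"], 2 / 3)
  # w never co-occurs with u inside u-subtrees nor vice versa: penalty 1
  expect_equal(pd$directional["w", "u"], 1)
  expect_equal(pd$values["w", "h"], (3 / 4 + 1) / 2)  # one-sided evidence

  # random forests: C++ scan equals the R per-tree implementation
  set.seed(44)
  trees <- replicate(15, random_tree(p_vars = 5, max_depth = 5), simplify = FALSE)
  fo2 <- as_test_forest(trees, p = 5)
  pd2 <- forest_pair_depth(fo2)
  for (v in 1:5) for (w in setdiff(1:5, v)) {
    obs <- unlist(lapply(trees, pair_normalized_depths, v = v, w = w))
    expected <- if (length(obs)) mean(obs) else 1
    expect_equal(unname(pd2$directional[v, w]), expected)
  }
  # symmetry, diagonal, range
  expect_identical(pd2$values, t(pd2$values))
  expect_true(all(diag(pd2$values) == 1))
  expect_true(all(pd2$values >= 0 & pd2$values <= 1))
})

test_that("analytic minimal-depth pmf has its limiting properties", {
  for (p in c(2, 5, 10, 100)) expect_equal(minimal_depth_pmf(p, 0), 1 / p)
  expect_equal(minimal_depth_pmf(1, 0:3), c(1, 0, 0, 0))
  # partial sums stay below 1 and approach it
  for (p in c(3, 7)) {
    cum <- cumsum(minimal_depth_pmf(p, 0:30))
    expect_true(all(diff(cum) >= 0))
    expect_true(all(cum <= 1 + 1e-12))
    expect_gt(cum[31], 1 - 1e-6)
  }
})

test_that("minimal-depth pmf matches balanced random-tree simulation", {
  # complete binary trees of depth 8, uniform split variable at every node:
  # the count of v-nodes at level s is Binomial(2^s, 1/p); the minimal depth
  # is the first level with a positive count.
  p <- 5; L <- 8; n_sim <- 5000
  set.seed(2024)
  first_hit <- function() {
    for (s in 0:L) if (stats::rbinom(1, 2^s, 1 / p) > 0) return(s)
    Inf
  }
  sims <- replicate(n_sim, first_hit())
  for (s in 0:2) {
    phat <- mean(sims == s)
    p0 <- minimal_depth_pmf(p, s)
    se <- sqrt(p0 * (1 - p0) / n_sim)
    expect_lt(abs(phat - p0), 3 * se)
  }
})

test_that("pairwise-depth CDF is a valid cumulative of the convolution", {
  p <- 6; l <- 5
  cdf <- pair_depth_cdf(p, 0:l, l)
  expect_true(all(diff(cdf) >= 0))
  # independent re-implementation of the printed convolution
  direct_pmf <- function(d) {
    tot <- 0
    for (m in d:l)
      tot <- tot + minimal_depth_pmf(p, l - m) * minimal_depth_pmf(p, l - m + d)
    tot
  }
  expect_equal(unname(cdf[l + 1]), sum(vapply(0:l, direct_pmf, 1.0)))
  expect_equal(unname(cdf[1]), direct_pmf(0))
  expect_equal(unname(cdf[3]), sum(vapply(0:2, direct_pmf, 1.0)))
})

test_that("cdf normalization mode produces values in [0, 1]", {
  set.seed(10)
  x <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("g", 1:5)))
  f <- grow_forest(x, forest_params(n_trees = 20, seed = 2))
  pd <- forest_pair_depth(f, normalization = "cdf")
  expect_true(all(pd$values >= 0 & pd$values <= 1))
  expect_identical(pd$values, t(pd$values))
})
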