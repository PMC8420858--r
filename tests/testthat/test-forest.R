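test_that("bootstrap draws follow the out-of-bag law", {
  expect_error(draw_bootstrap(0), ">= 1")
  set.seed(1)
  # a single case is always drawn
  expect_equal(draw_bootstrap(1)$oob, integer(0))

  # E[|oob|/n] = (1 - 1/n)^n; Monte-Carlo check at n = 10
  set.seed(42)
  fr <- replicate(1e4, length(draw_bootstrap(10)$oob) / 10)
  expected <- (1 - 1 / 10)^10
  expect_lt(abs(mean(fr) - expected), 3 * sd(fr) / sqrt(length(fr)))

  # structural contract: inbag multiset size n, oob = never-drawn cases
  bs <- draw_bootstrap(25)
  expect_length(bs$inbag, 25)
  expect_setequal(c(unique(bs$inbag), bs$oob), 1:25)
})

test_that("pseudo-response selection is uniform without replacement", {
  expect_error(select_pseudo_responses(5, 6), "1..p")
  set.seed(3)
  expect_setequal(select_pseudo_responses(5, 5), 1:5)
  set.seed(7)
  a <- select_pseudo_responses(5, 1)
  set.seed(7)
  expect_identical(select_pseudo_responses(5, 1), a)

  set.seed(11)
  draws <- replicate(1e4, select_pseudo_responses(100, 10))
  freq <- tabulate(draws, 100) / 1e4
  expect_true(all(abs(freq - 0.1) < 0.01))
})

test_that("split statistic matches the definition", {
  # hand value: q=1, values (1,2,3,4), split {1,2} | {3,4} -> 0.5 + 0.5
  expect_equal(split_statistic(matrix(1:4, 4, 1), c(TRUE, TRUE, FALSE, FALSE)),
               1.0)
  # piecewise-constant split is perfect
  expect_equal(split_statistic(matrix(c(0, 0, 10, 10), 4, 1),
                               c(TRUE, TRUE, FALSE, FALSE)), 0)
  # constant pseudo-response column contributes nothing
  expect_equal(split_statistic(cbind(rep(5, 6), 1:6), rep(c(TRUE, FALSE), 3)),
               split_statistic(matrix(1:6, 6, 1), rep(c(TRUE, FALSE), 3)))
  expect_error(split_statistic(matrix(1:4, 4, 1), rep(TRUE, 4)), "non-empty")
  # agrees with the independent implementation on random inputs
  set.seed(5)
  for (i in 1:20) {
    y <- matrix(rnorm(8 * 3), 8, 3)
    left <- sample(c(TRUE, FALSE), 8, replace = TRUE)
    if (all(left) || !any(left)) left[1] <- !left[1]
    expect_equal(split_statistic(y, left), oracle_split_stat(y, left))
  }
})

test_that("best_split agrees with exhaustive search", {
  # worked example: predictor separating two response clusters exactly
  x <- cbind(x = c(1, 2, 3, 4), y = c(0, 0, 10, 10))
  got <- best_split(x, 1:4, candidate_vars = 1, response_set = 2)
  expect_equal(got$var, 1)
  expect_equal(got$value, 2.5)
  expect_equal(got$stat, 0)

  # all-constant candidates: no split
  xc <- cbind(rep(1, 5), rnorm(5))
  expect_null(best_split(xc, 1:5, candidate_vars = 1, response_set = 2))

  # tie rule: duplicated columns give exactly equal statistics; lower index wins
  xd <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 3, 4), y = c(0, 0, 1, 1))
  tie <- best_split(xd, 1:4, candidate_vars = c(2, 1), response_set = 3)
  expect_equal(tie$var, 1)

  set.seed(99)
  for (i in 1:60) {
    n <- sample(5:30, 1); p <- sample(2:6, 1)
    x <- matrix(rnorm(n * p), n, p)
    if (runif(1) < 0.4) x[sample(length(x), n)] <- NA
    cand <- sample(p, sample(seq_len(p), 1))
    resp <- sample(p, sample(seq_len(p), 1))
    got <- best_split(x, 1:n, cand, resp)
    exp <- oracle_best_split(x, cand, resp)
    expect_equal(is.null(got), is.null(exp))
    if (!is.null(got)) {
      expect_equal(got$var, exp$var)
      expect_equal(got$value, exp$value)
      expect_equal(got$stat, exp$stat, tolerance = 1e-7)
    }
  }
})

test_that("grow_tree respects stopping rules and structural invariants", {
  set.seed(8)
  x <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("g", 1:4)))

  # nodesize >= n: single terminal root of depth 0
  t1 <- grow_tree(x, forest_params(nodesize = 30, seed = 1))
  expect_length(t1$split_var, 1L)
  expect_true(is.na(t1$split_var[1]))
  expect_equal(t1$depth, 0L)

  # one binary variable perfectly partitioning two response clusters:
  # a depth-1 tree splitting on that variable
  cluster <- rep(c(0, 1), each = 15)
  xx <- cbind(flag = cluster, r1 = cluster * 10 + rnorm(30, sd = .01),
              r2 = -cluster * 10 + rnorm(30, sd = .01))
  set.seed(2)
  t2 <- grow_tree(xx, forest_params(mtry = 3, q_pseudo = 3, nodesize = 15,
                                    seed = 2))
  expect_equal(t2$split_var[1], 1L)
  expect_equal(max(t2$depth), 1L)
  expect_equal(t2$split_value[1], 0.5)

  # determinism
  set.seed(77); ta <- grow_tree(x, forest_params(seed = 5))
  set.seed(77); tb <- grow_tree(x, forest_params(seed = 5))
  expect_identical(ta, tb)

  # invariants: terminal <=> no split <=> no children; child depth = parent + 1;
  # every case lands in exactly one terminal
  set.seed(12)
  tr <- grow_tree(x, forest_params(nodesize = 3, seed = 9))
  term <- is.na(tr$split_var)
  expect_identical(term, is.na(tr$left))
  expect_identical(term, is.na(tr$right))
  internal <- which(!term)
  expect_true(all(tr$depth[tr$left[internal]] == tr$depth[internal] + 1L))
  expect_true(all(tr$depth[tr$right[internal]] == tr$depth[internal] + 1L))
  expect_true(all(tr$term_of_case %in% which(term)))
  expect_length(tr$term_of_case, nrow(x))
  members <- terminal_members(tr)
  expect_equal(sum(members$inbag_count), nrow(x))
})

test_that("forests are deterministic and reproduce grow_tree per tree", {
  set.seed(4)
  x <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("g", 1:5)))
  f1 <- grow_forest(x, forest_params(n_trees = 10, seed = 21))
  f2 <- grow_forest(x, forest_params(n_trees = 10, seed = 21))
  expect_identical(f1$trees, f2$trees)

  set.seed(lrhunt:::derive_seed(21L, "tree", 1L))
  t1 <- grow_tree(x, forest_params(n_trees = 10, seed = 21))
  expect_identical(f1$trees[[1]], t1)
})

test_that("per-tree OOB fraction matches its closed-form expectation", {
  set.seed(6)
  x <- matrix(rnorm(200 * 4), 200, 4, dimnames = list(NULL, paste0("g", 1:4)))
  f <- grow_forest(x, forest_params(n_trees = 100, nodesize = 50, seed = 31))
  fr <- vapply(f$trees, function(t) mean(t$inbag_count == 0L), 1.0)
  expected <- (1 - 1 / 200)^200
  expect_lt(abs(mean(fr) - expected), 3 * sd(fr) / sqrt(length(fr)))
})

test_that("synthetic-contrast mode grows valid deterministic forests", {
  set.seed(13)
  x <- matrix(rnorm(50 * 4), 50, 4, dimnames = list(NULL, paste0("g", 1:4)))
  p <- forest_params(n_trees = 5, seed = 3,
                     unsupervised_mode = "synthetic_contrast")
  f1 <- grow_forest(x, p)
  f2 <- grow_forest(x, p)
  expect_identical(f1$trees, f2$trees)
  expect_true(all(vapply(f1$trees, function(t) max(t$depth), 1L) >= 1L))
})
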