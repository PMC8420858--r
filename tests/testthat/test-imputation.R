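make_small_ism <- function(n_A = 3, n_B = 2, seed = 1) {
  set.seed(seed)
  X_A <- expression_matrix(
    matrix(rnorm(n_A * 3), n_A, 3,
           dimnames = list(sprintf("a%d", 1:n_A), c("L1", "L2", "X1"))),
    cell_type = "A")
  X_B <- expression_matrix(
    matrix(rnorm(n_B * 3), n_B, 3,
           dimnames = list(sprintf("b%d", 1:n_B), c("R1", "R2", "Y1"))),
    cell_type = "B")
  pairs <- lr_pair_table(c("L1", "L2"), c("R1", "R2"))
  list(X_A = X_A, X_B = X_B, pairs = pairs,
       ism = assemble_interaction_space(X_A, X_B, pairs))
}

test_that("interaction space has exactly the two missing off-blocks", {
  s <- make_small_ism()
  ism <- s$ism
  expect_equal(dim(ism$values), c(5L, 4L))
  expect_equal(sum(ism$missing_mask), 3 * 2 + 2 * 2)
  # mask is exactly rows-A x receptor cols and rows-B x ligand cols
  expect_true(all(ism$missing_mask[1:3, 3:4]))
  expect_true(all(ism$missing_mask[4:5, 1:2]))
  expect_true(!any(ism$missing_mask[1:3, 1:2]))
  expect_true(!any(ism$missing_mask[4:5, 3:4]))
  # observed entries equal the sources
  expect_equal(ism$values[1:3, 1:2], unclass(s$X_A)[, c("L1", "L2")],
               ignore_attr = TRUE)
  expect_equal(ism$values[4:5, 3:4], unclass(s$X_B)[, c("R1", "R2")],
               ignore_attr = TRUE)
})

test_that("assembly errors on absent genes and suffixes role clashes", {
  s <- make_small_ism()
  badpairs <- lr_pair_table("NOPE", "R1")
  expect_error(assemble_interaction_space(s$X_A, s$X_B, badpairs),
               "absent from sender")
  # same gene name on both sides gets role-suffixed columns, never merged
  XA <- expression_matrix(matrix(rnorm(6), 3, 2,
                                 dimnames = list(paste0("a", 1:3),
                                                 c("SHARED", "L1"))), "A")
  XB <- expression_matrix(matrix(rnorm(4), 2, 2,
                                 dimnames = list(paste0("b", 1:2),
                                                 c("SHARED", "R1"))), "B")
  pr <- lr_pair_table(c("SHARED", "L1"), c("R1", "SHARED"))
  ism <- assemble_interaction_space(XA, XB, pr)
  expect_setequal(colnames(ism$values), c("SHARED.L", "L1", "SHARED.R", "R1"))
  expect_equal(unname(ism$ligand_col["SHARED"]), "SHARED.L")
  expect_equal(unname(ism$receptor_col["SHARED"]), "SHARED.R")
})

test_that("imputation is the identity on complete data", {
  set.seed(9)
  x <- matrix(rnorm(30 * 5), 30, 5,
              dimnames = list(paste0("c", 1:30), paste0("g", 1:5)))
  ism <- list(values = x, missing_mask = matrix(FALSE, 30, 5))
  out <- rf_impute(ism, forest_params(n_trees = 10, seed = 2))
  expect_identical(out$values, x)
})

test_that("imputation preserves observed values and stays in observed range", {
  set.seed(21)
  cm <- matrix(rnorm(60 * 8), 60, 8,
               dimnames = list(sprintf("r%02d", 1:60), paste0("g", 1:8)))
  ism <- generate_block_missing(cm, n_A = 30, p_A = 4)
  out <- rf_impute(ism, forest_params(n_trees = 30, seed = 5))
  expect_true(!any(is.na(out$values)))
  expect_identical(out$values[!ism$missing_mask], ism$values[!ism$missing_mask])
  for (g in seq_len(ncol(cm))) {
    obs <- ism$values[!ism$missing_mask[, g], g]
    imp <- out$values[ism$missing_mask[, g], g]
    expect_true(all(imp >= min(obs) - 1e-12 & imp <= max(obs) + 1e-12))
  }
  # conservation: the multiset of observed values is untouched
  expect_identical(sort(out$values[!ism$missing_mask]),
                   sort(ism$values[!ism$missing_mask]))
})

test_that("imputation preconditions reject empty rows/columns", {
  vals <- matrix(c(1, NA, NA, NA), 2, 2,
                 dimnames = list(c("r1", "r2"), c("c1", "c2")))
  ism <- list(values = vals, missing_mask = is.na(vals))
  expect_error(rf_impute(ism), "zero observed")
})

test_that("multiple imputation is seeded, independent, and mask-confined", {
  set.seed(31)
  cm <- matrix(rnorm(40 * 6), 40, 6,
               dimnames = list(sprintf("r%02d", 1:40), paste0("g", 1:6)))
  ism <- generate_block_missing(cm, n_A = 20, p_A = 3)
  imps <- multiple_impute(ism, M = 3, forest_params(n_trees = 15), base_seed = 7)
  expect_length(imps, 3L)
  imps2 <- multiple_impute(ism, M = 3, forest_params(n_trees = 15), base_seed = 7)
  expect_identical(lapply(imps, `[[`, "values"), lapply(imps2, `[[`, "values"))
  # single imputation
  one <- multiple_impute(ism, M = 1, forest_params(n_trees = 15), base_seed = 7)
  expect_identical(one[[1]]$values, imps[[1]]$values)
  # datasets differ only at masked entries
  expect_false(identical(imps[[1]]$values, imps[[2]]$values))
  expect_identical(imps[[1]]$values[!ism$missing_mask],
                   imps[[2]]$values[!ism$missing_mask])
})

test_that("block masking helper masks exactly the off-blocks and keeps truth", {
  set.seed(2)
  cm <- matrix(rnorm(20), 5, 4,
               dimnames = list(paste0("r", 1:5), paste0("g", 1:4)))
  ism <- generate_block_missing(cm, n_A = 3, p_A = 2)
  expect_equal(sum(ism$missing_mask), 3 * 2 + 2 * 2)
  restored <- ism$values
  restored[ism$missing_mask] <- ism$truth[ism$missing_mask]
  expect_identical(restored, cm)
})
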