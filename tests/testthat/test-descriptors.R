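test_that("descriptor computation is deterministic with a shared column set", {
  X <- compute_descriptors(c(eth = "CCO", benz = "c1ccccc1", eth2 = "CCO"))
  expect_equal(nrow(X), 3L)
  expect_equal(unname(X["eth", ]), unname(X["eth2", ]))
  expect_false(identical(unname(X["eth", ]), unname(X["benz", ])))
  expect_match(attr(X, "provenance"), "OpenBabel")
})

test_that("simulator library descriptors are finite or flagged", {
  sim <- fix_sim()
  X <- compute_descriptors(sim$lib$compounds[1:20, ])
  expect_equal(attr(X, "failed"), character(0))
  expect_true(all(is.finite(X) | is.na(X)))
})

test_that("preprocessing drops constant columns, imputes and Z-scores", {
  set.seed(1)
  X <- cbind(a = rnorm(20), b = rnorm(20, 5, 2), const = rep(3, 20))
  X[3, "a"] <- NA
  Z <- preprocess_descriptors(X)
  expect_false("const" %in% colnames(Z))
  expect_true("const" %in% attr(Z, "dropped"))
  expect_false(anyNA(Z))
  expect_equal(unname(colMeans(Z)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("preprocessing is idempotent and its stats reproduce the output", {
  set.seed(2)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("a", "b", "c")))
  Z <- preprocess_descriptors(X)
  Z2 <- preprocess_descriptors(Z)
  expect_equal(unclass(Z2)[, ], unclass(Z)[, ], tolerance = 1e-12)
  # stored stats applied to the raw matrix give the normalized one back
  expect_equal(apply_normalization(X, attr(Z, "center"), attr(Z, "scale")),
               unclass(Z)[, ], tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("KNN imputation recovers masked values", {
  # k = 1 with an identical twin row: imputed value equals the twin's
  X <- rbind(c(1, 2, 3), c(1, 2, 3), c(9, 8, 7))
  X[1, 2] <- NA
  expect_equal(knn_impute(X, k = 1)[1, 2], 2)
  # mask-and-recover on correlated data: RMSE well below the column sd
  set.seed(3)
  n <- 60
  base <- rnorm(n)
  M <- cbind(x1 = base + rnorm(n, 0, 0.1), x2 = 2 * base + rnorm(n, 0, 0.1),
             x3 = -base + rnorm(n, 0, 0.1))
  Mm <- M
  holes <- cbind(sample(n, 10), sample(3, 10, replace = TRUE))
  Mm[holes] <- NA
  imp <- knn_impute(Mm, k = 5)
  rmse <- sqrt(mean((imp[holes] - M[holes])^2))
  expect_lt(rmse, min(apply(M, 2, sd)))
})

test_that("RFECV tallies behave at degenerate settings", {
  set.seed(4)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6,
              dimnames = list(NULL, c("x1", "x2", paste0("n", 1:4))))
  y <- 4 * X[, 1] - 3 * X[, 2] + rnorm(n, 0, 0.2) + 20
  sel <- rfecv_select(X, y, fractions = 0.8, reps_per_fraction = 5, folds = 5,
                      threshold = 4, seed = 9)
  # threshold = total - 1: only always-selected descriptors survive
  expect_true(all(c("x1", "x2") %in% sel$selected))
  expect_true(all(sel$frequencies[sel$selected] == 5))
  expect_true(all(sel$frequencies <= 5))
  expect_error(rfecv_select(X, y, fractions = 0.8, reps_per_fraction = 5,
                            threshold = 5, seed = 1),
               "below the total repeat count")
  # same seed, same selection
  sel2 <- rfecv_select(X, y, fractions = 0.8, reps_per_fraction = 5,
                       folds = 5, threshold = 4, seed = 9)
  expect_identical(sel$frequencies, sel2$frequencies)
})

test_that("selection results round-trip through JSON", {
  sel <- structure(list(selected = c("a", "b"),
                        frequencies = c(a = 10, b = 9, c = 1),
                        config = list(fractions = 0.8, reps_per_fraction = 10,
                                      folds = 5, threshold = 7, total = 10,
                                      seed = 1)),
                   class = "selection_result")
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  back <- read_selection(path)
  expect_equal(back$selected, sel$selected)
  expect_equal(back$frequencies, sel$frequencies)
  expect_equal(back$config$threshold, 7)
})
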