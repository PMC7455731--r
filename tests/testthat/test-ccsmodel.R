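test_that("the default hyperparameter grid crosses 7 costs with 15 widths", {
  cfg <- model_config(N_MD = 15)
  expect_length(cfg$C_grid, 7L)
  expect_length(cfg$gamma_grid, 15L)
  expect_equal(length(cfg$C_grid) * length(cfg$gamma_grid), 105L)
  expect_equal(cfg$C_grid, c(0.001, 0.005, 0.025, 0.05, 0.1, 0.25, 0.5) / 15)
  expect_equal(cfg$gamma_grid, 2^(1:15))
  expect_equal(cfg$folds, 10)
  expect_equal(cfg$repeats, 100)
})

test_that("grid tuning finds a planted optimum and is reproducible", {
  set.seed(8)
  n <- 80
  X <- cbind(x = seq(-2, 2, length.out = n), z = rnorm(n, 0, 0.01))
  y <- 100 + 30 * sin(X[, "x"]) + rnorm(n, 0, 0.5)
  cfg <- model_config(N_MD = 2, C_grid = c(1e-6, 10),
                      gamma_grid = c(0.5, 4096), folds = 5, repeats = 2)
  t1 <- tune_hyperparameters(X, y, cfg, seed = 11)
  expect_equal(t1$C, 10)          # vanishing C underfits to the median
  expect_equal(t1$gamma, 0.5)     # enormous gamma memorizes nothing
  expect_equal(nrow(t1$cv_table), 4L)
  t2 <- tune_hyperparameters(X, y, cfg, seed = 11)
  expect_identical(t1$cv_table, t2$cv_table)
  expect_error(tune_hyperparameters(X[1:3, ], y[1:3], cfg), "folds")
})

test_that("training is deterministic and echoes its hyperparameters", {
  sim <- fix_sim()
  inst <- simulate_training_instances(sim$lib, sim$cfg, polarity = "+")
  m1 <- train_ccs_model(inst, sim$lib$compounds, "+", C = 10, gamma = 2^-5)
  m2 <- train_ccs_model(inst, sim$lib$compounds, "+", C = 10, gamma = 2^-5)
  expect_equal(m1$C, 10)
  expect_equal(m1$gamma, 2^-5)
  expect_true(is.finite(m1$epsilon))
  q <- sim$lib$compounds[1:10, ]
  expect_equal(predict_ccs(m1, q, "[M+H]+")$ccs,
               predict_ccs(m2, q, "[M+H]+")$ccs)
  # wrong-polarity inputs are rejected
  expect_error(train_ccs_model(data.frame(compound_id = "SIM001",
                                          adduct = "[M-H]-", ccs = 150),
                               sim$lib$compounds, "+"), "polarity")
  expect_error(predict_ccs(m1, q, "[M-H]-"), "polarity")
})

test_that("training compounds are predicted close to their training values", {
  sim <- fix_sim()
  inst <- simulate_training_instances(sim$lib, sim$cfg, polarity = "+")
  m <- train_ccs_model(inst, sim$lib$compounds, "+", C = 10, gamma = 2^-5)
  pred <- predict_ccs(m, sim$lib$compounds[match(inst$compound_id,
                                                 sim$lib$compounds$id), ],
                      inst$adduct)
  re <- abs(pred$ccs - inst$ccs) / inst$ccs * 100
  expect_lt(median(re), max(3 * m$metrics$MRE, 3))
  expect_true(all(pred$level == "4"))
  expect_true(all(pred$ccs > 0))
  expect_true(all(pred$rss >= 0 & pred$rss <= 1))
  # compounds identical to training structures carry maximal RSS
  expect_equal(max(pred$rss), 1)
})

test_that("evaluation metrics follow their definitions", {
  ev0 <- evaluate_predictions(c(100, 200), c(100, 200))
  expect_equal(ev0$MRE, 0); expect_equal(ev0$ARE, 0); expect_equal(ev0$R2, 1)
  # RE 1% and 3% -> MRE = ARE = 2
  ev <- evaluate_predictions(c(101, 206), c(100, 200))
  expect_equal(ev$MRE, 2); expect_equal(ev$ARE, 2)
  expect_error(evaluate_predictions(numeric(), numeric()), "non-empty")
})

test_that("the cumulative error curve is a valid CDF", {
  set.seed(9)
  truth <- runif(200, 100, 300)
  pred <- truth * (1 + rnorm(200, 0, 0.03))
  ev <- evaluate_predictions(pred, truth)
  frac <- ev$cumulative$fraction
  expect_true(all(diff(frac) >= 0))
  expect_equal(frac[length(frac)], 1)
  expect_true(all(frac >= 0 & frac <= 1))
  expect_equal(ev$cumulative$threshold[2] - ev$cumulative$threshold[1], 0.5)
})

test_that("normalization aligns query columns by name, not position", {
  set.seed(10)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  Z <- preprocess_descriptors(X)
  perm <- X[, c("d", "b", "a", "c")]
  expect_equal(apply_normalization(perm, attr(Z, "center"), attr(Z, "scale")),
               unclass(Z)[, ], tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(apply_normalization(X[, 1:2], attr(Z, "center"),
                                   attr(Z, "scale")), "lacks descriptors")
})
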