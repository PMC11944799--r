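test_that("the default path specification is a DAG with salt exogenous", {
  spec <- path_model_spec()
  expect_equal(spec$exogenous, "salt")
  expect_equal(nrow(spec$edges), 9)
  expect_equal(nrow(path_model_spec(include_salt_mnc = FALSE)$edges), 8)
  expect_error(path_model_spec(data.frame(from = c("a", "b"),
                                          to = c("b", "a"))), "cyclic")
})

test_that("a saturated recursive model fits perfectly", {
  set.seed(8)
  n <- 60
  d <- data.frame(x = rnorm(n))
  d$y <- 0.5 * d$x + rnorm(n)
  d$z <- 0.3 * d$x - 0.4 * d$y + rnorm(n)
  spec <- path_model_spec(data.frame(from = c("x", "x", "y"),
                                     to = c("y", "z", "z")))
  fit <- fit_path_model(d, spec)
  expect_equal(fit$df, 0)
  expect_lt(fit$chi_square, 1e-8)
  expect_equal(fit$rmsea, 0)
})

test_that("exact dependence gives a unit standardized coefficient", {
  d <- data.frame(x = 1:30, y = 1:30)
  fit <- fit_path_model(d, path_model_spec(data.frame(from = "x",
                                                      to = "y")))
  expect_equal(fit$paths$coefficient, 1, tolerance = 1e-12)
  expect_lt(fit$paths$p_value, 1e-12)
})

test_that("a single-predictor path coefficient equals Pearson r", {
  set.seed(12)
  d <- data.frame(x = rnorm(25))
  d$y <- 0.7 * d$x + rnorm(25)
  fit <- fit_path_model(d, path_model_spec(data.frame(from = "x",
                                                      to = "y")))
  expect_equal(fit$paths$coefficient, cor(d$x, d$y), tolerance = 1e-10)
})

test_that("fit statistics are invariant to affine unit changes", {
  set.seed(13)
  n <- 80
  d <- data.frame(salt = rnorm(n))
  d$rare_bacterial <- 0.4 * d$salt + rnorm(n)
  d$abundant_bacterial <- rnorm(n)
  d$rare_fungal <- rnorm(n)
  d$abundant_fungal <- rnorm(n)
  d$mnc <- -0.3 * d$rare_bacterial + 0.5 * d$rare_fungal + rnorm(n)
  f1 <- fit_path_model(d)
  d2 <- transform(d, salt = salt * 100 + 3, mnc = mnc / 7 - 2)
  f2 <- fit_path_model(d2)
  expect_equal(f2$chi_square, f1$chi_square, tolerance = 1e-8)
  expect_equal(f2$paths$coefficient, f1$paths$coefficient,
               tolerance = 1e-8)
  expect_equal(f2$rmsea, f1$rmsea, tolerance = 1e-8)
})

test_that("degenerate designs are rejected", {
  d <- data.frame(x = 1:20, y = rnorm(20), z = rep(1, 20))
  expect_error(
    fit_path_model(d, path_model_spec(data.frame(from = "x", to = "z"))),
    "constant")
  d$w <- d$x
  expect_error(
    fit_path_model(d, path_model_spec(data.frame(from = c("x", "w"),
                                                 to = c("y", "y")))),
    "singular")
})

test_that("random-forest importance finds a planted signal", {
  set.seed(21)
  n <- 120
  pred <- as.data.frame(matrix(rnorm(n * 7), n,
                               dimnames = list(NULL, mnc_vars())))
  resp <- 2 * pred$SOC + rnorm(n, 0, 0.5)
  imp <- rf_importance(pred, resp, seed = 1)
  expect_equal(imp$importance$predictor[1], "SOC")
  expect_gt(imp$r_squared, 0.5)
  expect_identical(rf_importance(pred, resp, seed = 1)$importance,
                   imp$importance)
})

test_that("null responses yield near-zero importances", {
  set.seed(22)
  pred <- as.data.frame(matrix(rnorm(60 * 4), 60,
                               dimnames = list(NULL, letters[1:4])))
  resp <- rnorm(60)
  imp <- rf_importance(pred, resp, seed = 2)
  expect_lt(mean(imp$importance$inc_mse_pct), 15)
  expect_warning(rf_importance(pred, rep(1, 60)), "constant")
})

test_that("duplicated predictors share importance", {
  set.seed(23)
  n <- 100
  pred <- data.frame(a = rnorm(n))
  pred$b <- pred$a
  pred$c <- rnorm(n); pred$d <- rnorm(n)
  resp <- 3 * pred$a + rnorm(n, 0, 0.5)
  imp <- rf_importance(pred, resp, seed = 3)$importance
  ia <- imp$inc_mse_pct[imp$predictor == "a"]
  ib <- imp$inc_mse_pct[imp$predictor == "b"]
  expect_lt(max(ia, ib) / (ia + ib), 0.9)
})

test_that("the driver table joins sources consistently", {
  cfg <- synth_config(seed = 5)
  ds <- generate_coupled_dataset(cfg)
  tab <- assemble_driver_table(ds$bacteria, ds$fungi, ds$nutrients)
  expect_equal(nrow(tab), 41)
  expect_equal(ncol(tab), 13)  # salt, 4 Shannon, mnc, 7 nutrients
  expect_equal(tab$salt, ds$nutrients$salt[
    match(rownames(tab), ds$nutrients$sample_id)])
  expect_equal(mean(tab$SOC), mean(ds$nutrients$SOC))
  mnc <- compute_mnc(ds$nutrients)
  expect_equal(tab$mnc, unname(mnc$mnc[rownames(tab)]))
  cls <- classify_taxa(ds$bacteria)
  ad <- alpha_diversity(subset_by_class(ds$bacteria, cls, "rare"))
  expect_equal(tab$rare_bacterial,
               ad$shannon[match(rownames(tab), ad$sample_id)])
  # disjoint sample ids fail
  fung2 <- ds$fungi
  rownames(fung2$counts) <- paste0("zz_", rownames(fung2$counts))
  names(fung2$crop) <- rownames(fung2$counts)
  expect_error(assemble_driver_table(ds$bacteria, fung2, ds$nutrients),
               "shared samples")
})
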