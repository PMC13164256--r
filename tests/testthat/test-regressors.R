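test_that("OLS fitter solves the normal equations on toy data", {
  fm <- make_feature_matrix(matrix(c(0, 1, 2), ncol = 1,
                                   dimnames = list(NULL, "voltage_V")),
                            c(1, 1, 4))
  m <- fit_mlr(fm)
  expect_equal(unname(m$coefficients), c(0.5, 1.5), tolerance = 1e-10)

  fm2 <- make_feature_matrix(matrix(c(0, 1, 2, 3), ncol = 1,
                                    dimnames = list(NULL, "voltage_V")),
                             2 * c(0, 1, 2, 3) + 1)
  m2 <- fit_mlr(fm2)
  expect_equal(unname(m2$coefficients), c(1, 2), tolerance = 1e-10)
  expect_equal(unname(predict(m2, fm2)), c(1, 3, 5, 7), tolerance = 1e-10)
  # collinear design errors
  X <- cbind(voltage_V = c(0, 1, 2, 3), dup = c(0, 2, 4, 6))
  expect_error(fit_mlr(make_feature_matrix(X, 1:4)), "collinear")
})

test_that("OLS on noise-free generated data recovers generator slopes", {
  cfg <- generator_config(n_records = 80, noise_sd = 0,
                          b0 = c(H2SO4 = 10, H2C2O4 = 20, H3PO4 = 30),
                          b_V = c(H2SO4 = 1.2, H2C2O4 = 1.2, H3PO4 = 1.2),
                          b_T = -0.4, b_t = 0.005, seed = 12)
  rec <- generate_dataset(cfg)$records
  sl <- suppressWarnings(mlr_slopes(fit_mlr(encode_features(rec))))
  expect_equal(unname(sl$estimate["voltage_V"]), 1.2, tolerance = 1e-8)
  expect_equal(unname(sl$estimate["temperature_C"]), -0.4, tolerance = 1e-8)
  expect_equal(unname(sl$estimate["time_min"]), 0.005, tolerance = 1e-8)
})

test_that("metrics match hand arithmetic and handle edge cases", {
  y <- c(0, 0, 3); yh <- c(0, 1, 2)
  m <- evaluate_predictions(y, yh)
  expect_equal(m$r2, 2 / 3)                 # SS_res 2, SS_tot 6
  expect_equal(m$rmse, sqrt(2 / 3))
  expect_equal(m$mae, 2 / 3)
  perfect <- evaluate_predictions(y, y)
  expect_equal(perfect$r2, 1); expect_equal(perfect$rmse, 0)
  mean_pred <- evaluate_predictions(y, rep(mean(y), 3))
  expect_equal(mean_pred$r2, 0)
  expect_true(m$rmse >= m$mae)
  expect_warning(z <- evaluate_predictions(c(2, 2, 2), c(1, 2, 3)),
                 "zero-variance")
  expect_true(is.na(z$r2))
})

test_that("network training is seed-deterministic and early stopping works", {
  rec <- make_records(12, seed = 9)
  set.seed(9)
  rec$pore_diameter_nm <- rec$pore_diameter_nm + rnorm(nrow(rec), 0, 5)
  fm <- encode_features(rec)
  cfg <- ann_config(max_epochs = 40, seed = 42)
  a1 <- fit_ann(fm, cfg)
  a2 <- fit_ann(fm, cfg)
  expect_identical(a1$W, a2$W)
  expect_identical(predict(a1, fm), predict(a2, fm))
  # a different seed changes the fit
  a3 <- fit_ann(fm, ann_config(max_epochs = 40, seed = 1))
  expect_false(identical(a1$W, a3$W))
  # patience halts on a flat validation loss well before max_epochs
  rec_flat <- rec
  rec_flat$pore_diameter_nm <- rec$pore_diameter_nm
  cfg_pat <- ann_config(max_epochs = 1000, early_stop_patience = 5,
                        learning_rate = 1e-15, seed = 42)
  a4 <- fit_ann(encode_features(rec_flat), cfg_pat)
  expect_lt(a4$history$epochs_run, 1000)
  # zero-weight network predicts a constant
  a0 <- a1
  a0$W <- lapply(a0$W, function(w) w * 0)
  a0$b <- lapply(a0$b, function(x) x * 0)
  expect_equal(unname(predict(a0, fm)), rep(a0$y_center, nrow(fm$X)))
})

test_that("the rectifier network fits noise-free linear data closely", {
  cfg <- generator_config(n_records = 500, noise_sd = 0,
                          b0 = c(H2SO4 = 10, H2C2O4 = 10, H3PO4 = 10),
                          seed = 7)
  fm <- encode_features(generate_dataset(cfg)$records)
  a <- fit_ann(fm, ann_config(seed = 42))
  expect_gt(evaluate_predictions(fm$y, predict(a, fm))$r2, 0.99)
})

test_that("cross-validation folds, aggregation and report are consistent", {
  rec <- suppressMessages(complete_cases(generate_dataset(
    generator_config(n_records = 77, seed = 21))$records))
  cv <- kfold_cv(rec, "mlr", k = 5, seed = 13)
  expect_length(cv$fold_r2, 5)
  expect_equal(cv$mean, mean(cv$fold_r2))
  expect_equal(cv$sd, sqrt(mean((cv$fold_r2 - mean(cv$fold_r2))^2)))
  # fold sizes near-equal: 77 = 2 x 16 + 3 x 15
  set.seed(13)
  sizes <- sort(as.vector(table(sample(rep(1:5, length.out = 77)))))
  expect_equal(sizes, c(15, 15, 15, 16, 16))
  # determinism
  cv2 <- kfold_cv(rec, "mlr", k = 5, seed = 13)
  expect_identical(cv$fold_r2, cv2$fold_r2)
  expect_error(kfold_cv(rec[1:4, ], "mlr", k = 4), "fewer than 2")
})

test_that("training R2 of OLS with intercept is never negative", {
  for (s in 1:5) {
    cfg <- generator_config(n_records = 40, noise_sd = 40, seed = s)
    fm <- encode_features(generate_dataset(cfg)$records)
    m <- fit_mlr(fm)
    expect_gte(evaluate_predictions(fm$y, predict(m, fm))$r2, 0)
  }
})

test_that("models round-trip through JSON save/load", {
  rec <- make_records(14, seed = 14)
  fm <- encode_features(rec)
  m <- fit_mlr(fm)
  a <- fit_ann(fm, ann_config(max_epochs = 20, seed = 42))
  pm <- withr::local_tempfile(fileext = ".json")
  pa <- withr::local_tempfile(fileext = ".json")
  save_model(m, pm); save_model(a, pa)
  m2 <- load_model(pm); a2 <- load_model(pa)
  expect_equal(predict(m2, rec), predict(m, rec), tolerance = 1e-12)
  expect_equal(predict(a2, rec), predict(a, rec), tolerance = 1e-12)
})
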