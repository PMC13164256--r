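test_that("electrolyte names canonicalize across spelling variants", {
  expect_equal(as.vector(canonicalize_electrolyte(
    c("sulphuric acid", "Sulfuric Acid", "H2SO4", "H_2_SO_4_"))),
    rep("H2SO4", 4))
  expect_equal(as.vector(canonicalize_electrolyte("H2C2O4")), "H2C2O4")
  expect_equal(as.vector(canonicalize_electrolyte("oxalic acid")), "H2C2O4")
  expect_equal(as.vector(canonicalize_electrolyte("Phosphoric")), "H3PO4")
  out <- canonicalize_electrolyte(c("citric acid", "H2SO4"))
  expect_equal(as.vector(out), c("citric acid", "H2SO4"))
  expect_equal(attr(out, "unknown"), c(TRUE, FALSE))
})

test_that("case-wise deletion keeps exactly the complete records", {
  rec <- make_records()
  rec$temperature_C[c(2, 5)] <- NA
  rec$time_min[5] <- NA
  kept <- suppressMessages(complete_cases(rec))
  expect_equal(nrow(kept), nrow(rec) - 2)
  expect_identical(kept$source_id, rec$source_id[-c(2, 5)])
  # idempotent; no-op with empty requirement or complete data
  expect_identical(suppressMessages(complete_cases(kept)), kept)
  expect_identical(complete_cases(rec, character(0)), rec)
  expect_error(complete_cases(rec, "no_such_field"), "schema")
  rec$temperature_C <- NA_real_
  expect_warning(suppressMessages(complete_cases(rec)), "no complete cases")
})

test_that("summary statistics use the population SD and count non-missing", {
  rec <- make_records()[1:3, ]
  rec$voltage_V <- c(10, 20, 30)
  rec$temperature_C <- c(5, NA, 15)
  s <- summarize_dataset(rec, c("voltage_V", "temperature_C", "pore_depth_um"))
  v <- s[s$parameter == "voltage_V", ]
  expect_equal(v$min, 10); expect_equal(v$max, 30); expect_equal(v$mean, 20)
  expect_equal(v$sd, sqrt(200 / 3), tolerance = 1e-12)  # population formula
  expect_equal(v$n, 3)
  tc <- s[s$parameter == "temperature_C", ]
  expect_equal(tc$n, 2); expect_equal(tc$mean, 10)
  pd <- s[s$parameter == "pore_depth_um", ]
  expect_equal(pd$n, 0); expect_true(is.na(pd$mean))
  one <- summarize_dataset(rec[2, ], "voltage_V")
  expect_equal(one$sd, 0); expect_equal(one$min, one$max)
})

test_that("encoding produces the documented design matrices", {
  rec <- make_records(n_per_class = 1)
  fm <- encode_features(rec, mode = "onehot")
  expect_equal(ncol(fm$X), 6)
  ind <- fm$X[, paste0("electrolyte_", ELECTROLYTES)]
  expect_equal(sort(colnames(ind)), sort(paste0("electrolyte_", ELECTROLYTES)))
  expect_equal(ind[cbind(1:3, match(rec$electrolyte, ELECTROLYTES))],
               rep(1, 3))
  expect_true(all(ind %in% c(0, 1)))

  fmc <- encode_features(make_records(), mode = "compact")
  expect_equal(ncol(fmc$X), 4)

  rec3 <- make_records()[1:3, ]
  rec3$voltage_V <- c(20, 40, 60)
  rec3$electrolyte <- "H2SO4"
  fm3 <- encode_features(rec3)
  expect_equal(unname(fm3$X[, "voltage_V"]),
               c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  # training columns standardized to mean 0, population SD 1
  fm_all <- encode_features(make_records(8, seed = 2))
  for (cl in c("voltage_V", "temperature_C", "time_min")) {
    expect_lt(abs(mean(fm_all$X[, cl])), 1e-10)
    x <- fm_all$X[, cl]
    expect_lt(abs(sqrt(mean((x - mean(x))^2)) - 1), 1e-10)
  }
  # de-standardization round trip
  expect_equal(destandardize(fm_all, "voltage_V"),
               make_records(8, seed = 2)$voltage_V, tolerance = 1e-9)
  # scaler fitted on training rows only
  tr <- make_records(6, seed = 3); te <- make_records(2, seed = 4)
  fm_te <- encode_features(tr, te)
  fm_tr <- encode_features(tr)
  expect_identical(fm_te$scaler, fm_tr$scaler)
  # unseen level errors
  tr_sub <- tr[tr$electrolyte != "H3PO4", ]
  expect_error(encode_features(tr_sub, te), "absent from training")
  tr$temperature_C[1] <- NA
  expect_error(encode_features(tr), "complete")
})

test_that("stratified split preserves class proportions and partitions", {
  rec <- make_records(20, seed = 6)
  rec <- rec[c(1:18, 21:38, 41:45), ]  # class sizes 18/18/5
  sp <- stratified_split(rec, 0.22, seed = 1)
  expect_equal(sum(sp$test$electrolyte == "H2SO4"), 4)
  expect_equal(sum(sp$test$electrolyte == "H2C2O4"), 4)
  expect_equal(sum(sp$test$electrolyte == "H3PO4"), 1)
  expect_equal(nrow(sp$train) + nrow(sp$test), nrow(rec))
  expect_length(intersect(sp$train$source_id, sp$test$source_id), 0)
  expect_setequal(c(sp$train$source_id, sp$test$source_id), rec$source_id)
  # seed determinism
  sp2 <- stratified_split(rec, 0.22, seed = 1)
  expect_identical(sp$test$source_id, sp2$test$source_id)
  # single-class 80/20
  one <- make_records(40, seed = 7); one$electrolyte <- "H2C2O4"
  sp3 <- stratified_split(one[1:100, ], 0.2, seed = 2)
  expect_equal(nrow(sp3$test), 20)
  # singleton class stays in training, with a warning
  tiny <- rec[c(1:6, 41), ]
  expect_warning(sp4 <- stratified_split(tiny, 0.3, seed = 3), "single")
  expect_true("H3PO4" %in% sp4$train$electrolyte)
})

test_that("CSV round trip preserves records and flags schema errors", {
  ds <- inject_missingness(generate_dataset(
    generator_config(n_records = 25, seed = 8)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_dataset(ds, path)
  back <- read_dataset(path)
  expect_equal(back$pore_diameter_nm, ds$records$pore_diameter_nm,
               tolerance = 1e-12)
  expect_equal(back$electrolyte, ds$records$electrolyte)
  expect_equal(is.na(back$temperature_C), is.na(ds$records$temperature_C))

  broken <- read.csv(path)
  broken$pore_diameter_nm <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(broken, path2, row.names = FALSE)
  expect_error(read_dataset(path2), "pore_diameter_nm")

  bad <- read.csv(path, colClasses = "character")
  bad$voltage_V[3] <- "abc"
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(bad, path3, row.names = FALSE, na = "")
  expect_error(read_dataset(path3), "row 3")
})
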