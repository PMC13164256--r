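# Record schema shared by the generator, the CSV reader/writer and the
# preprocessing steps. Empty CSV fields are missing values.
DATASET_COLUMNS <- c("source_id", "year", "electrolyte",
                     "concentration_value", "concentration_unit",
                     "voltage_V", "temperature_C", "time_min",
                     "current_density_mA_cm2", "pore_diameter_nm",
                     "interpore_distance_nm", "pore_depth_um", "technique")

NUMERIC_COLUMNS <- c("year", "concentration_value", "voltage_V",
                     "temperature_C", "time_min", "current_density_mA_cm2",
                     "pore_diameter_nm", "interpore_distance_nm",
                     "pore_depth_um")

#' Canonicalize electrolyte names
#'
#' Literature sources name the same acid many ways ("sulphuric acid",
#' "sulfuric acid", "H2SO4", with or without subscript markup). This maps
#' spelling/case/formula variants onto the three canonical codes; anything
#' unrecognized passes through unchanged with attribute `unknown = TRUE`
#' entries so callers can exclude it downstream rather than fail.
#'
#' @param raw Character vector of raw electrolyte labels.
#' @return Character vector of canonical codes (`H2SO4`, `H2C2O4`, `H3PO4`)
#'   or the original label where unrecognized; attribute `"unknown"` is a
#'   logical vector flagging unrecognized entries.
#' @examples
#' canonicalize_electrolyte(c("sulphuric acid", "Oxalic Acid", "citric acid"))
#' @export
canonicalize_electrolyte <- function(raw) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(as.character(raw))))
  lut <- c(h2so4 = "H2SO4", sulphuricacid = "H2SO4", sulfuricacid = "H2SO4",
           sulphuric = "H2SO4", sulfuric = "H2SO4",
           h2c2o4 = "H2C2O4", oxalicacid = "H2C2O4", oxalic = "H2C2O4",
           h3po4 = "H3PO4", phosphoricacid = "H3PO4", phosphoric = "H3PO4")
  out <- unname(lut[key])
  unknown <- is.na(out) & !is.na(raw)
  out[unknown] <- as.character(raw)[unknown]
  out[is.na(raw)] <- NA_character_
  attr(out, "unknown") <- unknown
  out
}

#' Keep only records complete in the required fields (case-wise deletion)
#'
#' The standard treatment of missing process parameters in literature
#' compilations: records missing any required field are dropped outright
#' (imputation of mechanistically coupled parameters would add spurious
#' precision). Order is preserved and the retained count is reported via
#' `message()`.
#'
#' @param records Data frame in the record schema (or a
#'   `"synthetic_dataset"`).
#' @param required_fields Character vector of column names that must be
#'   non-missing; defaults to the four modelling inputs.
#' @return The filtered data frame.
#' @examples
#' ds <- generate_dataset(generator_config(n_records = 20, seed = 1))
#' ds <- inject_missingness(ds)
#' nrow(complete_cases(ds$records))
#' @export
complete_cases <- function(records,
                           required_fields = c("voltage_V", "temperature_C",
                                               "time_min", "electrolyte")) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  bad <- setdiff(required_fields, names(records))
  if (length(bad))
    stop("required_fields not in schema: ", paste(bad, collapse = ", "))
  if (!length(required_fields)) return(records)
  keep <- rep(TRUE, nrow(records))
  for (f in required_fields) keep <- keep & !is.na(records[[f]])
  out <- records[keep, , drop = FALSE]
  if (!nrow(out)) warning("no complete cases remain")
  message(sprintf("complete_cases: kept %d of %d records", nrow(out),
                  nrow(records)))
  out
}

# Population SD (divisor n) -- the aggregation convention used throughout
# (summary tables and cross-validation fold statistics).
pop_sd <- function(x) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n == 0) return(NA_real_)
  sqrt(sum((x - mean(x))^2) / n)
}

#' Per-parameter summary statistics
#'
#' Min/max/mean/SD/N over non-missing values for each numeric parameter, in
#' the format of a dataset-characteristics table. SD uses the population
#' formula (divisor N), the same convention as the cross-validation
#' aggregation.
#'
#' @param records Data frame in the record schema (or `"synthetic_dataset"`).
#' @param columns Numeric columns to summarize.
#' @return Data frame with columns `parameter`, `min`, `max`, `mean`, `sd`,
#'   `n`. All-missing columns get `n = 0` and `NA` statistics.
#' @export
summarize_dataset <- function(records,
                              columns = c("voltage_V", "temperature_C",
                                          "time_min", "pore_diameter_nm",
                                          "interpore_distance_nm",
                                          "pore_depth_um")) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  if (!nrow(records)) stop("empty dataset")
  rows <- lapply(columns, function(cl) {
    x <- records[[cl]]
    x <- x[!is.na(x)]
    if (!length(x))
      return(data.frame(parameter = cl, min = NA_real_, max = NA_real_,
                        mean = NA_real_, sd = NA_real_, n = 0L))
    data.frame(parameter = cl, min = min(x), max = max(x), mean = mean(x),
               sd = pop_sd(x), n = length(x))
  })
  do.call(rbind, rows)
}

#' Encode and standardize features for the surrogate models
#'
#' Builds the design matrix from complete records. Continuous inputs
#' (voltage, temperature, time) are standardized to zero mean and unit
#' population SD using statistics fitted on the *training* rows only (the
#' scaler is reused for any apply set, so no information leaks from held-out
#' data). The categorical electrolyte is either
#' one-hot encoded (`mode = "onehot"`: three 0/1 indicator columns, all
#' levels retained, not standardized; 6 columns total) or integer-coded and
#' standardized like the continuous inputs (`mode = "compact"`: 4 columns
#' total, matching a 4-input network).
#'
#' @param train_records Complete-case data frame used to fit the scaler.
#' @param apply_records Data frame to encode with the training scaler;
#'   defaults to `train_records`.
#' @param mode `"onehot"` (default) or `"compact"`.
#' @return A list of class `"feature_matrix"`: `X` (matrix), `y` (pore
#'   diameters, nm), `column_map` (data frame mapping columns to source
#'   features), `scaler` (per-column mean/SD), `mode`, `levels`.
#' @export
encode_features <- function(train_records, apply_records = train_records,
                            mode = c("onehot", "compact")) {
  mode <- match.arg(mode)
  for (nm in c("voltage_V", "temperature_C", "time_min", "electrolyte")) {
    if (any(is.na(train_records[[nm]])) || any(is.na(apply_records[[nm]])))
      stop("encode_features requires complete records in ", nm,
           "; run complete_cases() first")
  }
  lev <- ELECTROLYTES[ELECTROLYTES %in% unique(train_records$electrolyte)]
  unseen <- setdiff(unique(apply_records$electrolyte), lev)
  if (length(unseen))
    stop("electrolyte level(s) absent from training data: ",
         paste(unseen, collapse = ", "))
  cont <- c("voltage_V", "temperature_C", "time_min")
  code_of <- function(e) match(e, ELECTROLYTES) - 1  # H2SO4:0 H2C2O4:1 H3PO4:2

  scaler_mean <- vapply(cont, function(cl) mean(train_records[[cl]]), 0)
  scaler_sd <- vapply(cont, function(cl) pop_sd(train_records[[cl]]), 0)
  if (mode == "compact") {
    scaler_mean <- c(electrolyte_code = mean(code_of(train_records$electrolyte)),
                     scaler_mean)
    scaler_sd <- c(electrolyte_code = pop_sd(code_of(train_records$electrolyte)),
                   scaler_sd)
  }
  if (any(scaler_sd == 0))
    stop("zero-variance training column: ",
         paste(names(scaler_sd)[scaler_sd == 0], collapse = ", "))

  scaler <- list(mean = scaler_mean, sd = scaler_sd)
  X <- .encode_apply(apply_records, scaler, mode, lev)
  if (mode == "onehot") {
    column_map <- data.frame(
      column = colnames(X),
      feature = c(rep("electrolyte_type", length(lev)), cont),
      level = c(lev, rep(NA_character_, length(cont))),
      stringsAsFactors = FALSE)
  } else {
    column_map <- data.frame(
      column = colnames(X),
      feature = c("electrolyte_type", cont),
      level = NA_character_, stringsAsFactors = FALSE)
  }
  structure(list(X = X, y = apply_records$pore_diameter_nm,
                 column_map = column_map, scaler = scaler,
                 mode = mode, levels = lev),
            class = "feature_matrix")
}

# Apply a fitted scaler/encoding to a set of records; shared by
# encode_features() and the predict() methods of fitted surrogates.
.encode_apply <- function(rec, scaler, mode, lev) {
  cont <- c("voltage_V", "temperature_C", "time_min")
  unseen <- setdiff(unique(rec$electrolyte), lev)
  if (length(unseen))
    stop("electrolyte level(s) absent from training data: ",
         paste(unseen, collapse = ", "))
  Xc <- sapply(cont, function(cl)
    (rec[[cl]] - scaler$mean[[cl]]) / scaler$sd[[cl]])
  Xc <- matrix(Xc, nrow = nrow(rec), dimnames = list(NULL, cont))
  if (mode == "onehot") {
    ind <- sapply(lev, function(l) as.numeric(rec$electrolyte == l))
    ind <- matrix(ind, nrow = nrow(rec),
                  dimnames = list(NULL, paste0("electrolyte_", lev)))
    cbind(ind, Xc)
  } else {
    code <- match(rec$electrolyte, ELECTROLYTES) - 1
    ec <- (code - scaler$mean[["electrolyte_code"]]) /
      scaler$sd[["electrolyte_code"]]
    cbind(electrolyte_code = ec, Xc)
  }
}

#' Invert the standardization of a continuous feature column
#'
#' @param fm A `"feature_matrix"`.
#' @param column Name of a standardized column.
#' @return Numeric vector on the original scale.
#' @export
destandardize <- function(fm, column) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (!column %in% names(fm$scaler$mean))
    stop("column '", column, "' is not standardized")
  fm$X[, column] * fm$scaler$sd[[column]] + fm$scaler$mean[[column]]
}

#' Train/test split stratified by electrolyte type
#'
#' Allocates `round(class_n * test_fraction)` records of each electrolyte
#' class to the test set after a seeded within-class shuffle, keeping at
#' least one training member per class (a singleton class goes entirely to
#' training with a warning).
#'
#' @param records Complete-case data frame.
#' @param test_fraction Fraction held out, in (0, 1).
#' @param seed Integer seed for the within-class shuffle.
#' @return List with data frames `train` and `test`.
#' @export
stratified_split <- function(records, test_fraction = 0.22, seed = 42) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  stopifnot(test_fraction > 0, test_fraction < 1)
  set.seed(seed)
  test_idx <- integer(0)
  for (e in unique(records$electrolyte)) {
    idx <- which(records$electrolyte == e)
    if (length(idx) == 1) {
      warning("class ", e, " has a single record; kept entirely in training")
      next
    }
    n_test <- min(round(length(idx) * test_fraction), length(idx) - 1)
    test_idx <- c(test_idx, sample(idx)[seq_len(n_test)])
  }
  list(train = records[-test_idx, , drop = FALSE],
       test = records[sort(test_idx), , drop = FALSE])
}

#' Read an anodization dataset from CSV
#'
#' Comma-separated, UTF-8, `.` decimal; empty fields are missing. The header
#' must contain the full record schema (see [write_dataset()] for the column
#' list). Non-numeric entries in numeric columns raise an error naming the
#' offending row.
#'
#' @param path File path.
#' @return Data frame in the record schema.
#' @export
read_dataset <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", na.strings = "")
  missing_cols <- setdiff(DATASET_COLUMNS, names(raw))
  if (length(missing_cols))
    stop("dataset file is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  raw <- raw[DATASET_COLUMNS]
  for (cl in NUMERIC_COLUMNS) {
    v <- raw[[cl]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(!is.na(v) & is.na(num))
    if (length(bad))
      stop("non-numeric value '", v[bad[1]], "' in column ", cl,
           ", row ", bad[1])
    raw[[cl]] <- num
  }
  raw$year <- as.integer(raw$year)
  raw
}

#' Write an anodization dataset to CSV
#'
#' Round-trips with [read_dataset()]: missing values serialize as empty
#' fields. Columns: `source_id, year, electrolyte, concentration_value,
#' concentration_unit, voltage_V, temperature_C, time_min,
#' current_density_mA_cm2, pore_diameter_nm, interpore_distance_nm,
#' pore_depth_um, technique`.
#'
#' @param records Data frame in the record schema (or `"synthetic_dataset"`).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(records, path) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  utils::write.csv(records[DATASET_COLUMNS], path, row.names = FALSE,
                   na = "")
  invisible(path)
}
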