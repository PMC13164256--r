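# Shared fixtures built in code.

# Minimal complete-case record frame covering all three electrolytes.
make_records <- function(n_per_class = 4, seed = 1) {
  cfg <- generator_config(n_records = 3 * n_per_class,
                          class_probs = c(H2SO4 = 1, H2C2O4 = 0, H3PO4 = 0),
                          seed = seed)
  # force balanced classes deterministically
  ds <- generate_dataset(cfg)$records
  ds$electrolyte <- rep(ELECTROLYTES, each = n_per_class)
  for (e in ELECTROLYTES) {
    idx <- ds$electrolyte == e
    rng <- cfg$voltage_range[[e]]
    ds$voltage_V[idx] <- seq(rng[1], rng[2], length.out = sum(idx))
  }
  ds$pore_diameter_nm <- mean_diameter(ds$electrolyte, ds$voltage_V,
                                       ds$temperature_C, ds$time_min, cfg)
  ds
}

# Hand-buildable feature matrix for exercising the fitters on toy data.
make_feature_matrix <- function(X, y) {
  structure(list(X = X, y = y,
                 column_map = data.frame(column = colnames(X),
                                         feature = colnames(X),
                                         level = NA_character_),
                 scaler = list(mean = stats::setNames(numeric(ncol(X)),
                                                      colnames(X)),
                               sd = stats::setNames(rep(1, ncol(X)),
                                                    colnames(X))),
                 mode = "compact", levels = ELECTROLYTES),
            class = "feature_matrix")
}
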