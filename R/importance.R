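# Collapse per-column scores onto the four original features. Indicator (or
# integer-coded) electrolyte columns are summed into a single
# "electrolyte_type" entry: summation preserves the normalization total,
# unlike max or mean.
.aggregate_importance <- function(scores, column_map, method, model_label) {
  stopifnot(identical(names(scores), column_map$column))
  if (all(scores == 0))
    stop("all scores are zero; importance normalization undefined")
  per_feature <- tapply(scores, column_map$feature, sum)
  order_ref <- c("voltage_V", "temperature_C", "time_min", "electrolyte_type")
  per_feature <- per_feature[order_ref[order_ref %in% names(per_feature)]]
  pct <- 100 * per_feature / sum(per_feature)
  structure(list(
    table = data.frame(feature = names(pct), importance_pct = as.numeric(pct),
                       rank = rank(-pct, ties.method = "min"),
                       stringsAsFactors = FALSE),
    method = method, model = model_label,
    caveat = paste("weight-based importance is an indicative proxy;",
                   "it inspects first-layer weights or standardized",
                   "coefficients only and ignores deeper interactions")),
    class = "importance_report")
}

#' Connection-weight feature importance of the network surrogate
#'
#' For each input column, the mean absolute weight connecting it to the
#' first hidden layer; indicator columns of the electrolyte are summed into
#' one "electrolyte_type" score; scores are normalized to sum to 100%.
#' This first-layer-weight proxy is indicative rather than definitive — it
#' ignores how signals transform in deeper layers.
#'
#' @param model A fitted `"naa_ann"`.
#' @return An `"importance_report"`: a 4-row table of
#'   `(feature, importance_pct, rank)` summing to 100, plus method metadata.
#' @export
ann_importance <- function(model) {
  stopifnot(inherits(model, "naa_ann"))
  W1 <- model$W[[1]]
  scores <- rowMeans(abs(W1))
  names(scores) <- model$column_map$column
  .aggregate_importance(scores, model$column_map,
                        "mean absolute first-layer weight", "ann")
}

#' Standardized-coefficient feature importance of the linear surrogate
#'
#' Absolute values of the coefficients fitted on standardized inputs
#' (intercept excluded); electrolyte indicator coefficients are summed by
#' absolute value into one "electrolyte_type" score; normalized to 100%.
#' The reference-cell indicator dropped during fitting contributes zero.
#'
#' @param model A fitted `"naa_mlr"`.
#' @return An `"importance_report"` (see [ann_importance()]).
#' @export
mlr_importance <- function(model) {
  stopifnot(inherits(model, "naa_mlr"))
  co <- model$coefficients[-1]  # drop intercept
  scores <- stats::setNames(numeric(nrow(model$column_map)),
                            model$column_map$column)
  scores[names(co)] <- abs(co)
  .aggregate_importance(scores, model$column_map,
                        "absolute standardized coefficient", "mlr")
}

#' @export
print.importance_report <- function(x, ...) {
  cat("Feature importance (", x$method, ", ", toupper(x$model), ")\n",
      sep = "")
  tab <- x$table
  tab$importance_pct <- round(tab$importance_pct, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}
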