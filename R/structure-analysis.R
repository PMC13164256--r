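#' Predicted pore diameter across a voltage sweep
#'
#' Evaluates a fitted surrogate over a voltage grid at fixed temperature,
#' time and electrolyte (the conventional presentation of the
#' voltage-diameter relationship: 10 degC, 60 min). The reported slope is
#' the mean finite difference over the grid, in nm/V. A warning is issued
#' when the grid leaves the surrogate's usual training support (above 150 V
#' literature data are sparse).
#'
#' @param model A fitted `"naa_mlr"` or `"naa_ann"`.
#' @param electrolyte One of the training electrolyte levels.
#' @param V_grid Strictly increasing voltage grid (V).
#' @param T_C Fixed temperature (degC).
#' @param t_min Fixed time (min).
#' @return List of class `"sweep_result"`: `parameter`, `grid`,
#'   `prediction` (nm), `slope` (nm per unit), `fixed` conditions.
#' @export
voltage_response <- function(model, electrolyte, V_grid = seq(20, 150, by = 5),
                             T_C = 10, t_min = 60) {
  stopifnot(all(diff(V_grid) > 0))
  if (max(V_grid) > 150)
    warning("voltage grid extends above 150 V, where training data are sparse")
  rec <- data.frame(electrolyte = electrolyte, voltage_V = V_grid,
                    temperature_C = T_C, time_min = t_min,
                    stringsAsFactors = FALSE)
  pred <- predict(model, rec)
  structure(list(parameter = "voltage_V", grid = V_grid, prediction = pred,
                 slope = mean(diff(pred) / diff(V_grid)),
                 fixed = list(electrolyte = electrolyte, temperature_C = T_C,
                              time_min = t_min)),
            class = "sweep_result")
}

#' Temperature sensitivity of predicted pore diameter
#'
#' As [voltage_response()] with the swept and fixed axes swapped: predicted
#' diameter over a temperature grid at fixed voltage and time. In the
#' literature the sensitivity is modest and negative, around -0.3 to -0.5
#' nm/degC.
#'
#' @inheritParams voltage_response
#' @param T_grid Strictly increasing temperature grid (degC).
#' @param V Fixed voltage (V).
#' @return A `"sweep_result"`; `slope` is in nm/degC.
#' @export
temperature_sensitivity <- function(model, electrolyte,
                                    T_grid = seq(0, 30, by = 1),
                                    V = 40, t_min = 60) {
  stopifnot(all(diff(T_grid) > 0))
  rec <- data.frame(electrolyte = electrolyte, voltage_V = V,
                    temperature_C = T_grid, time_min = t_min,
                    stringsAsFactors = FALSE)
  pred <- predict(model, rec)
  structure(list(parameter = "temperature_C", grid = T_grid,
                 prediction = pred,
                 slope = mean(diff(pred) / diff(T_grid)),
                 fixed = list(electrolyte = electrolyte, voltage_V = V,
                              time_min = t_min)),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat("Sweep of", x$parameter, "over [", min(x$grid), ",", max(x$grid),
      "]:", length(x$grid), "points; mean slope",
      sprintf("%.4f", x$slope), "nm per unit\n")
  invisible(x)
}

#' Empirical voltage proportionality rule for oxalic-acid pores
#'
#' The widely used single-parameter rule of thumb: pore diameter =
#' 1.29 x voltage (nm) for oxalic-acid anodization.
#'
#' @param V Voltage (V), vectorised; must be non-negative.
#' @return Pore diameter (nm).
#' @examples
#' empirical_rule(40)  # 51.6 nm
#' @export
empirical_rule <- function(V) {
  stopifnot(all(V >= 0))
  1.29 * V
}

#' Benchmark a surrogate against the 1.29 x V rule
#'
#' On a set of oxalic-acid records, compares the RMSE of the fitted
#' multivariate surrogate against the single-parameter proportionality rule,
#' both evaluated on the identical records.
#'
#' @param model A fitted surrogate.
#' @param records Data frame restricted to oxalic-acid (`H2C2O4`) records.
#' @return List with `rmse_model`, `rmse_rule` (nm) and `n`.
#' @export
rule_benchmark <- function(model, records) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  records <- records[records$electrolyte == "H2C2O4", , drop = FALSE]
  if (!nrow(records)) stop("no oxalic-acid records to benchmark on")
  y <- records$pore_diameter_nm
  list(rmse_model = evaluate_predictions(y, predict(model, records))$rmse,
       rmse_rule = evaluate_predictions(y, empirical_rule(records$voltage_V))$rmse,
       n = nrow(records))
}

#' Regression of pore diameter on interpore distance
#'
#' OLS fit over all records reporting both measurements. In self-ordered
#' anodic alumina the relationship is approximately linear with slope
#' ~0.35 (pore diameter is 30-40% of the interpore distance).
#'
#' @param records Data frame (or `"synthetic_dataset"`).
#' @return List with `slope`, `intercept`, `r2`, `n`.
#' @export
pore_interpore_regression <- function(records) {
  if (inherits(records, "synthetic_dataset")) records <- records$records
  ok <- !is.na(records$pore_diameter_nm) & !is.na(records$interpore_distance_nm)
  if (sum(ok) < 3) stop("need at least 3 records with both measurements")
  fit <- stats::lm(pore_diameter_nm ~ interpore_distance_nm,
                   data = records[ok, ])
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r2 = summary(fit)$r.squared, n = sum(ok))
}

#' Geometric porosity of a hexagonal pore array
#'
#' For cylindrical pores on a hexagonal lattice the areal (= volumetric)
#' porosity is
#' \deqn{\epsilon = \frac{\pi}{2\sqrt{3}} \left(\frac{d_p}{D_{int}}\right)^2}
#' bounded above by pi/(2 sqrt 3) ~ 0.9069 when neighbouring pores touch.
#'
#' @param d_p Pore diameter (nm); must satisfy `0 <= d_p < D_int`.
#' @param D_int Interpore distance (nm).
#' @return Porosity fraction.
#' @examples
#' hexagonal_porosity(35, 100)  # ~0.111
#' @export
hexagonal_porosity <- function(d_p, D_int) {
  stopifnot(all(d_p >= 0), all(D_int > 0))
  if (any(d_p >= D_int))
    stop("pore diameter must be smaller than the interpore distance")
  (pi / (2 * sqrt(3))) * (d_p / D_int)^2
}

#' Drug-loading capacity of a nanoporous layer
#'
#' Assumes the pore volume is completely filled with drug solution at
#' concentration `C0`, so the areal loading is porosity x depth x C0
#' (with depth converted from micrometres to centimetres, yielding
#' micrograms per square centimetre).
#'
#' @param d_p Pore diameter (nm).
#' @param D_int Interpore distance (nm).
#' @param depth Pore depth (um); must be non-negative.
#' @param C0 Drug concentration (mg/mL).
#' @return Loading (ug/cm^2).
#' @examples
#' loading_capacity(35.58, 100, depth = 10, C0 = 100)  # ~10 ug/cm^2
#' @export
loading_capacity <- function(d_p, D_int, depth, C0) {
  stopifnot(all(depth >= 0), all(C0 >= 0))
  eps <- hexagonal_porosity(d_p, D_int)
  # depth um -> cm (1e-4); C0 mg/mL = mg/cm^3; mg -> ug (1e3)
  eps * (depth * 1e-4) * C0 * 1e3
}
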