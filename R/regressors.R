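#' Hyperparameters of the feed-forward pore-diameter network
#'
#' Fixed architecture and optimizer settings for the 64-32-16 rectifier
#' network: three hidden layers of 64, 32 and 16 units, linear output, Adam
#' optimizer (lr 0.001, beta1 0.9, beta2 0.999, eps 1e-8), mini-batches of
#' 32, at most 1000 epochs, early stopping on a held-out 15% validation
#' split with patience 50 epochs, L2 penalty 1e-4, seed 42.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths.
#' @param learning_rate,beta1,beta2,epsilon Adam settings.
#' @param batch_size Mini-batch size.
#' @param max_epochs Epoch budget.
#' @param early_stop_patience Epochs without validation improvement before
#'   training halts.
#' @param validation_fraction Fraction of the training rows held out to
#'   monitor generalization (not stratified).
#' @param l2_penalty L2 weight-decay coefficient.
#' @param seed Seed for weight initialization, the validation split and
#'   batch shuffling; a fixed seed makes training bit-reproducible.
#' @return List of class `"ann_config"`.
#' @export
ann_config <- function(hidden_sizes = c(64, 32, 16), learning_rate = 0.001,
                       beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                       batch_size = 32, max_epochs = 1000,
                       early_stop_patience = 50, validation_fraction = 0.15,
                       l2_penalty = 1e-4, seed = 42) {
  stopifnot(all(hidden_sizes > 0), learning_rate > 0, beta1 > 0, beta2 > 0,
            epsilon > 0, batch_size > 0, max_epochs > 0,
            early_stop_patience > 0,
            validation_fraction > 0, validation_fraction < 1,
            l2_penalty >= 0)
  structure(list(hidden_sizes = as.integer(hidden_sizes),
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_patience = as.integer(early_stop_patience),
                 validation_fraction = validation_fraction,
                 l2_penalty = l2_penalty, seed = as.integer(seed)),
            class = "ann_config")
}

#' Fit the multiple-linear-regression surrogate
#'
#' Ordinary least squares of pore diameter on the encoded features. Under
#' one-hot encoding the design uses reference-cell coding (the first
#' electrolyte indicator is dropped and an intercept added) so the normal
#' equations are full rank; under compact encoding all four standardized
#' columns enter with an intercept.
#'
#' @param fm A `"feature_matrix"` from [encode_features()].
#' @return Object of class `"naa_mlr"` with elements `coefficients` (named,
#'   including `(Intercept)`), `fit` (the underlying `lm` object, for
#'   standard errors), the encoding metadata and `dropped_level`.
#' @export
fit_mlr <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  X <- fm$X
  dropped <- NA_character_
  if (fm$mode == "onehot") {
    dropped <- paste0("electrolyte_", fm$levels[1])
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
  }
  df <- as.data.frame(X)
  df$.y <- fm$y
  fit <- stats::lm(.y ~ ., data = df)
  if (any(is.na(stats::coef(fit))))
    stop("rank-deficient design; collinear column(s): ",
         paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
               collapse = ", "))
  structure(list(coefficients = stats::coef(fit), fit = fit,
                 column_map = fm$column_map, scaler = fm$scaler,
                 mode = fm$mode, levels = fm$levels,
                 dropped_level = dropped),
            class = "naa_mlr")
}

# Coerce predict() input (records data frame or feature_matrix) to a design
# matrix consistent with the model's training encoding.
.model_design <- function(object, newdata) {
  if (inherits(newdata, "feature_matrix")) {
    if (!identical(newdata$column_map$column, object$column_map$column))
      stop("feature-matrix columns do not match the model's encoding")
    newdata$X
  } else {
    .encode_apply(newdata, object$scaler, object$mode, object$levels)
  }
}

#' @export
predict.naa_mlr <- function(object, newdata, ...) {
  X <- .model_design(object, newdata)
  if (object$mode == "onehot")
    X <- X[, setdiff(colnames(X), object$dropped_level), drop = FALSE]
  co <- object$coefficients
  drop(cbind(1, X[, names(co)[-1], drop = FALSE]) %*% co)
}

#' Slopes of the linear surrogate on the original measurement scale
#'
#' De-standardizes the fitted coefficients of the continuous inputs
#' (coefficient divided by the training population SD), giving slopes in
#' nm/V, nm/degC and nm/min.
#'
#' @param model A `"naa_mlr"`.
#' @return Named list with `estimate` and `se` vectors on original units.
#' @export
mlr_slopes <- function(model) {
  stopifnot(inherits(model, "naa_mlr"))
  sm <- summary(model$fit)$coefficients
  cont <- intersect(rownames(sm), names(model$scaler$sd))
  sds <- unlist(model$scaler$sd[cont])
  list(estimate = sm[cont, "Estimate"] / sds,
       se = sm[cont, "Std. Error"] / sds)
}

relu <- function(z) pmax(z, 0)

.ann_forward <- function(W, b, X) {
  L <- length(W)
  A <- vector("list", L)
  Z <- vector("list", L)
  a <- X
  for (l in seq_len(L)) {
    z <- a %*% W[[l]] + matrix(b[[l]], nrow(a), length(b[[l]]), byrow = TRUE)
    a <- if (l < L) relu(z) else z
    Z[[l]] <- z
    A[[l]] <- a
  }
  list(Z = Z, A = A, out = drop(a))
}

#' Fit the feed-forward network surrogate
#'
#' Trains the rectifier network of [ann_config()] by mini-batch Adam on a
#' mean-squared-error loss with L2 weight decay. Weights use seeded
#' He-normal initialization (SD `sqrt(2/fan_in)`), biases start at zero.
#' A `validation_fraction` share of the rows is held out (seeded,
#' unstratified); training stops when the validation loss has not improved
#' for `early_stop_patience` consecutive epochs or at `max_epochs`, and the
#' weights from the best validation epoch are restored. The target is
#' centred and scaled internally during optimization and predictions are
#' returned in nm; the rectifier derivative at 0 is taken as 0.
#'
#' @param fm A `"feature_matrix"`.
#' @param config An [ann_config()].
#' @return Object of class `"naa_ann"` with weight matrices `W`, biases `b`,
#'   the target scaling, training `history` (per-epoch training/validation
#'   loss, epochs run, best epoch) and the encoding metadata.
#' @export
fit_ann <- function(fm, config = ann_config()) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(config, "ann_config"))
  X <- fm$X
  n <- nrow(X)
  if (n < config$batch_size)
    stop("need at least batch_size (", config$batch_size, ") samples")
  y_center <- mean(fm$y)
  y_scale <- pop_sd(fm$y)
  if (y_scale == 0) stop("constant target; nothing to fit")
  y <- (fm$y - y_center) / y_scale

  set.seed(config$seed)
  n_val <- max(1L, round(config$validation_fraction * n))
  perm <- sample(n)
  val_idx <- perm[seq_len(n_val)]
  tr_idx <- perm[-seq_len(n_val)]
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xva <- X[val_idx, , drop = FALSE]; yva <- y[val_idx]

  dims <- c(ncol(X), config$hidden_sizes, 1L)
  L <- length(dims) - 1L
  W <- lapply(seq_len(L), function(l)
    matrix(stats::rnorm(dims[l] * dims[l + 1], 0, sqrt(2 / dims[l])),
           dims[l], dims[l + 1]))
  b <- lapply(seq_len(L), function(l) numeric(dims[l + 1]))
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  step <- 0L

  ntr <- length(tr_idx)
  best_val <- Inf; best_W <- W; best_b <- b; best_epoch <- 0L
  wait <- 0L
  tr_loss <- numeric(0); va_loss <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(ntr)
    starts <- seq(1, ntr, by = config$batch_size)
    for (s in starts) {
      bi <- ord[s:min(s + config$batch_size - 1L, ntr)]
      Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
      m <- length(bi)
      fw <- .ann_forward(W, b, Xb)
      delta <- matrix((fw$out - yb) / m, m, 1)   # d(MSE/2)/d z_L
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        a_prev <- if (l == 1) Xb else fw$A[[l - 1]]
        gW[[l]] <- crossprod(a_prev, delta) + config$l2_penalty * W[[l]]
        gb[[l]] <- colSums(delta)
        if (l > 1) delta <- (delta %*% t(W[[l]])) * (fw$Z[[l - 1]] > 0)
      }
      step <- step + 1L
      c1 <- 1 - config$beta1^step
      c2 <- 1 - config$beta2^step
      for (l in seq_len(L)) {
        mW[[l]] <- config$beta1 * mW[[l]] + (1 - config$beta1) * gW[[l]]
        vW[[l]] <- config$beta2 * vW[[l]] + (1 - config$beta2) * gW[[l]]^2
        W[[l]] <- W[[l]] - config$learning_rate * (mW[[l]] / c1) /
          (sqrt(vW[[l]] / c2) + config$epsilon)
        mb[[l]] <- config$beta1 * mb[[l]] + (1 - config$beta1) * gb[[l]]
        vb[[l]] <- config$beta2 * vb[[l]] + (1 - config$beta2) * gb[[l]]^2
        b[[l]] <- b[[l]] - config$learning_rate * (mb[[l]] / c1) /
          (sqrt(vb[[l]] / c2) + config$epsilon)
      }
    }
    tl <- mean((.ann_forward(W, b, Xtr)$out - ytr)^2)
    vl <- mean((.ann_forward(W, b, Xva)$out - yva)^2)
    if (!is.finite(tl) || !is.finite(vl))
      stop("non-finite loss at epoch ", epoch)
    tr_loss <- c(tr_loss, tl); va_loss <- c(va_loss, vl)
    if (vl < best_val - 1e-10) {
      best_val <- vl; best_W <- W; best_b <- b; best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$early_stop_patience) break
    }
  }
  structure(list(W = best_W, b = best_b, config = config,
                 y_center = y_center, y_scale = y_scale,
                 column_map = fm$column_map, scaler = fm$scaler,
                 mode = fm$mode, levels = fm$levels,
                 history = list(epochs_run = length(tr_loss),
                                best_epoch = best_epoch,
                                train_loss = tr_loss, val_loss = va_loss)),
            class = "naa_ann")
}

#' @export
predict.naa_ann <- function(object, newdata, ...) {
  X <- .model_design(object, newdata)
  .ann_forward(object$W, object$b, X)$out * object$y_scale + object$y_center
}

#' @export
print.naa_mlr <- function(x, ...) {
  cat("Linear pore-diameter surrogate (OLS),", x$mode, "encoding\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
print.naa_ann <- function(x, ...) {
  cat("Feed-forward pore-diameter surrogate (",
      paste(x$config$hidden_sizes, collapse = "-"), " rectifier units, ",
      x$mode, " encoding)\n", sep = "")
  cat("  epochs run:", x$history$epochs_run,
      "(best validation at", x$history$best_epoch, ")\n")
  invisible(x)
}

#' Regression metrics for pore-diameter predictions
#'
#' R-squared (1 - SS_res/SS_tot about the mean of `y`), RMSE and MAE in nm.
#'
#' @param y Observed values.
#' @param y_hat Predicted values, same length.
#' @return List of class `"naa_metrics"`: `r2`, `rmse`, `mae`, `n`. With a
#'   zero-variance `y`, `r2` is `NA` with a warning.
#' @export
evaluate_predictions <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  ss_res <- sum((y - y_hat)^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) {
    warning("zero-variance response; R-squared undefined")
    NA_real_
  } else 1 - ss_res / ss_tot
  structure(list(r2 = r2, rmse = sqrt(mean((y - y_hat)^2)),
                 mae = mean(abs(y - y_hat)), n = length(y)),
            class = "naa_metrics")
}

#' @export
print.naa_metrics <- function(x, ...) {
  cat(sprintf("n = %d  R2 = %.4f  RMSE = %.2f nm  MAE = %.2f nm\n",
              x$n, x$r2, x$rmse, x$mae))
  invisible(x)
}

#' Aggregate cross-validation fold scores
#'
#' Mean and population standard deviation (divisor k) of the per-fold
#' R-squared values — the convention used for reporting k-fold results.
#'
#' @param scores Numeric vector of per-fold scores.
#' @return List with `mean` and `sd`.
#' @examples
#' cv_aggregate(c(0.764, 0.6644, 0.6615, 0.6784, 0.8783))
#' @export
cv_aggregate <- function(scores) {
  list(mean = mean(scores), sd = pop_sd(scores))
}

#' k-fold cross-validation of a surrogate
#'
#' Shuffles the complete-case records with `seed`, cuts them into `k`
#' near-equal folds (sizes differing by at most one), and for each fold
#' refits the chosen surrogate on the remaining folds — including refitting
#' the scaler on those folds only, so no standardization statistics leak
#' from the held-out fold — and scores R-squared on the held-out fold.
#' Folds are not stratified by electrolyte.
#'
#' @param records Complete-case data frame.
#' @param model `"mlr"` or `"ann"`.
#' @param k Number of folds.
#' @param seed Seed for fold assignment (independent of the network seed).
#' @param mode Encoding mode passed to [encode_features()].
#' @param config [ann_config()] used when `model = "ann"`.
#' @return List of class `"cv_report"`: `fold_r2`, `mean`, `sd`
#'   (population), `k`, `seed`, `model`.
#' @export
kfold_cv <- function(records, model = c("mlr", "ann"), k = 5, seed = 42,
                     mode = c("onehot", "compact"), config = ann_config()) {
  model <- match.arg(model)
  mode <- match.arg(mode)
  if (inherits(records, "synthetic_dataset")) records <- records$records
  n <- nrow(records)
  stopifnot(k >= 2, n >= k)
  set.seed(seed)
  fold_of <- sample(rep(seq_len(k), length.out = n))
  if (min(table(fold_of)) < 2) stop("a fold has fewer than 2 samples")
  fold_r2 <- vapply(seq_len(k), function(f) {
    tr <- records[fold_of != f, , drop = FALSE]
    te <- records[fold_of == f, , drop = FALSE]
    fm_tr <- encode_features(tr, mode = mode)
    fm_te <- encode_features(tr, te, mode = mode)
    fit <- if (model == "mlr") fit_mlr(fm_tr) else fit_ann(fm_tr, config)
    evaluate_predictions(fm_te$y, predict(fit, fm_te))$r2
  }, 0)
  agg <- cv_aggregate(fold_r2)
  structure(list(fold_r2 = fold_r2, mean = agg$mean, sd = agg$sd, k = k,
                 seed = seed, model = model),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV, %s: R2 per fold %s; mean %.4f, SD %.4f\n",
              x$k, toupper(x$model),
              paste(sprintf("%.4f", x$fold_r2), collapse = " "),
              x$mean, x$sd))
  invisible(x)
}

#' Save / load a fitted surrogate as portable JSON
#'
#' Serializes the model configuration, encoding metadata and fitted
#' parameters (coefficients or weight matrices) to a JSON file. The
#' underlying `lm` object of an MLR fit is not stored; the reloaded model
#' predicts identically but carries no standard errors.
#'
#' @param model A `"naa_mlr"` or `"naa_ann"`.
#' @param path Output file.
#' @return `path` invisibly (`save_model`); the reconstructed model
#'   (`load_model`).
#' @export
save_model <- function(model, path) {
  base <- list(class = class(model), mode = model$mode,
               levels = model$levels, column_map = model$column_map,
               scaler = list(mean = as.list(model$scaler$mean),
                             sd = as.list(model$scaler$sd)))
  extra <- if (inherits(model, "naa_mlr")) {
    list(coefficients = as.list(model$coefficients),
         dropped_level = model$dropped_level)
  } else {
    list(W = model$W, b = model$b, y_center = model$y_center,
         y_scale = model$y_scale, config = unclass(model$config))
  }
  jsonlite::write_json(c(base, extra), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  scaler <- list(mean = as.list(obj$scaler$mean), sd = as.list(obj$scaler$sd))
  if ("naa_mlr" %in% obj$class) {
    structure(list(coefficients = unlist(obj$coefficients), fit = NULL,
                   column_map = obj$column_map, scaler = scaler,
                   mode = obj$mode, levels = obj$levels,
                   dropped_level = obj$dropped_level),
              class = "naa_mlr")
  } else {
    cfg <- do.call(ann_config, obj$config)
    structure(list(W = lapply(obj$W, as.matrix), b = lapply(obj$b, as.numeric),
                   config = cfg, y_center = obj$y_center,
                   y_scale = obj$y_scale, column_map = obj$column_map,
                   scaler = scaler, mode = obj$mode, levels = obj$levels,
                   history = NULL),
              class = "naa_ann")
  }
}
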