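#' Fit the linear count-bias correction
#'
#' Raw pipeline totals systematically underestimate the number of flowers on
#' a plant: some flowers are occluded or out of frame, a few are counted
#' twice from opposite sides. An ordinary-least-squares line
#' `reference = a * raw + b` fitted against manual reference counts absorbs
#' this bias. Confidence intervals use the t distribution with `n - 2`
#' degrees of freedom.
#'
#' @param x raw pipeline totals (one per plant).
#' @param y reference counts (field ground truth: the average of the manual
#'   operator counts).
#' @param level confidence level for the parameter intervals (default 0.95).
#' @return A `calibration_model`: list with `slope`, `intercept`, `ci`
#'   (2 x 2 matrix, rows slope/intercept), `n`, `sigma2` (residual
#'   variance), `r_squared`, and the underlying `lm` fit.
#' @export
fit_ols <- function(x, y, level = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length", call. = FALSE)
  n <- length(x)
  if (n < 3)
    stop("calibration needs at least 3 points (got ", n, ")", call. = FALSE)
  if (stats::var(x) == 0)
    stop("calibration is unfittable: raw totals are constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # exact linear data makes lm warn about a perfect fit; that case is
  # handled explicitly below, so the warning is noise here
  ci <- suppressWarnings(stats::confint(fit, level = level))
  model <- list(slope = unname(stats::coef(fit)[2]),
                intercept = unname(stats::coef(fit)[1]),
                ci = rbind(slope = ci["x", ], intercept = ci["(Intercept)", ]),
                n = n,
                sigma2 = sum(stats::resid(fit)^2) / (n - 2),
                r_squared = suppressWarnings(summary(fit)$r.squared),
                fit = fit)
  # exact linear data: lm reports NaN intervals; the width is truly zero
  if (model$sigma2 < 1e-20) {
    model$ci <- rbind(slope = c(model$slope, model$slope),
                      intercept = c(model$intercept, model$intercept))
    colnames(model$ci) <- colnames(ci)
  }
  class(model) <- "calibration_model"
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("count calibration: y = %.3f x + %.3f  (n = %d)\n",
              x$slope, x$intercept, x$n))
  cat(sprintf("  95%% CI slope [%.3f, %.3f], intercept [%.3f, %.3f]\n",
              x$ci["slope", 1], x$ci["slope", 2],
              x$ci["intercept", 1], x$ci["intercept", 2]))
  invisible(x)
}

#' Apply a calibration model to raw totals
#'
#' Corrected count = `slope * raw + intercept`, floored at zero (a count
#' cannot be negative). Corrected values are real numbers, as reference
#' counts themselves are operator averages with decimals; use `round` for
#' display.
#'
#' @param model a [fit_ols()] result.
#' @param raw numeric vector of raw totals.
#' @param round round the corrected values to integers (default `FALSE`).
#' @return numeric vector of corrected counts.
#' @export
apply_calibration <- function(model, raw, round = FALSE) {
  stopifnot(inherits(model, "calibration_model"))
  out <- pmax(0, model$slope * as.numeric(raw) + model$intercept)
  if (round) base::round(out) else out
}

#' @export
predict.calibration_model <- function(object, newdata, ...) {
  apply_calibration(object, newdata)
}

#' Leave-one-out corrected counts
#'
#' For each plant i, fits the calibration on all other plants and predicts
#' plant i — an honest estimate of out-of-sample correction accuracy when
#' the calibration set is as small as a handful of plants.
#'
#' @inheritParams fit_ols
#' @return numeric vector: the held-out corrected count for each point.
#' @export
loo_predictions <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 4)
    stop("leave-one-out needs at least 4 points", call. = FALSE)
  vapply(seq_along(x), function(i) {
    m <- tryCatch(fit_ols(x[-i], y[-i]),
                  error = function(e) stop("leave-one-out fold ", i,
                                           " unfittable: ", conditionMessage(e),
                                           call. = FALSE))
    apply_calibration(m, x[i])
  }, numeric(1))
}

#' Count-accuracy error metrics
#'
#' The per-plant accuracy measures reported for the counting pipeline:
#' * MAE, mean absolute error, in flowers;
#' * MAPE, mean absolute percentage error (percent of the reference count);
#' * the population (divisor n) standard deviation of the per-plant
#'   absolute percentage errors;
#' * R^2 computed against the reference as `1 - SS_res / SS_tot`
#'   (not a squared correlation), so a biased predictor is penalized.
#'
#' @param predicted predicted (raw or corrected) counts.
#' @param truth reference counts; must be strictly positive for MAPE.
#' @return An `error_report`: list with `mae`, `mape`, `ape_sd`,
#'   `r_squared`, `n`.
#' @export
error_metrics <- function(predicted, truth) {
  predicted <- as.numeric(predicted); truth <- as.numeric(truth)
  if (length(predicted) != length(truth))
    stop("predicted and truth must have equal length", call. = FALSE)
  if (any(truth == 0))
    stop("MAPE undefined: reference counts contain zero", call. = FALSE)
  ape <- abs(predicted - truth) / abs(truth) * 100
  structure(list(mae = mean(abs(predicted - truth)),
                 mape = mean(ape),
                 ape_sd = sqrt(mean((ape - mean(ape))^2)),
                 r_squared = 1 - sum((predicted - truth)^2) /
                   sum((truth - mean(truth))^2),
                 n = length(truth)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf("n = %d plants: MAE = %.2f flowers, MAPE = %.2f%% (APE sd %.2f%%), R^2 = %.3f\n",
              x$n, x$mae, x$mape, x$ape_sd, x$r_squared))
  invisible(x)
}

#' Calibrate a count table
#'
#' Convenience wrapper around [fit_ols()] / [loo_predictions()] /
#' [apply_calibration()] / [error_metrics()] for a per-plant table of raw
#' totals and reference counts. Three documented modes:
#' * `"full"` — fit on all plants, correct all plants (in-sample);
#' * `"loo"` — leave-one-out: each plant corrected by a model fitted on the
#'   others;
#' * `"subset"` — fit on the plants in `subset`, correct every plant.
#'
#' @param counts data frame with columns `raw_total` and `reference`
#'   (and optionally `plant_id`).
#' @param mode `"full"`, `"loo"` or `"subset"`.
#' @param subset integer indices of fitting plants for `mode = "subset"`.
#' @return list with `model` (the fitted [fit_ols()] model; for `"loo"` the
#'   full-data model is reported), `corrected` (per-plant corrected counts),
#'   `errors_raw` and `errors_corrected` ([error_metrics()] reports).
#' @export
calibrate_counts <- function(counts, mode = c("full", "loo", "subset"),
                             subset = NULL) {
  mode <- match.arg(mode)
  stopifnot(all(c("raw_total", "reference") %in% names(counts)))
  x <- counts$raw_total; y <- counts$reference
  model <- if (mode == "subset") {
    if (is.null(subset)) stop("mode 'subset' needs subset indices", call. = FALSE)
    fit_ols(x[subset], y[subset])
  } else fit_ols(x, y)
  corrected <- switch(mode,
                      full = apply_calibration(model, x),
                      subset = apply_calibration(model, x),
                      loo = loo_predictions(x, y))
  list(model = model, corrected = corrected,
       errors_raw = error_metrics(x, y),
       errors_corrected = error_metrics(corrected, y))
}

#' Packaged per-plant count table from the field validation
#'
#' Loads the packaged CSV of the seven-plant field test: per-side raw
#' detector counts, per-plant raw totals, the reference count (average of
#' four manual operator counts) and the published bias-corrected totals.
#'
#' @return list with `sides` (columns `plant_id`, `side`, `raw_count`) and
#'   `plants` (columns `plant_id`, `raw_total`, `reference`, `corrected`).
#' @export
field_counts <- function() {
  sides <- utils::read.csv(system.file("extdata", "field_side_counts.csv",
                                       package = "hazelcount"))
  plants <- utils::read.csv(system.file("extdata", "field_plant_counts.csv",
                                        package = "hazelcount"))
  list(sides = sides, plants = plants)
}
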