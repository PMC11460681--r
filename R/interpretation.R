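#' Univariate partial dependence curve
#'
#' `pdp(t)` is the mean predicted occurrence probability over all rows of
#' the table with the chosen feature forced to `t` and every other
#' covariate held at its observed combination. Computed by batch
#' prediction; exactly equal to the brute-force row-by-row average.
#'
#' @param model a fitted xgboost model (or an `sdm_fit`).
#' @param table the table whose observed covariate combinations are
#'   averaged over.
#' @param feature feature name.
#' @param grid ascending numeric grid; default 100 evenly spaced points
#'   spanning the observed feature range in `table` (for the study pipeline
#'   that table pools occurrence and background cells, so the grid spans
#'   the observed background + occurrence temperature range).
#' @param n_grid grid resolution when `grid` is NULL.
#' @return data.frame of class `pdp_curve`: `feature` value (`temp` column
#'   named after the feature), `pdp` (mean predicted probability),
#'   `scaled` (min-max scaled to `[0, 1]`).
#' @export
compute_pdp <- function(model, table, feature, grid = NULL, n_grid = 100L) {
  if (inherits(model, "sdm_fit")) model <- model$model
  feats <- setdiff(names(table), c("label", "cell_id", "lon", "lat"))
  if (!feature %in% feats) stop("feature '", feature, "' not in table")
  if (is.null(grid)) {
    r <- range(table[[feature]], na.rm = TRUE)
    grid <- seq(r[1], r[2], length.out = n_grid)
  }
  if (length(grid) == 0) stop("empty PDP grid")
  if (is.unsorted(grid, strictly = TRUE)) stop("PDP grid must be strictly ascending")
  X <- as.matrix(table[feats])
  n <- nrow(X)
  big <- X[rep(seq_len(n), times = length(grid)), , drop = FALSE]
  big[, feature] <- rep(grid, each = n)
  preds <- predict(model, big)
  pdp <- colMeans(matrix(preds, nrow = n))
  out <- data.frame(grid, pdp = pdp, scaled = scale_unit_interval(pdp))
  names(out)[1] <- feature
  attr(out, "feature") <- feature
  class(out) <- c("pdp_curve", "data.frame")
  out
}

#' Gain-based variable importance across bootstrap iterations
#'
#' Extracts per-feature gain from each iteration's fitted trees. Features
#' never split upon carry zero gain. Summarized by the median and full
#' min-max range per feature across iterations.
#'
#' @param bundle a `model_bundle` from [bootstrap_models].
#' @return list with `per_iteration` (data.frame `iteration`, `feature`,
#'   `gain`) and `summary` (data.frame `feature`, `median_gain`,
#'   `min_gain`, `max_gain`, ordered by decreasing median).
#' @export
variable_importance <- function(bundle) {
  stopifnot(length(bundle$fits) >= 1)
  feats <- bundle$fits[[1]]$fit$features
  rows <- lapply(seq_along(bundle$fits), function(it) {
    imp <- xgboost::xgb.importance(model = bundle$fits[[it]]$fit$model)
    gain <- structure(rep(0, length(feats)), names = feats)
    gain[imp$Feature] <- imp$Gain
    data.frame(iteration = it, feature = feats, gain = as.numeric(gain),
               row.names = NULL)
  })
  per_it <- do.call(rbind, rows)
  med <- vapply(split(per_it$gain, per_it$feature), stats::median, 0)
  mn <- vapply(split(per_it$gain, per_it$feature), min, 0)
  mx <- vapply(split(per_it$gain, per_it$feature), max, 0)
  summ <- data.frame(feature = names(med), median_gain = med,
                     min_gain = mn, max_gain = mx, row.names = NULL)
  summ <- summ[order(-summ$median_gain), ]
  list(per_iteration = per_it, summary = summ)
}

pdp_values <- function(curve) {
  stopifnot(nrow(curve) >= 3)
  t <- curve[[1]]
  if (is.unsorted(t, strictly = TRUE)) stop("PDP grid must be strictly ascending")
  list(t = t, v = curve$pdp)
}

#' Thermal minimum from a partial dependence curve
#'
#' Forward empirical derivatives `d_i = (v_{i+1} - v_i) / (t_{i+1} - t_i)`.
#' \describe{
#'   \item{`persistent_rise`}{the temperature at the first grid point whose
#'     derivative is strictly positive and stays strictly positive for the
#'     next temperature step as well (the curve "begins increasing").}
#'   \item{`steepest`}{the temperature at the largest derivative (lowest
#'     temperature on ties) -- the point of most rapid increase.}
#' }
#' Returns `NA` when no grid point qualifies (e.g. a constant curve).
#'
#' @param curve a `pdp_curve` (or data.frame with the grid in column 1 and
#'   a `pdp` column), at least 3 grid points.
#' @param mode `"persistent_rise"` (default) or `"steepest"`.
#' @return temperature in degrees C, or `NA_real_`.
#' @export
extract_thermal_minimum <- function(curve,
                                    mode = c("persistent_rise", "steepest")) {
  mode <- match.arg(mode)
  pv <- pdp_values(curve)
  d <- diff(pv$v) / diff(pv$t)
  if (mode == "persistent_rise") {
    ok <- which(d[-length(d)] > 0 & d[-1] > 0)
    if (length(ok) == 0) return(NA_real_)
    pv$t[ok[1]]
  } else {
    if (all(d <= 0)) return(NA_real_)
    pv$t[which.max(d)]  # which.max takes the first (lowest T) on ties
  }
}

#' Thermal optimum from a partial dependence curve
#'
#' The grid temperature of the curve maximum (lowest temperature on exact
#' ties). Flagged absent (`NA`) when the maximum is attained at the final
#' grid point -- a boundary maximum gives no evidence of an interior
#' optimum (field curves rarely resolve structure above the optimum).
#'
#' @inheritParams extract_thermal_minimum
#' @return temperature in degrees C, or `NA_real_`.
#' @export
extract_thermal_optimum <- function(curve) {
  pv <- pdp_values(curve)
  vmax <- max(pv$v)
  if (pv$v[length(pv$v)] == vmax) return(NA_real_)  # boundary maximum
  pv$t[which.max(pv$v)]
}

#' Summarize per-iteration thermal extrema
#'
#' Median and full min-max range across the iterations where the quantity
#' is defined, with the number of undefined iterations reported. Returns an
#' absent summary (all `NA`) with a reason when no iteration defines the
#' quantity.
#'
#' @param values numeric vector of per-iteration estimates (`NA` = absent).
#' @return list `median`, `min`, `max`, `n_defined`, `n_undefined`,
#'   `reason` (NULL unless absent).
#' @export
summarize_extrema <- function(values) {
  stopifnot(length(values) >= 1)
  def <- values[!is.na(values)]
  if (length(def) == 0) {
    return(list(median = NA_real_, min = NA_real_, max = NA_real_,
                n_defined = 0L, n_undefined = length(values),
                reason = "quantity undefined in every iteration"))
  }
  list(median = stats::median(def), min = min(def), max = max(def),
       n_defined = length(def), n_undefined = sum(is.na(values)),
       reason = NULL)
}

#' Extract and summarize field thermal extrema from a model bundle
#'
#' For each bootstrap iteration, computes the temperature PDP over a shared
#' grid and extracts the thermal minimum (both rules) and optimum; then
#' summarizes each quantity across iterations.
#'
#' @param bundle a `model_bundle`.
#' @param feature temperature feature name.
#' @param grid shared PDP grid (default: `n_grid` points over the pooled
#'   observed range in the bundle's table).
#' @param n_grid extraction grid resolution, default 40. Deliberately
#'   coarser than the 100-point plotting default of [compute_pdp]: partial
#'   dependence of a boosted tree ensemble is piecewise constant, and the
#'   empirical-derivative rules need the difference step to exceed the
#'   ensemble's step spacing, otherwise the persistent-rise rule fires at
#'   isolated mid-slope steps instead of the onset of the rise.
#' @return list of class `field_extrema`: `per_iteration` (data.frame),
#'   `tmin` / `tmin_steepest` / `topt` (summaries from
#'   [summarize_extrema]), `curves` (list of `pdp_curve`), `grid`.
#' @export
field_thermal_extrema <- function(bundle, feature = "temperature_mean",
                                  grid = NULL, n_grid = 40L) {
  if (is.null(grid)) {
    r <- range(bundle$table[[feature]], na.rm = TRUE)
    grid <- seq(r[1], r[2], length.out = n_grid)
  }
  curves <- lapply(bundle$fits, function(f) {
    compute_pdp(f$fit$model, bundle$table, feature, grid = grid)
  })
  per_it <- data.frame(
    iteration = seq_along(curves),
    tmin = vapply(curves, extract_thermal_minimum, 0, mode = "persistent_rise"),
    tmin_steepest = vapply(curves, extract_thermal_minimum, 0, mode = "steepest"),
    topt = vapply(curves, extract_thermal_optimum, 0)
  )
  structure(list(per_iteration = per_it,
                 tmin = summarize_extrema(per_it$tmin),
                 tmin_steepest = summarize_extrema(per_it$tmin_steepest),
                 topt = summarize_extrema(per_it$topt),
                 curves = curves, grid = grid),
            class = "field_extrema")
}
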