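#' Min-max scale values to the unit interval
#'
#' `(v - min) / (max - min)`. A constant input maps to all zeros with a
#' warning rather than failing (a flat curve carries no shape to scale).
#'
#' @param values numeric, length >= 2.
#' @return scaled values in `[0, 1]`.
#' @export
scale_unit_interval <- function(values) {
  stopifnot(length(values) >= 2)
  rng <- range(values, na.rm = TRUE)
  if (rng[1] == rng[2]) {
    warning("constant input: scaled curve set to all zeros")
    return(rep(0, length(values)))
  }
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Pearson product-moment correlation
#'
#' Thin validated wrapper over the standard product-moment correlation;
#' fails informatively (naming the offending side) on zero variance.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0) stop("zero variance in x")
  if (stats::sd(y) == 0) stop("zero variance in y")
  stats::cor(x, y)
}

#' Correlate lab-based and field-based thermal extrema across species
#'
#' Computes the Pearson correlation between median field (SDM
#' partial-dependence) and median lab (mechanistic M(T)) thermal minima,
#' and separately for thermal optima, together with per-species
#' lab-minus-field differences (degrees C). Species missing one side of a
#' quantity are excluded pairwise from that quantity only, with counts
#' reported.
#'
#' @param pairs data.frame with columns `species`, `field_tmin`,
#'   `field_topt`, `lab_tmin`, `lab_topt` (medians; `NA` = absent).
#' @return list of class `lab_field_comparison`: `r_tmin`, `r_topt`,
#'   `differences` (data.frame of lab - field per species),
#'   `n_excluded_tmin`, `n_excluded_topt`.
#' @export
compare_lab_field <- function(pairs) {
  stopifnot(all(c("species", "field_tmin", "field_topt",
                  "lab_tmin", "lab_topt") %in% names(pairs)))
  corr_for <- function(lab, field, what) {
    ok <- !is.na(lab) & !is.na(field)
    if (sum(ok) < 3) {
      stop("fewer than 3 species with both lab and field ", what,
           " defined (", sum(ok), ")")
    }
    list(r = pearson_r(lab[ok], field[ok]), n_excluded = sum(!ok))
  }
  tmin <- corr_for(pairs$lab_tmin, pairs$field_tmin, "thermal minima")
  topt <- corr_for(pairs$lab_topt, pairs$field_topt, "thermal optima")
  structure(list(
    r_tmin = tmin$r, r_topt = topt$r,
    differences = data.frame(
      species = pairs$species,
      tmin_lab_minus_field = pairs$lab_tmin - pairs$field_tmin,
      topt_lab_minus_field = pairs$lab_topt - pairs$field_topt
    ),
    n_excluded_tmin = tmin$n_excluded, n_excluded_topt = topt$n_excluded
  ), class = "lab_field_comparison")
}

#' @export
print.lab_field_comparison <- function(x, ...) {
  cat(sprintf("<lab_field_comparison> r(Tmin) = %.3f, r(Topt) = %.3f over %d species\n",
              x$r_tmin, x$r_topt, nrow(x$differences)))
  invisible(x)
}
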