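#' Briere thermal performance curve
#'
#' Briere-1 form `c * T * (T - T0) * sqrt(Tm - T)` on `(T0, Tm)`, zero
#' outside; the standard asymmetric trait response (used for mosquito
#' development rate, MDR).
#'
#' @param temp temperature in degrees C (vectorized).
#' @param c positive scale.
#' @param t0 lower thermal zero (degrees C).
#' @param tm upper thermal zero (degrees C), `t0 < tm`.
#' @return trait value, nonnegative and continuous.
#' @export
briere <- function(temp, c, t0, tm) {
  stopifnot(c > 0, t0 < tm)
  out <- rep(0, length(temp))
  inside <- temp > t0 & temp < tm
  ti <- temp[inside]
  out[inside] <- c * ti * (ti - t0) * sqrt(tm - ti)
  out
}

#' Quadratic thermal performance curve
#'
#' Symmetric quadratic trait responses:
#' \describe{
#'   \item{`concave_down`}{`q * (T - T0) * (Tm - T)` truncated at 0 outside
#'     `(T0, Tm)`: zero at both roots, maximal at the midpoint (eggs per
#'     female per day, egg-to-adult survival).}
#'   \item{`concave_up`}{`q * (T - T0) * (T - Tm)`: minimal (negative) at
#'     the midpoint, growing toward both ends and positive outside the
#'     roots (adult mortality rate; downstream composition clamps it below
#'     at a positive floor).}
#' }
#'
#' @param temp temperature in degrees C (vectorized).
#' @param q positive scale.
#' @param t0,tm roots in degrees C, `t0 < tm`.
#' @param orientation `"concave_down"` or `"concave_up"`.
#' @return trait value.
#' @export
quadratic_tpc <- function(temp, q, t0, tm,
                          orientation = c("concave_down", "concave_up")) {
  stopifnot(q > 0, t0 < tm)
  orientation <- match.arg(orientation)
  if (orientation == "concave_down") {
    pmax(0, q * (temp - t0) * (tm - temp))
  } else {
    q * (temp - t0) * (temp - tm)
  }
}

# Evaluate one trait draw over a grid.
eval_trait <- function(trait, temp) {
  switch(trait$family,
    briere = briere(temp, trait$c, trait$t0, trait$tm),
    quadratic = quadratic_tpc(temp, trait$q, trait$t0, trait$tm,
                              trait$orientation),
    stop("unknown trait family: ", trait$family)
  )
}

#' Synthetic reference trait parameter set
#'
#' A plausible, internally consistent set of trait thermal-performance
#' parameters for a generic warm-climate mosquito. These are synthetic
#' placeholders for testing and simulation -- NOT fitted values for any
#' real species (the source posteriors for real species live in the trait
#' literature and are not reproduced here).
#'
#' @return named list of trait parameter lists (`efd`, `pea`, `mdr`, `mu`),
#'   each with `family` and its parameters.
#' @export
default_trait_params <- function() {
  list(
    efd = list(family = "quadratic", orientation = "concave_down",
               q = 0.04, t0 = 14, tm = 34),    # eggs/female/day
    pea = list(family = "quadratic", orientation = "concave_down",
               q = 0.004, t0 = 13, tm = 38),   # probability
    mdr = list(family = "briere", c = 6e-5, t0 = 11, tm = 40),  # 1/days
    mu = list(family = "quadratic", orientation = "concave_up",
              q = 0.01, t0 = 16, tm = 30)      # deaths/day
  )
}

#' Trait set whose abundance curve matches a target truth
#'
#' Constructs a trait parameter set whose composed abundance curve M(T) has
#' its thermal minimum exactly at `tmin` (the development-rate lower zero
#' dominates the numerator supports), its maximum support edge at `tmax`,
#' and its optimum calibrated to `topt` by shifting the two concave-down
#' quadratics' common center until the dense-grid argmax of M lands on the
#' target (1-D numerical calibration at construction time).
#'
#' @param tmin,topt,tmax target critical temperatures, `tmin < topt < tmax`.
#' @return named trait parameter list as in [default_trait_params].
#' @export
trait_params_for_truth <- function(tmin = 12, topt = 27, tmax = 36) {
  stopifnot(tmin < topt, topt < tmax)
  half <- (tmax - tmin) / 2 + 4
  make <- function(shift) {
    ctr <- topt + shift
    list(
      efd = list(family = "quadratic", orientation = "concave_down",
                 q = 0.04, t0 = min(ctr - half, tmin - 1), tm = max(ctr + half, tmax + 2)),
      pea = list(family = "quadratic", orientation = "concave_down",
                 q = 0.004, t0 = tmin - 2, tm = tmax + 4),
      mdr = list(family = "briere", c = 6e-5, t0 = tmin, tm = tmax),
      mu = list(family = "quadratic", orientation = "concave_up",
                q = 0.01, t0 = tmin + 3, tm = tmax - 3)
    )
  }
  dense <- seq(tmin, tmax, by = 0.01)
  argmax_for <- function(shift) {
    tr <- make(shift)
    m <- eval_trait(tr$efd, dense) * eval_trait(tr$pea, dense) *
      eval_trait(tr$mdr, dense) / pmax(eval_trait(tr$mu, dense), 1e-3)^2
    dense[which.max(m)]
  }
  opt <- stats::optimize(function(s) (argmax_for(s) - topt)^2,
                         interval = c(-10, 10))
  make(opt$minimum)
}

#' Generate pseudo-posterior trait parameter draws
#'
#' Samples per-draw trait parameters around true values: thermal thresholds
#' get additive Gaussian noise with SD `dispersion` (degrees C), scale
#' parameters get multiplicative lognormal noise with sdlog
#' `0.05 * dispersion`. Draws violating validity (`t0 >= tm`) are redrawn.
#' `dispersion = 0` collapses every draw to the true values.
#'
#' @param true_params named trait list (see [default_trait_params]).
#' @param n_draws number of posterior draws (study default 5000).
#' @param dispersion nonnegative spread (degrees C on thresholds).
#' @param seed RNG seed.
#' @return list of class `trait_posterior`: per trait, a data.frame of
#'   draws (one row per draw); plus `n_draws`, `true_params`.
#' @export
generate_trait_posteriors <- function(true_params = default_trait_params(),
                                      n_draws = 5000L, dispersion = 0.5,
                                      seed = 1L) {
  stopifnot(n_draws >= 1, dispersion >= 0)
  with_seed(seed, {
    draws <- lapply(true_params, function(tr) {
      t0 <- tr$t0 + rnorm(n_draws, 0, dispersion)
      tm <- tr$tm + rnorm(n_draws, 0, dispersion)
      bad <- which(t0 >= tm)
      while (length(bad) > 0) {
        t0[bad] <- tr$t0 + rnorm(length(bad), 0, dispersion)
        tm[bad] <- tr$tm + rnorm(length(bad), 0, dispersion)
        bad <- bad[t0[bad] >= tm[bad]]
      }
      scale_name <- if (tr$family == "briere") "c" else "q"
      sc <- tr[[scale_name]] * exp(rnorm(n_draws, 0, 0.05 * dispersion))
      df <- data.frame(t0 = t0, tm = tm, scale = sc)
      attr(df, "family") <- tr$family
      attr(df, "orientation") <- tr$orientation %||% NA_character_
      df
    })
    structure(list(draws = draws, n_draws = as.integer(n_draws),
                   true_params = true_params),
              class = "trait_posterior")
  })
}

draw_trait <- function(posterior, trait, i) {
  df <- posterior$draws[[trait]]
  fam <- attr(df, "family")
  out <- list(family = fam, t0 = df$t0[i], tm = df$tm[i])
  if (fam == "briere") out$c <- df$scale[i] else {
    out$q <- df$scale[i]
    out$orientation <- attr(df, "orientation")
  }
  out
}

#' Temperature-dependent mosquito abundance curve M(T)
#'
#' Composes the trait curves into equilibrium abundance
#' `M(T) = EFD(T) * pEA(T) * MDR(T) / mu(T)^2` per posterior draw, with
#' M set to zero wherever any numerator trait is nonpositive and the
#' mortality rate clamped below at `mu_floor` to prevent division blow-up
#' where the concave-up quadratic approaches zero. Pointwise median and
#' 2.5/97.5 percentile credible band are attached.
#'
#' @param posterior a `trait_posterior`.
#' @param grid ascending temperature grid (degrees C), default 0-45 by 0.1.
#' @param mu_floor lower clamp for the mortality rate (day^-1).
#' @return list of class `abundance_curve`: `grid`, `draws` (n_draws x
#'   n_grid matrix), `median`, `lower`, `upper`, `mu_floor`,
#'   `mu_clamp_fraction` (share of draw-by-grid points where the clamp was
#'   active).
#' @export
abundance_curve <- function(posterior, grid = seq(0, 45, by = 0.1),
                            mu_floor = 1e-3) {
  if (length(grid) == 0) stop("empty temperature grid")
  stopifnot(!is.unsorted(grid, strictly = TRUE), mu_floor > 0)
  n <- posterior$n_draws
  M <- matrix(0, n, length(grid))
  clamped <- 0
  for (i in seq_len(n)) {
    efd <- eval_trait(draw_trait(posterior, "efd", i), grid)
    pea <- eval_trait(draw_trait(posterior, "pea", i), grid)
    mdr <- eval_trait(draw_trait(posterior, "mdr", i), grid)
    mu <- eval_trait(draw_trait(posterior, "mu", i), grid)
    mu_c <- pmax(mu, mu_floor)
    clamped <- clamped + sum(mu < mu_floor)
    m <- efd * pea * mdr / mu_c^2
    m[efd <= 0 | pea <= 0 | mdr <= 0] <- 0
    M[i, ] <- m
  }
  qs <- apply(M, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE)
  structure(list(grid = grid, draws = M,
                 median = qs[2, ], lower = qs[1, ], upper = qs[3, ],
                 mu_floor = mu_floor,
                 mu_clamp_fraction = clamped / (n * length(grid))),
            class = "abundance_curve")
}

#' Thermal extrema of one abundance curve draw
#'
#' `tmin` = first grid temperature with `M > 0`; `topt` = grid argmax
#' (lowest temperature on ties); `tmax` = last grid temperature with
#' `M > 0`. All absent (`NA`) when M is identically zero.
#'
#' @param m numeric M(T) values over `grid`.
#' @param grid ascending temperature grid.
#' @return named numeric `c(tmin, topt, tmax)` (possibly `NA`).
#' @export
curve_extrema <- function(m, grid) {
  stopifnot(length(m) == length(grid), !is.unsorted(grid, strictly = TRUE))
  pos <- which(m > 0)
  if (length(pos) == 0) {
    return(c(tmin = NA_real_, topt = NA_real_, tmax = NA_real_))
  }
  c(tmin = grid[pos[1]], topt = grid[which.max(m)], tmax = grid[pos[length(pos)]])
}

#' Posterior summary of mechanistic thermal extrema
#'
#' Per-draw extrema of the abundance curve, summarized by the median and
#' 2.5th/97.5th percentile credible interval over the draws where each
#' quantity is defined.
#'
#' @param curve an `abundance_curve`.
#' @return list of class `mechanistic_extrema`: `per_draw` (data.frame),
#'   and for each of `tmin`, `topt`, `tmax` a list `median`, `lower`,
#'   `upper`; plus `n_undefined`.
#' @export
posterior_summary <- function(curve) {
  ex <- t(apply(curve$draws, 1, curve_extrema, grid = curve$grid))
  ex <- as.data.frame(ex)
  if (all(is.na(ex$tmin))) {
    stop("no posterior draw has a defined abundance curve")
  }
  summ <- lapply(ex, function(v) {
    d <- v[!is.na(v)]
    list(median = stats::median(d),
         lower = stats::quantile(d, 0.025, names = FALSE),
         upper = stats::quantile(d, 0.975, names = FALSE))
  })
  structure(c(summ, list(per_draw = ex, n_undefined = sum(is.na(ex$tmin)))),
            class = "mechanistic_extrema")
}

#' @export
print.mechanistic_extrema <- function(x, ...) {
  cat(sprintf("<mechanistic_extrema> Tmin %.2f [%.2f, %.2f]  Topt %.2f [%.2f, %.2f]  Tmax %.2f [%.2f, %.2f]\n",
              x$tmin$median, x$tmin$lower, x$tmin$upper,
              x$topt$median, x$topt$lower, x$topt$upper,
              x$tmax$median, x$tmax$lower, x$tmax$upper))
  invisible(x)
}
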