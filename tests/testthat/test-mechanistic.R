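test_that("Briere curve matches its closed form and zeroes", {
  expect_equal(briere(10, 1e-4, 10, 38), 0)
  expect_equal(briere(38, 1e-4, 10, 38), 0)
  expect_equal(briere(c(5, 45), 1e-4, 10, 38), c(0, 0))
  # direct formula evaluation at an interior point
  expect_equal(briere(25, 1e-4, 10, 38), 1e-4 * 25 * 15 * sqrt(13))
  # continuity near the upper zero (sqrt tail: O(sqrt(eps)))
  expect_lt(briere(38 - 1e-8, 1e-4, 10, 38), 1e-4)
})

test_that("quadratic curves have the stated vertex structure", {
  # concave-down: zero at the roots, vertex value q ((Tm-T0)/2)^2 at midpoint
  expect_equal(quadratic_tpc(5, 0.01, 5, 35), 0)
  expect_equal(quadratic_tpc(20, 0.01, 5, 35), 0.01 * 15 * 15)
  expect_equal(quadratic_tpc(20, 0.01, 5, 35), 0.01 * ((35 - 5) / 2)^2)
  expect_equal(quadratic_tpc(40, 0.01, 5, 35), 0)  # truncated outside
  # concave-up: minimal at the midpoint, grows toward both ends
  up <- function(t) quadratic_tpc(t, 0.02, 10, 30, "concave_up")
  expect_lt(up(20), up(15))
  expect_lt(up(20), up(25))
  expect_gt(up(5), 0)
  expect_gt(up(35), 0)
  expect_equal(up(20), 0.02 * 10 * (-10))
})

test_that("abundance composition reproduces hand arithmetic", {
  # trait parameters engineered so that at T = 20: EFD = 2, pEA = 0.5,
  # MDR = 0.1, mu = 0.2  =>  M = 2 * 0.5 * 0.1 / 0.2^2 = 2.5
  tp <- list(
    efd = list(family = "quadratic", orientation = "concave_down",
               q = 0.02, t0 = 10, tm = 30),
    pea = list(family = "quadratic", orientation = "concave_down",
               q = 0.005, t0 = 10, tm = 30),
    mdr = list(family = "briere", c = 0.1 / (200 * sqrt(10)), t0 = 10, tm = 30),
    mu = list(family = "quadratic", orientation = "concave_up",
              q = 0.001, t0 = 30, tm = 40)
  )
  post <- generate_trait_posteriors(tp, n_draws = 3, dispersion = 0, seed = 1)
  ac <- abundance_curve(post, grid = c(5, 20, 35))
  expect_equal(ac$draws[1, 2], 2.5)
  expect_equal(ac$draws[1, c(1, 3)], c(0, 0))  # numerator support ends
  # identical draws -> zero-width credible band
  expect_equal(ac$lower, ac$upper)
  expect_equal(ac$median, ac$draws[1, ])
  expect_error(abundance_curve(post, grid = numeric(0)), "empty")
})

test_that("mortality clamping keeps the composition finite and reported", {
  post <- generate_trait_posteriors(default_trait_params(), n_draws = 5,
                                    dispersion = 0, seed = 1)
  ac <- abundance_curve(post)
  expect_true(all(is.finite(ac$draws)))
  expect_true(all(ac$draws >= 0))
  expect_gt(ac$mu_clamp_fraction, 0)  # concave-up mu dips below the floor
})

test_that("extrema of a single curve follow their definitions", {
  grid <- seq(0, 40, by = 0.5)
  m <- ifelse(grid > 12 & grid < 35, (grid - 12) * (35 - grid), 0)
  ex <- curve_extrema(m, grid)
  expect_equal(unname(ex["tmin"]), 12.5)  # first grid point with M > 0
  expect_equal(unname(ex["topt"]), 23.5)  # vertex of the product
  expect_equal(unname(ex["tmax"]), 34.5)
  # ties at the maximum resolve to the lowest temperature
  mt <- c(0, 1, 2, 2, 1, 0)
  expect_equal(unname(curve_extrema(mt, 1:6)["topt"]), 3)
  expect_true(all(is.na(curve_extrema(rep(0, 5), 1:5))))
})

test_that("numerator scaling moves M but never the extrema", {
  tp <- default_trait_params()
  tp2 <- tp; tp2$efd$q <- tp$efd$q * 7
  p1 <- generate_trait_posteriors(tp, n_draws = 2, dispersion = 0, seed = 1)
  p2 <- generate_trait_posteriors(tp2, n_draws = 2, dispersion = 0, seed = 1)
  a1 <- abundance_curve(p1); a2 <- abundance_curve(p2)
  expect_equal(a2$draws[1, ], 7 * a1$draws[1, ])
  expect_equal(curve_extrema(a2$draws[1, ], a2$grid),
               curve_extrema(a1$draws[1, ], a1$grid))
})

test_that("grid refinement moves extrema by at most one coarse step", {
  post <- generate_trait_posteriors(default_trait_params(), n_draws = 1,
                                    dispersion = 0, seed = 1)
  coarse <- abundance_curve(post, grid = seq(0, 45, by = 0.2))
  fine <- abundance_curve(post, grid = seq(0, 45, by = 0.1))
  exc <- curve_extrema(coarse$draws[1, ], coarse$grid)
  exf <- curve_extrema(fine$draws[1, ], fine$grid)
  expect_true(all(abs(exc - exf) <= 0.2 + 1e-12))
})

test_that("pseudo-posteriors collapse at zero dispersion and center on truth", {
  tp <- default_trait_params()
  p0 <- generate_trait_posteriors(tp, n_draws = 50, dispersion = 0, seed = 3)
  expect_true(all(p0$draws$mdr$t0 == tp$mdr$t0))
  expect_true(all(p0$draws$efd$scale == tp$efd$q))
  # the study default is 5000 draws
  expect_equal(eval(formals(generate_trait_posteriors)$n_draws), 5000L)
  # draw means converge to truth within 3 standard errors
  disp <- 0.5
  p <- generate_trait_posteriors(tp, n_draws = 5000, dispersion = disp, seed = 4)
  se <- disp / sqrt(5000)
  expect_lt(abs(mean(p$draws$mdr$t0) - tp$mdr$t0), 3 * se)
  expect_lt(abs(mean(p$draws$pea$tm) - tp$pea$tm), 3 * se)
  expect_true(all(p$draws$mu$t0 < p$draws$mu$tm))  # validity enforced
})

test_that("posterior summaries have zero width for identical draws", {
  post <- generate_trait_posteriors(default_trait_params(), n_draws = 10,
                                    dispersion = 0, seed = 1)
  ac <- abundance_curve(post)
  ps <- posterior_summary(ac)
  expect_equal(ps$tmin$lower, ps$tmin$upper)
  expect_equal(ps$topt$median, ps$topt$lower)
  expect_equal(ps$n_undefined, 0)
})
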