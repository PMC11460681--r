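test_that("partial dependence equals the brute-force row loop", {
  tab <- separable_table(60)
  prof <- tiny_profile()
  sp <- stratified_split(tab, 0.8, seed = 1)
  hp <- list(learning_rate = 0.2, max_depth = 3, min_child_weight = 1,
             row_subsample = 1, column_subsample = 1, min_split_loss = 0)
  fit <- fit_and_evaluate(sp$train, sp$eval, hp, nrounds = 15, prof, 1)
  grid <- seq(min(tab$temperature_mean), max(tab$temperature_mean),
              length.out = 9)
  pdp <- compute_pdp(fit, tab, "temperature_mean", grid = grid)
  feats <- c("temperature_mean", "other")
  oracle <- vapply(grid, function(t) {
    X <- as.matrix(tab[feats]); X[, "temperature_mean"] <- t
    mean(predict(fit$model, X))
  }, 0)
  expect_equal(pdp$pdp, oracle, tolerance = 1e-12)
  expect_error(compute_pdp(fit, tab, "temperature_mean", grid = numeric(0)),
               "empty")
  expect_error(compute_pdp(fit, tab, "nope"), "not in table")
})

test_that("a feature the model cannot use yields a constant curve and zero gain", {
  tab <- separable_table(200)
  tab$other <- NULL
  tab$dead <- 1  # constant in training: no split can use it
  prof <- tiny_profile()
  sp <- stratified_split(tab, 0.8, seed = 1)
  hp <- list(learning_rate = 0.2, max_depth = 3, min_child_weight = 1,
             row_subsample = 1, column_subsample = 1, min_split_loss = 0)
  fit <- fit_and_evaluate(sp$train, sp$eval, hp, nrounds = 10, prof, 1)
  pdp <- compute_pdp(fit, tab, "dead", grid = seq(0, 1, length.out = 5))
  expect_equal(diff(range(pdp$pdp)), 0)
  bun <- structure(list(fits = list(list(fit = fit)), table = tab),
                   class = "model_bundle")
  vi <- variable_importance(bun)
  expect_equal(vi$summary$median_gain[vi$summary$feature == "dead"], 0)
  # the informative feature holds all the gain
  expect_equal(vi$summary$median_gain[vi$summary$feature == "temperature_mean"],
               1, tolerance = 1e-6)
})

test_that("extraction rules read constructed curves exactly", {
  curve <- function(t, v) {
    structure(data.frame(temperature = t, pdp = v,
                         scaled = suppressWarnings(scale_unit_interval(v))),
              class = c("pdp_curve", "data.frame"))
  }
  # flat to 10 degC, linear rise 10..20, plateau after
  t <- seq(0, 30, by = 1)
  v <- pmin(pmax(t - 10, 0), 10)
  cv <- curve(t, v)
  expect_equal(extract_thermal_minimum(cv, "persistent_rise"), 10)
  expect_equal(extract_thermal_minimum(cv, "steepest"), 10) # ties -> lowest T
  # logistic: steepest forward difference straddles the inflection (22.25),
  # so the unique maximal difference is over [22, 22.5]
  tl <- seq(0, 40, by = 0.5)
  cl <- curve(tl, 1 / (1 + exp(-(tl - 22.25) / 2)))
  expect_equal(extract_thermal_minimum(cl, "steepest"), 22)
  # constant curve: no rise anywhere
  cc <- curve(t, rep(0.4, length(t)))
  expect_true(is.na(extract_thermal_minimum(cc, "persistent_rise")))
  expect_true(is.na(extract_thermal_minimum(cc, "steepest")))
  # unimodal: optimum at the peak; plateau max takes the lowest temperature
  cu <- curve(t, -(t - 18)^2)
  expect_equal(extract_thermal_optimum(cu), 18)
  vp <- c(seq(0, 1, length.out = 11), rep(1, 5), seq(0.9, 0, length.out = 15))
  expect_equal(extract_thermal_optimum(curve(t, vp)), 10)
  # monotone increasing: boundary maximum -> no interior optimum
  expect_true(is.na(extract_thermal_optimum(curve(t, t))))
  expect_error(extract_thermal_minimum(curve(t[1:2], v[1:2])), "3")
})

test_that("curve scaling is affine-invariant", {
  t <- seq(0, 10, by = 0.5)
  v <- sin(t / 3) + 2
  expect_equal(scale_unit_interval(v), scale_unit_interval(3.7 * v + 11))
})

test_that("extrema summaries use defined iterations only", {
  s <- summarize_extrema(c(10, 12, 14))
  expect_equal(s$median, 12)
  expect_equal(c(s$min, s$max), c(10, 14))
  s1 <- summarize_extrema(5)
  expect_equal(s1$median, 5)
  expect_equal(s1$max - s1$min, 0)
  s2 <- summarize_extrema(c(10, NA, 14))
  expect_equal(s2$median, 12)
  expect_equal(s2$n_undefined, 1)
  s3 <- summarize_extrema(c(NA_real_, NA_real_))
  expect_true(is.na(s3$median))
  expect_match(s3$reason, "undefined")
})
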