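test_that("collinearity screen flags offending pairs and honors the boundary", {
  withr::with_seed(2, {
    x <- rnorm(1000); noise <- matrix(rnorm(4000), ncol = 4)
  })
  feats <- data.frame(a = x, b = x, n1 = noise[, 1], n2 = noise[, 2])
  sc <- screen_covariates(feats)
  expect_equal(nrow(sc$flagged), 1)
  expect_equal(abs(sc$flagged$r), 1)
  # independent noise columns never flagged at 0.8
  sc2 <- screen_covariates(as.data.frame(noise))
  expect_equal(nrow(sc2$flagged), 0)
  # boundary convention: |r| exactly at the threshold is flagged (>=)
  y <- 0.6 * x + rnorm(1000)
  r_xy <- abs(cor(x, y))
  sc3 <- screen_covariates(data.frame(x = x, y = y), threshold = r_xy)
  expect_equal(nrow(sc3$flagged), 1)
  # zero-variance feature is reported, not fatal
  sc4 <- screen_covariates(data.frame(x = x, z = rep(1, 1000)))
  expect_equal(sc4$zero_variance, "z")
})

test_that("stratified split preserves class proportions and partitions exactly", {
  tab <- data.frame(label = rep(c(1L, 0L), c(100, 200)), f = seq_len(300))
  sp <- stratified_split(tab, 0.8, seed = 3)
  expect_equal(nrow(sp$train), 240)
  expect_equal(sum(sp$train$label), 80)
  expect_equal(nrow(sp$eval), 60)
  expect_equal(sum(sp$eval$label), 20)
  expect_equal(sort(c(sp$train$f, sp$eval$f)), tab$f)        # exact partition
  expect_length(intersect(sp$train$f, sp$eval$f), 0)
  expect_identical(stratified_split(tab, 0.8, seed = 3), sp) # same seed
  expect_false(identical(stratified_split(tab, 0.8, seed = 4), sp))
  expect_error(stratified_split(data.frame(label = c(1L, 0L, 0L), f = 1:3)),
               "at least 2 rows")
})

test_that("cross-validation folds are disjoint, exhaustive and two-class", {
  labels <- rep(c(1L, 0L), c(40, 80))
  folds <- thermoniche:::stratified_folds(labels, 5, seed = 1)
  expect_equal(sort(unlist(folds)), seq_along(labels))
  expect_true(all(vapply(folds, function(ix)
    length(unique(labels[ix])) == 2, TRUE)))
})

test_that("log loss and rank AUC match their closed-form anchors", {
  y <- c(1, 0, 1, 0)
  expect_lt(thermoniche:::log_loss(y, c(1, 0, 1, 0)), 1e-12)
  expect_equal(thermoniche:::log_loss(y, rep(0.5, 4)), log(2))
  # AUC symmetry: predictions and their complement sum to 1
  withr::with_seed(4, { s <- runif(200); lab <- rbinom(200, 1, 0.4) })
  expect_equal(thermoniche:::rank_auc(s, lab) +
                 thermoniche:::rank_auc(1 - s, lab), 1)
  # independent reference implementation (pROC; fixed direction so the
  # reference is the raw statistic, not the auto-flipped one)
  ref <- as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                        direction = "<", levels = c(0, 1))))
  expect_equal(thermoniche:::rank_auc(s, lab), ref, tolerance = 1e-12)
  expect_error(thermoniche:::rank_auc(s, rep(1, 200)), "single class")
})

test_that("tuning stays in bounds, within budget, and returns the argmin", {
  tab <- separable_table(300)
  prof <- tiny_profile()
  tn <- tune_hyperparameters(tab, prof$space, seed = 2, profile = prof)
  tr <- tn$trace
  expect_lte(nrow(tr), prof$space$max_opt_rounds)
  b <- prof$space$bounds
  for (nm in names(b)) {
    expect_true(all(tr[[nm]] >= b[[nm]][1] & tr[[nm]] <= b[[nm]][2]))
  }
  expect_true(all(tr$max_depth == round(tr$max_depth)))
  expect_equal(tn$cv_logloss, min(tr$objective))
  expect_equal(unlist(tn$best), unlist(tr[which.min(tr$objective),
                                          names(b)]), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lte(tn$nrounds, prof$space$max_boost_rounds)
})

test_that("a separable table is perfectly discriminated; single-class eval fails", {
  tab <- separable_table(400)
  sp <- stratified_split(tab, 0.8, seed = 1)
  hp <- list(learning_rate = 0.3, max_depth = 3, min_child_weight = 1,
             row_subsample = 1, column_subsample = 1, min_split_loss = 0)
  fit <- fit_and_evaluate(sp$train, sp$eval, hp, nrounds = 30,
                          profile = tiny_profile(), seed = 1)
  expect_equal(fit$auc_eval, 1)
  expect_equal(fit$auc_train, 1)
  expect_true(all(diff(fit$roc_eval$tpr) >= 0))  # ROC is monotone
  bad_eval <- sp$eval; bad_eval$label <- 1L
  expect_error(fit_and_evaluate(sp$train, bad_eval, hp, 10,
                                tiny_profile(), 1), "single class")
})

test_that("bootstrap iterations carry independent splits and configured count", {
  tab <- separable_table(300)
  bun <- bootstrap_models(tab, n_iterations = 3, master_seed = 7,
                          profile = tiny_profile())
  expect_length(bun$fits, 3)
  seeds <- vapply(bun$fits, function(f) f$seed, 0)
  expect_equal(length(unique(seeds)), 3)
  tr1 <- sort(bun$fits[[1]]$split$train$temperature_mean)
  tr2 <- sort(bun$fits[[2]]$split$train$temperature_mean)
  expect_false(identical(tr1, tr2))           # different splits
  aucs <- vapply(bun$fits, function(f) f$fit$auc_eval, 0)
  expect_true(all(aucs >= 0 & aucs <= 1))
})
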