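#' Hyperparameter space for the gradient-boosted classifier
#'
#' Box bounds over six tuned hyperparameters, plus the boosting-round cap,
#' optimization budget and cross-validation fold count.
#'
#' @param learning_rate,max_depth,min_child_weight,row_subsample,
#'   column_subsample,min_split_loss length-2 `c(lower, upper)` bounds.
#' @param max_boost_rounds cap on boosting rounds per fit.
#' @param max_opt_rounds cap on Bayesian-optimization evaluations.
#' @param n_folds cross-validation folds.
#' @return list of class `hyperparameter_space`.
#' @export
hyperparameter_space <- function(learning_rate = c(1e-4, 0.3),
                                 max_depth = c(2, 50),
                                 min_child_weight = c(1, 50),
                                 row_subsample = c(0.25, 1),
                                 column_subsample = c(0.5, 1),
                                 min_split_loss = c(0, 100),
                                 max_boost_rounds = 10000L,
                                 max_opt_rounds = 24L,
                                 n_folds = 5L) {
  structure(list(
    bounds = list(learning_rate = learning_rate, max_depth = max_depth,
                  min_child_weight = min_child_weight,
                  row_subsample = row_subsample,
                  column_subsample = column_subsample,
                  min_split_loss = min_split_loss),
    integer_params = c("max_depth", "min_child_weight"),
    max_boost_rounds = as.integer(max_boost_rounds),
    max_opt_rounds = as.integer(max_opt_rounds),
    n_folds = as.integer(n_folds)
  ), class = "hyperparameter_space")
}

#' Fitting profiles
#'
#' `profile_paper()` mirrors the published study's budgets (24 optimization
#' rounds, up to 10,000 boosting rounds, 20 bootstrap iterations).
#' `profile_desk()` is the reduced, desk-scale preset used throughout the
#' package's own simulations and tests (8 optimization rounds, up to 300
#' boosting rounds, 5 bootstrap iterations, coarser histogram bins): small
#' enough to run on one CPU in minutes while leaving the recovery signal
#' intact.
#'
#' @param ... overrides for individual fields.
#' @return list of class `fit_profile` with fields `space`, `n_iterations`,
#'   `early_stopping_rounds`, `max_bin`.
#' @export
profile_paper <- function(...) {
  out <- list(space = hyperparameter_space(), n_iterations = 20L,
              early_stopping_rounds = 50L, max_bin = 256L)
  out[names(list(...))] <- list(...)
  structure(out, class = "fit_profile")
}

#' @rdname profile_paper
#' @export
profile_desk <- function(...) {
  out <- list(space = hyperparameter_space(max_boost_rounds = 300L,
                                           max_opt_rounds = 8L),
              n_iterations = 5L, early_stopping_rounds = 25L, max_bin = 64L)
  out[names(list(...))] <- list(...)
  structure(out, class = "fit_profile")
}

#' Screen covariates for collinearity
#'
#' Computes all pairwise Pearson correlations and reports the pairs at or
#' above the threshold. Advisory only: nothing is dropped automatically.
#' Zero-variance features are reported separately (their correlations are
#' undefined).
#'
#' @param features data.frame or matrix of numeric feature columns
#'   (>= 2 features, >= 3 rows).
#' @param threshold absolute-correlation threshold (flagged at `>=`).
#' @return list with `flagged` (data.frame `feature_1`, `feature_2`, `r`),
#'   `correlations` (full matrix), `zero_variance` (character).
#' @export
screen_covariates <- function(features, threshold = 0.8) {
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 2, nrow(features) >= 3)
  sds <- vapply(features, stats::sd, 0, na.rm = TRUE)
  zero_var <- names(sds)[!is.finite(sds) | sds == 0]
  cm <- suppressWarnings(stats::cor(features, use = "pairwise.complete.obs"))
  pairs <- which(upper.tri(cm), arr.ind = TRUE)
  r <- cm[pairs]
  flag <- !is.na(r) & abs(r) >= threshold
  flagged <- data.frame(feature_1 = rownames(cm)[pairs[flag, 1]],
                        feature_2 = colnames(cm)[pairs[flag, 2]],
                        r = r[flag])
  list(flagged = flagged, correlations = cm, zero_variance = zero_var)
}

#' Stratified train/evaluation split
#'
#' Random partition preserving the presence proportion: each class is split
#' `train_fraction` / remainder separately (rounded per class), so train and
#' evaluation presence proportions agree within integer rounding.
#'
#' @param table training table with a binary `label` column.
#' @param train_fraction fraction assigned to the training set.
#' @param seed RNG seed.
#' @return list with `train` and `eval` data.frames (disjoint, exhaustive).
#' @export
stratified_split <- function(table, train_fraction = 0.8, seed = 1L) {
  stopifnot(all(table$label %in% c(0L, 1L)))
  if (min(table(table$label)) < 2) {
    stop("each class needs at least 2 rows to split")
  }
  with_seed(seed, {
    idx_train <- unlist(lapply(split(seq_len(nrow(table)), table$label),
                               function(ix) {
                                 k <- round(train_fraction * length(ix))
                                 sample(ix, k)
                               }))
  })
  idx_train <- sort(idx_train)
  list(train = table[idx_train, , drop = FALSE],
       eval = table[-idx_train, , drop = FALSE])
}

# Stratified disjoint folds covering seq_len(n) exactly.
stratified_folds <- function(labels, k, seed) {
  with_seed(seed, {
    folds <- vector("list", k)
    for (cls in unique(labels)) {
      ix <- sample(which(labels == cls))
      grp <- rep(seq_len(k), length.out = length(ix))
      for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], ix[grp == f])
    }
    lapply(folds, sort)
  })
}

feature_names <- function(table) setdiff(names(table), c("label", "cell_id",
                                                         "lon", "lat"))

as_dmatrix <- function(table) {
  xgboost::xgb.DMatrix(as.matrix(table[feature_names(table)]),
                       label = table$label)
}

xgb_params <- function(hp, profile) {
  list(objective = "binary:logistic", eval_metric = "logloss",
       eta = hp$learning_rate, max_depth = hp$max_depth,
       min_child_weight = hp$min_child_weight,
       subsample = hp$row_subsample, colsample_bytree = hp$column_subsample,
       gamma = hp$min_split_loss,
       tree_method = "hist", max_bin = profile$max_bin, nthread = 1)
}

#' Tune hyperparameters by Bayesian optimization over CV log loss
#'
#' Each proposal is scored by 5-fold cross-validated out-of-fold log loss
#' with early-stopped selection of the boosting-round count; folds are
#' stratified (disjoint, covering the training table exactly). At most
#' `space$max_opt_rounds` proposals are evaluated and the argmin proposal is
#' returned together with its selected round count.
#'
#' @param train training table (`label` + features).
#' @param space a [hyperparameter_space].
#' @param seed RNG seed (folds and optimizer).
#' @param profile a `fit_profile` (early stopping, histogram bins).
#' @return list with `best` (hyperparameter list), `nrounds` (selected
#'   boosting rounds), `cv_logloss`, `trace`.
#' @export
tune_hyperparameters <- function(train, space = hyperparameter_space(),
                                 seed = 1L, profile = profile_desk()) {
  labels <- train$label
  k <- space$n_folds
  folds <- stratified_folds(labels, k, seed)
  single_class <- vapply(folds, function(ix) length(unique(labels[ix])) < 2,
                         TRUE)
  if (any(single_class)) {
    stop("could not build ", k, "-fold stratified folds with both classes; ",
         "training table too small or too imbalanced")
  }
  dtrain <- as_dmatrix(train)
  seeds <- derive_seeds(seed, 2L)

  score <- function(hp) {
    cv <- xgboost::xgb.cv(
      params = c(xgb_params(hp, profile), list(seed = seeds[1])),
      data = dtrain, nrounds = space$max_boost_rounds, folds = folds,
      early_stopping_rounds = profile$early_stopping_rounds, verbose = 0
    )
    el <- cv$evaluation_log
    best_it <- which.min(el$test_logloss_mean)
    list(objective = el$test_logloss_mean[best_it], nrounds = best_it)
  }

  opt <- bayes_optimize(score, bounds = space$bounds,
                        integer_params = space$integer_params,
                        n_rounds = space$max_opt_rounds, seed = seeds[2])
  list(best = opt$best,
       nrounds = as.integer(opt$trace$nrounds[opt$best_round]),
       cv_logloss = opt$best_objective,
       trace = opt$trace)
}

#' Fit the final model and evaluate discrimination
#'
#' Trains on the full training table (all folds) with the tuned
#' hyperparameters and round count, then computes ROC curves and rank-based
#' AUC (midrank tie handling) on both the training and evaluation sets.
#'
#' @param train,eval training and evaluation tables.
#' @param hp tuned hyperparameter list.
#' @param nrounds boosting rounds for the final fit.
#' @param profile a `fit_profile`.
#' @param seed RNG seed for the boosting backend.
#' @return list of class `sdm_fit`: `model`, `auc_train`, `auc_eval`,
#'   `roc_train`, `roc_eval`, `hp`, `nrounds`, `features`.
#' @export
fit_and_evaluate <- function(train, eval, hp, nrounds,
                             profile = profile_desk(), seed = 1L) {
  if (length(unique(eval$label)) < 2) {
    stop("evaluation set contains a single class; AUC undefined")
  }
  feats <- feature_names(train)
  model <- xgboost::xgb.train(
    params = c(xgb_params(hp, profile), list(seed = as.integer(seed))),
    data = as_dmatrix(train), nrounds = nrounds, verbose = 0
  )
  p_train <- predict(model, as.matrix(train[feats]))
  p_eval <- predict(model, as.matrix(eval[feats]))
  structure(list(model = model,
                 auc_train = rank_auc(p_train, train$label),
                 auc_eval = rank_auc(p_eval, eval$label),
                 roc_train = roc_points(p_train, train$label),
                 roc_eval = roc_points(p_eval, eval$label),
                 hp = hp, nrounds = nrounds, features = feats),
            class = "sdm_fit")
}

#' ROC curve points
#'
#' @param scores predicted probabilities.
#' @param labels binary labels.
#' @return data.frame `threshold`, `fpr`, `tpr` (thresholds descending).
#' @export
roc_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- as.integer(labels)[ord]
  n1 <- sum(lab == 1L); n0 <- sum(lab == 0L)
  tpr <- cumsum(lab == 1L) / n1
  fpr <- cumsum(lab == 0L) / n0
  keep <- !duplicated(scores[ord], fromLast = TRUE)
  data.frame(threshold = c(Inf, scores[ord][keep]),
             fpr = c(0, fpr[keep]), tpr = c(0, tpr[keep]))
}

#' Fit the model over repeated train/evaluation splits
#'
#' Repeats the full split-tune-fit cycle with independent split seeds
#' derived from a master seed, collecting everything downstream
#' interpretation needs (models, hyperparameters, AUCs, the tables).
#'
#' @param table full training table (`label` + features).
#' @param n_iterations number of bootstrap iterations (study default 20;
#'   desk profile default 5).
#' @param master_seed master RNG seed.
#' @param profile a `fit_profile`.
#' @param train_fraction passed to [stratified_split].
#' @return list of class `model_bundle`: `fits` (list of per-iteration
#'   lists), `table`, `profile`, `master_seed`.
#' @export
bootstrap_models <- function(table, n_iterations = NULL, master_seed = 1L,
                             profile = profile_desk(),
                             train_fraction = 0.8) {
  n_iterations <- as.integer(n_iterations %||% profile$n_iterations)
  stopifnot(n_iterations >= 1)
  seeds <- derive_seeds(master_seed, n_iterations)
  fits <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    res <- tryCatch({
      sp <- stratified_split(table, train_fraction, seed = seeds[it])
      tn <- tune_hyperparameters(sp$train, profile$space, seed = seeds[it],
                                 profile = profile)
      fe <- fit_and_evaluate(sp$train, sp$eval, tn$best, tn$nrounds,
                             profile = profile, seed = seeds[it])
      list(seed = seeds[it], split = sp, tuning = tn, fit = fe)
    }, error = function(e) {
      stop("bootstrap iteration ", it, " failed: ", conditionMessage(e))
    })
    fits[[it]] <- res
  }
  structure(list(fits = fits, table = table, profile = profile,
                 master_seed = master_seed),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  aucs <- vapply(x$fits, function(f) f$fit$auc_eval, 0)
  cat(sprintf("<model_bundle> %d iterations; eval AUC median %.3f (range %.3f-%.3f)\n",
              length(x$fits), stats::median(aucs), min(aucs), max(aucs)))
  invisible(x)
}
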