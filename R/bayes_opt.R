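# Compact Gaussian-process Bayesian optimizer (minimization).
#
# Surrogate: zero-mean GP with isotropic RBF kernel on inputs scaled to
# [0, 1]^d, a small noise nugget, and standardized responses. Acquisition:
# expected improvement maximized over a random candidate set. This is
# deliberately minimal -- the contract is only bounded proposals, a fixed
# evaluation budget, and argmin selection over the trace.

rbf_kernel <- function(X1, X2, lengthscale) {
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  exp(-0.5 * pmax(d2, 0) / lengthscale^2)
}

gp_fit <- function(X, y, lengthscale = 0.3, noise = 1e-2) {
  mu <- mean(y); s <- stats::sd(y); if (!is.finite(s) || s == 0) s <- 1
  yz <- (y - mu) / s
  K <- rbf_kernel(X, X, lengthscale) + diag(noise + 1e-8, nrow(X))
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), yz))
  list(X = X, L = L, alpha = alpha, mu = mu, s = s, lengthscale = lengthscale)
}

gp_predict <- function(fit, Xnew) {
  Ks <- rbf_kernel(Xnew, fit$X, fit$lengthscale)
  mean_z <- as.vector(Ks %*% fit$alpha)
  V <- forwardsolve(t(fit$L), t(Ks))
  var_z <- pmax(1 + 1e-8 - colSums(V^2), 1e-12)
  list(mean = fit$mu + fit$s * mean_z, sd = fit$s * sqrt(var_z))
}

expected_improvement <- function(mean, sd, best) {
  z <- (best - mean) / sd
  (best - mean) * stats::pnorm(z) + sd * stats::dnorm(z)
}

#' Bayesian optimization of a black-box objective
#'
#' Minimizes `fn` over a box-bounded space in at most `n_rounds`
#' evaluations: a Latin-hypercube initial design followed by
#' GP/expected-improvement proposals. Integer dimensions are rounded before
#' evaluation. Returns the argmin over the evaluation trace.
#'
#' @param fn function taking a named list of parameter values, returning a
#'   scalar objective (lower is better) or a list with `objective` plus
#'   extra fields kept in the trace.
#' @param bounds named list of `c(lower, upper)` per parameter.
#' @param integer_params names of parameters constrained to integers.
#' @param n_rounds total evaluation budget (>= 2).
#' @param n_init initial space-filling evaluations (default: a third of the
#'   budget, at least 4, capped at `n_rounds`).
#' @param n_candidates random candidate points scored per EI proposal.
#' @param seed RNG seed.
#' @return list with `best` (named parameter list), `best_objective`,
#'   `trace` (data.frame of proposals and objectives, one row per round).
#' @export
bayes_optimize <- function(fn, bounds, integer_params = character(0),
                           n_rounds = 24L, n_init = NULL,
                           n_candidates = 512L, seed = 1L) {
  stopifnot(n_rounds >= 2)
  d <- length(bounds)
  nms <- names(bounds)
  n_init <- n_init %||% min(n_rounds, max(4L, ceiling(n_rounds / 3)))
  lower <- vapply(bounds, `[`, 0, 1)
  upper <- vapply(bounds, `[`, 0, 2)

  unscale <- function(u) {
    x <- lower + u * (upper - lower)
    x[nms %in% integer_params] <- round(x[nms %in% integer_params])
    stats::setNames(as.list(x), nms)
  }

  U <- matrix(NA_real_, n_rounds, d)
  obj <- rep(NA_real_, n_rounds)
  extras <- vector("list", n_rounds)

  with_seed(seed, {
    U[seq_len(n_init), ] <- lhs::randomLHS(n_init, d)
    for (r in seq_len(n_rounds)) {
      if (r > n_init) {
        fit <- gp_fit(U[seq_len(r - 1), , drop = FALSE], obj[seq_len(r - 1)])
        cand <- matrix(runif(n_candidates * d), n_candidates, d)
        pr <- gp_predict(fit, cand)
        ei <- expected_improvement(pr$mean, pr$sd, min(obj, na.rm = TRUE))
        U[r, ] <- cand[which.max(ei), ]
      }
      res <- fn(unscale(U[r, ]))
      if (is.list(res)) {
        obj[r] <- res$objective
        extras[[r]] <- res[setdiff(names(res), "objective")]
      } else {
        obj[r] <- res
      }
    }
  })

  params_mat <- t(apply(U, 1, function(u) unlist(unscale(u))))
  trace <- data.frame(round = seq_len(n_rounds), params_mat,
                      objective = obj)
  extra_nms <- unique(unlist(lapply(extras, names)))
  for (nm in extra_nms) {
    trace[[nm]] <- vapply(extras, function(e) e[[nm]] %||% NA_real_, 0)
  }
  ibest <- which.min(obj)
  list(best = unscale(U[ibest, ]), best_objective = obj[ibest],
       best_round = ibest, trace = trace)
}
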