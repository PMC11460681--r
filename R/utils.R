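# Internal helpers shared across modules.

# Scoped RNG: every generator is a pure function of (args, seed).
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

# Derive a stream of child seeds from a master seed (kept < 2^31).
derive_seeds <- function(master_seed, n) {
  with_seed(master_seed, sample.int(.Machine$integer.max - 1L, n))
}

km_per_deg_lat <- 110.574

km_per_deg_lon <- function(lat) 111.320 * cos(lat * pi / 180)

# Equirectangular planar distance in km, scaled at a reference latitude.
# Adequate at the desk-scale extents this package works over.
equirect_dist_km <- function(lon1, lat1, lon2, lat2, ref_lat = lat1) {
  dx <- (lon2 - lon1) * km_per_deg_lon(ref_lat)
  dy <- (lat2 - lat1) * km_per_deg_lat
  sqrt(dx^2 + dy^2)
}

# Smooth random field on an n_rows x n_cols grid: a short random cosine
# series over normalized coordinates. Deterministic under the caller's RNG.
smooth_field <- function(n_rows, n_cols, n_modes = 6L) {
  u <- (seq_len(n_cols) - 0.5) / n_cols
  v <- (seq_len(n_rows) - 0.5) / n_rows
  f <- matrix(0, n_rows, n_cols)
  for (k in seq_len(n_modes)) {
    fx <- runif(1, 0.5, 3); fy <- runif(1, 0.5, 3)
    px <- runif(1, 0, 2 * pi); py <- runif(1, 0, 2 * pi)
    amp <- rnorm(1, 0, 1 / k)
    f <- f + amp * outer(cos(2 * pi * fy * v + py), cos(2 * pi * fx * u + px))
  }
  f
}

# z-standardize a vector, guarding constants.
zstd <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

log_loss <- function(y, p, eps = 1e-15) {
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# Mann-Whitney rank AUC with midrank tie handling.
rank_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: evaluation set contains a single class")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
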