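# Shared fixtures and independent oracles.
#
# The oracles deliberately avoid the package's own fitting path: least
# squares through qr.solve on the explicitly shifted series, with the AIC
# and adjusted-R2 formulas written out inline.

# A small uniform-grid matrix from explicit row vectors.
tiny_mat <- function(..., spacing = 1, scale = "log2_ratio") {
  rows <- list(...)
  v <- do.call(rbind, rows)
  rownames(v) <- names(rows)
  interp_matrix(v, (seq_len(ncol(v)) - 1) * spacing, scale = scale)
}

# Smooth, mutually distinct test curves (mixed-frequency sinusoids).
test_curves <- function(n_reg, n_grid, seed, freqs = NULL) {
  set.seed(seed)
  t <- seq_len(n_grid) - 1
  v <- t(sapply(seq_len(n_reg), function(i) {
    f1 <- if (is.null(freqs)) runif(1, 0.5, 2.5) else freqs[i]
    sin(2 * pi * f1 * t / n_grid + runif(1, 0, 2 * pi)) +
      0.5 * sin(2 * pi * runif(1, 2.5, 5) * t / n_grid + runif(1, 0, 2 * pi))
  }))
  rownames(v) <- sprintf("R%02d", seq_len(n_reg))
  interp_matrix(v, t, scale = "log2_ratio")
}

# Independent delay shift by direct index arithmetic (0-based window_start).
oracle_shift <- function(series, d, window_start, n_grid) {
  series[(window_start - d + 1):(n_grid - d)]
}

# Independent OLS + information criteria via QR on the full design.
oracle_ols <- function(y, X) {
  Xf <- cbind(1, X)
  co <- qr.solve(Xf, y)
  rss <- sum((y - Xf %*% co)^2)
  n <- length(y)
  k <- ncol(Xf) + 1  # regressors + intercept + residual variance
  n_r <- ncol(Xf) - 1
  r2 <- 1 - rss / sum((y - mean(y))^2)
  list(coef = as.numeric(co), rss = rss,
       aic = n * log(max(rss, n * 1e-12) / n) + 2 * k,
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - n_r - 1))
}

# AIC of a given (subset, delay tuple) computed entirely by the oracles.
oracle_model_aic <- function(mat, target, regs, delays, window_start) {
  ng <- mat$n_grid
  y <- oracle_shift(mat$values[target, ], 0, window_start, ng)
  X <- sapply(seq_along(regs), function(j)
    oracle_shift(mat$values[regs[j], ], delays[j], window_start, ng))
  oracle_ols(y, as.matrix(X))$aic
}

# Exhaustive enumeration over all non-empty regulator subsets x delay
# tuples; returns the overall optimum and a per-subset AIC lookup.
oracle_exhaustive <- function(mat, target, candidates, max_delay,
                              window_start = max_delay) {
  best <- NULL
  subset_best <- list()
  for (m in seq_along(candidates)) {
    for (subset in utils::combn(candidates, m, simplify = FALSE)) {
      tuples <- do.call(expand.grid, rep(list(0:max_delay), m))
      sb <- Inf
      for (r in seq_len(nrow(tuples))) {
        aic <- oracle_model_aic(mat, target, subset,
                                as.integer(tuples[r, ]), window_start)
        sb <- min(sb, aic)
        if (is.null(best) || aic < best$aic)
          best <- list(regs = subset, delays = as.integer(tuples[r, ]),
                       aic = aic)
      }
      subset_best[[paste(sort(subset), collapse = "|")]] <- sb
    }
  }
  list(best = best, subset_best = subset_best)
}

# Benchmark cache: the standard noiseless / noisy benchmarks and their
# fitted networks are reused across test files.
bench_cache <- new.env(parent = emptyenv())

cached_benchmark_run <- function(noise_sd, seed = 1L) {
  key <- sprintf("b_%g_%d", noise_sd, seed)
  if (is.null(bench_cache[[key]])) {
    b <- make_benchmark(benchmark_spec(noise_sd = noise_sd, seed = seed))
    models <- fit_all_targets(b$data, b$targets, b$regulators)
    bench_cache[[key]] <- list(bench = b, models = models,
                               edges = build_network(models))
  }
  bench_cache[[key]]
}
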