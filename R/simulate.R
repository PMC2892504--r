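# Synthetic time-course benchmarks with known delayed-linear regulatory
# structure.
#
# The generator emulates the situation the method is built for: a cohort of
# co-oscillating regulators (a cell-cycle-like shared oscillation plus
# gene-specific harmonics), and targets that are noisy delayed linear
# combinations of a few regulators.  Every emitted target lies inside the
# method's operating regime -- each of its true regulators, alone and at
# its best delay, explains the noiseless target to at least the single-
# regulator screening cutoff -- mirroring the strong marginal co-expression
# of real cell-cycle genes.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards. `seed = NULL` uses the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Benchmark specification
#'
#' Defaults describe the standard benchmark used throughout the test
#' suite: 10 regulators and 20 targets on a 100-point grid, one to three
#' regulators per target with coefficient magnitudes in `[0.3, 2]` and
#' delays of 0--5 grid steps, and Gaussian observation noise of standard
#' deviation 0.1 on a signal range of roughly `[-3, 3]`.
#'
#' @param n_regulators,n_targets Number of regulator and target genes.
#' @param n_grid,grid_spacing Grid size and spacing (minutes).
#' @param edges_per_target Vector of admissible per-target regulator
#'   counts; sampled uniformly. Default `1:3`.
#' @param coef_range Magnitude range for regulation coefficients (signs
#'   are random). Default `c(0.3, 2)`.
#' @param delay_range Inclusive integer range of true delays in grid
#'   steps; a target's delays are drawn without replacement (kept
#'   mutually distinct, which aids identifiability) whenever the range
#'   allows it. Default `c(0, 5)`.
#' @param noise_sd Standard deviation of additive Gaussian noise on
#'   targets. Default 0.1.
#' @param intercept_range Range of target intercepts. Default
#'   `c(-0.5, 0.5)`.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_regulators = 10, n_targets = 20,
                           n_grid = 100, grid_spacing = 2,
                           edges_per_target = 1:3,
                           coef_range = c(0.3, 2),
                           delay_range = c(0L, 5L),
                           noise_sd = 0.1,
                           intercept_range = c(-0.5, 0.5),
                           seed = 1L) {
  stopifnot(n_regulators >= 1, n_targets >= 0, n_grid >= 8,
            grid_spacing > 0, noise_sd >= 0,
            all(edges_per_target >= 1),
            max(edges_per_target) <= n_regulators,
            delay_range[1] >= 0, delay_range[2] < n_grid / 2)
  structure(list(n_regulators = n_regulators, n_targets = n_targets,
                 n_grid = n_grid, grid_spacing = grid_spacing,
                 edges_per_target = edges_per_target,
                 coef_range = coef_range,
                 delay_range = as.integer(delay_range),
                 noise_sd = noise_sd,
                 intercept_range = intercept_range,
                 seed = as.integer(seed)),
            class = "benchmark_spec")
}

# Regulator curves, drawn on the current RNG stream.  Each curve is a
# shared-period oscillation (two full cycles over the span, in phase
# across genes -- the co-expression backbone that makes single-regulator
# screening informative, as in synchronised cell-cycle data) plus 2-3
# gene-specific harmonics and a low-amplitude smooth spline noise
# component, rescaled into a log-ratio-like range when a curve exceeds
# [-3, 3].  The harmonic amplitudes are large enough, relative to the
# backbone, that each regulator carries an individual temporal signature
# from which its delay is identifiable.
regulator_curves_impl <- function(n_reg, n_grid, grid_spacing) {
  times <- (seq_len(n_grid) - 1) * grid_spacing
  span <- times[n_grid]
  p0 <- span / 2
  v <- matrix(0, n_reg, n_grid)
  for (i in seq_len(n_reg)) {
    amp0 <- stats::runif(1, 1.3, 1.6)
    y <- amp0 * sin(2 * pi * times / p0)
    for (k in seq_len(sample(2:3, 1))) {
      per <- stats::runif(1, span / 14, span / 4)
      amp <- stats::runif(1, 0.5, 0.8)
      y <- y + amp * sin(2 * pi * times / per + stats::runif(1, 0, 2 * pi))
    }
    knots <- seq(0, span, length.out = 12)
    y <- y + stats::spline(knots, stats::rnorm(12, 0, 0.05),
                           xout = times, method = "natural")$y
    if (max(abs(y)) > 3) y <- y * 3 / max(abs(y))
    v[i, ] <- y
  }
  rownames(v) <- sprintf("REG%02d", seq_len(n_reg))
  interp_matrix(v, times, scale = "log2_ratio")
}

#' Generate smooth periodic regulator trajectories on a uniform grid
#'
#' @param n_reg Number of regulator curves (at least 1).
#' @param n_grid Grid length (at least 8).
#' @param grid_spacing Minutes between grid points.
#' @param seed Integer seed; the caller's RNG stream is untouched.
#' @return An [interp_matrix] of `n_reg` curves named `REG01`, `REG02`, ...
#' @export
generate_regulator_curves <- function(n_reg, n_grid = 100, grid_spacing = 2,
                                      seed = 1L) {
  stopifnot(n_reg >= 1, n_grid >= 8)
  with_seed(seed, regulator_curves_impl(n_reg, n_grid, grid_spacing))
}

# Delayed series of one regulator over the full grid: exact at in-range
# grid points, linearly back-extrapolated (natural spline) before the
# grid start so the matrix stays rectangular.
delayed_series <- function(mat, regulator, delay_steps) {
  v <- mat$values[regulator, ]
  stats::spline(mat$time_points, v,
                xout = mat$time_points - delay_steps * mat$grid_spacing,
                method = "natural")$y
}

#' Generate a target series from known truth edges
#'
#' `target(t) = intercept + sum coefficient * regulator(t - delay) +
#' N(0, noise_sd)`. At grid points before the largest delay the shifted
#' regulator values are back-extrapolated from its natural spline so the
#' series covers the whole grid; model fits never use that initial
#' stretch (the fitting window starts at the maximum delay).
#'
#' @param regulators An [interp_matrix] of regulator curves.
#' @param edges `data.frame` with columns `regulator`, `coefficient`,
#'   `delay_steps`; may be empty (intercept plus noise only). Delays must
#'   be below `n_grid / 2`.
#' @param intercept Scalar intercept.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Integer seed, or `NULL` to draw from the current stream.
#' @return Numeric vector of length `n_grid`.
#' @export
generate_target_from_truth <- function(regulators, edges, intercept = 0,
                                       noise_sd = 0, seed = NULL) {
  stopifnot(inherits(regulators, "interp_matrix"))
  if (nrow(edges) && any(edges$delay_steps >= regulators$n_grid / 2))
    stop("delays must be smaller than half the grid length")
  with_seed(seed, {
    y <- rep(intercept, regulators$n_grid)
    for (j in seq_len(nrow(edges)))
      y <- y + edges$coefficient[j] *
        delayed_series(regulators, edges$regulator[j], edges$delay_steps[j])
    y + stats::rnorm(regulators$n_grid, 0, noise_sd)
  })
}

# Is this noiseless target marginally identifiable?  Two conditions, both
# properties of the data alone: every true regulator, fitted singly at its
# best delay, (a) clears the single-regulator screening cutoff -- otherwise
# step 1 of the procedure would rightly filter it -- and (b) attains that
# best fit at its generating delay, so the marginal delay signal agrees
# with the truth.  Targets failing either are outside the operating regime
# the benchmark emulates and are redrawn.
target_in_regime <- function(regs, y_clean, edges, max_delay_steps, cutoff) {
  tmp <- interp_matrix(rbind(regs$values, ".tgt" = y_clean),
                       regs$time_points, regs$scale)
  for (j in seq_len(nrow(edges))) {
    sc <- scan_single_regulator(tmp, ".tgt", edges$regulator[j],
                                max_delay_steps)
    if (is.na(sc$fit$adj_r2) || sc$fit$adj_r2 < cutoff) return(FALSE)
    if (sc$assignment$delay_steps != edges$delay_steps[j]) return(FALSE)
  }
  TRUE
}

#' Generate a complete benchmark: expression matrix plus truth network
#'
#' Draws regulator curves, then for each target a random edge set --
#' distinct regulators with signed coefficients and mutually distinct grid
#' delays -- and the corresponding noisy series. Edge sets are redrawn
#' (deterministically, on the same seeded stream) until the noiseless
#' target is marginally identifiable: every true regulator, fitted singly,
#' reaches `regime_cutoff` adjusted R2 at a best delay equal to its
#' generating delay. After `attempts_per_k` failed draws the regulator
#' count is reduced by one and the search repeats; a single-regulator
#' target always satisfies the constraint.
#'
#' @param spec A [benchmark_spec()].
#' @param regime_cutoff Screening cutoff used for the operating-regime
#'   constraint. Default 0.8, the screening default.
#' @param attempts_per_k Edge-set draws attempted at each regulator count
#'   before relaxing it. Default 20.
#' @param dir Optional directory; when given, writes `expression.tsv`
#'   (matrix), `truth_edges.tsv`, `regulators.txt` and `targets.txt`.
#' @return A list of class `benchmark` with `data` (an [interp_matrix] of
#'   regulators and targets), `truth` (`data.frame` with `regulator`,
#'   `target`, `coefficient`, `delay_steps`), `regulators`, `targets`,
#'   `spec`.
#' @export
make_benchmark <- function(spec = benchmark_spec(), regime_cutoff = 0.8,
                           attempts_per_k = 20, dir = NULL) {
  stopifnot(inherits(spec, "benchmark_spec"))
  maxd_fit <- floor(0.1 * spec$n_grid)
  with_seed(spec$seed, {
    regs <- regulator_curves_impl(spec$n_regulators, spec$n_grid,
                                  spec$grid_spacing)
    truth <- list()
    tvals <- matrix(0, spec$n_targets, spec$n_grid)
    tnames <- sprintf("TGT%02d", seq_len(spec$n_targets))
    delays <- spec$delay_range[1]:spec$delay_range[2]
    for (i in seq_len(spec$n_targets)) {
      k0 <- spec$edges_per_target[sample.int(length(spec$edges_per_target), 1)]
      found <- FALSE
      for (k in seq(k0, 1L)) {  # relax regulator count downward if needed
        for (attempt in seq_len(attempts_per_k)) {
          e <- data.frame(
            regulator = sample(gene_ids(regs), k),
            coefficient = sample(c(-1, 1), k, replace = TRUE) *
              stats::runif(k, spec$coef_range[1], spec$coef_range[2]),
            delay_steps = as.integer(
              delays[sample.int(length(delays), k,
                                replace = length(delays) < k)]),
            stringsAsFactors = FALSE)
          y_clean <- generate_target_from_truth(regs, e, intercept = 0,
                                                noise_sd = 0)
          if (target_in_regime(regs, y_clean, e, maxd_fit, regime_cutoff)) {
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      intercept <- stats::runif(1, spec$intercept_range[1],
                                spec$intercept_range[2])
      tvals[i, ] <- y_clean + intercept +
        stats::rnorm(spec$n_grid, 0, spec$noise_sd)
      e$target <- tnames[i]
      truth[[i]] <- e
    }
    rownames(tvals) <- tnames
    truth <- if (length(truth)) do.call(rbind, truth) else
      data.frame(regulator = character(), coefficient = numeric(),
                 delay_steps = integer(), target = character())
    truth <- truth[c("regulator", "target", "coefficient", "delay_steps")]
    rownames(truth) <- NULL
    bench <- structure(list(
      data = interp_matrix(rbind(regs$values, tvals), regs$time_points,
                           regs$scale),
      truth = truth,
      regulators = gene_ids(regs),
      targets = tnames,
      spec = spec
    ), class = "benchmark")
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      write_expr_matrix(bench$data, file.path(dir, "expression.tsv"))
      utils::write.table(truth, file.path(dir, "truth_edges.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      writeLines(bench$regulators, file.path(dir, "regulators.txt"))
      writeLines(bench$targets, file.path(dir, "targets.txt"))
    }
    bench
  })
}

#' @export
print.benchmark <- function(x, ...) {
  cat(sprintf("<benchmark> %d regulators, %d targets, %d grid points, noise sd %g, %d truth edges\n",
              length(x$regulators), length(x$targets), x$data$n_grid,
              x$spec$noise_sd, nrow(x$truth)))
  invisible(x)
}

#' Score a predicted network against a truth edge list
#'
#' Edges match on the (regulator, target) pair; delay agreement is
#' reported separately for the matched pairs.
#'
#' @param edges Predicted edge table ([build_network()] layout).
#' @param truth Truth edges (`regulator`, `target`, `coefficient`,
#'   `delay_steps`).
#' @param grid_spacing Minutes per grid step, used to convert predicted
#'   delays back to steps.
#' @return A list with `precision`, `recall`, `n_pred`, `n_true`,
#'   `n_matched`, `delay_within_1` (fraction of matched edges whose
#'   predicted delay is within one grid step of truth), and
#'   `max_coef_error` over matched edges.
#' @export
benchmark_scores <- function(edges, truth, grid_spacing) {
  key <- function(d) paste(d$regulator, d$target, sep = "\r")
  pk <- key(edges); tk <- key(truth)
  matched <- intersect(pk, tk)
  pm <- edges[match(matched, pk), , drop = FALSE]
  tm <- truth[match(matched, tk), , drop = FALSE]
  pred_steps <- pm$delay / grid_spacing
  list(
    precision = if (nrow(edges)) length(matched) / nrow(edges) else NA_real_,
    recall = if (nrow(truth)) length(matched) / nrow(truth) else NA_real_,
    n_pred = nrow(edges), n_true = nrow(truth), n_matched = length(matched),
    delay_within_1 = if (length(matched))
      mean(abs(pred_steps - tm$delay_steps) <= 1 + 1e-9) else NA_real_,
    max_coef_error = if (length(matched))
      max(abs(pm$coefficient - tm$coefficient)) else NA_real_
  )
}
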