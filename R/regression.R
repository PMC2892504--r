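# The time-delay linear model.
#
# A target y is modelled as
#   y(t) = b0 + sum_i a_i * x_i(t - d_i * h) + e(t)
# on a uniform grid with spacing h, where each regulator x_i acts with its
# own integer-step delay d_i and signed coefficient a_i (positive =
# activation, negative = repression).  Fits are ordinary least squares on a
# fixed window of the grid so that AICs are comparable across delays and
# regulator sets.

RSS_FLOOR_PER_OBS <- 1e-12

#' Delay assignments
#'
#' A delay assignment pairs a regulator with a non-negative delay measured
#' in grid steps. Throughout the package, a set of assignments is a
#' `data.frame` with columns `regulator` (character) and `delay_steps`
#' (non-negative integer).
#'
#' @param regulator Character vector of regulator identifiers.
#' @param delay_steps Integer vector of delays in grid steps (recycled).
#' @return A `data.frame` with columns `regulator`, `delay_steps`.
#' @export
delay_assignments <- function(regulator = character(),
                              delay_steps = integer()) {
  d <- data.frame(regulator = as.character(regulator),
                  delay_steps = as.integer(delay_steps),
                  stringsAsFactors = FALSE)
  if (nrow(d) && any(d$delay_steps < 0)) stop("delays must be non-negative")
  d
}

#' Build the delay-aligned design for one target
#'
#' The response is the target's values at grid indices
#' `window_start .. n_grid - 1` (0-based); the regressor column for a
#' regulator with delay `d` is that regulator's values at indices
#' `window_start - d .. n_grid - 1 - d`. A fixed `window_start` (at least
#' the largest delay in use) keeps the sample size identical for every
#' delay, so information criteria are comparable.
#'
#' @param mat An [interp_matrix].
#' @param target_id Target gene identifier (row of `mat`).
#' @param assignments A [delay_assignments()] data frame (possibly empty).
#' @param window_start Integer, 0-based index of the first modelled grid
#'   column; must be at least `max(delay_steps)` and less than `n_grid`.
#' @return A list with `y` (response vector), `X` (regressor matrix, one
#'   column per assignment, columns named by regulator), and `n`.
#' @export
shift_align <- function(mat, target_id, assignments, window_start) {
  stopifnot(inherits(mat, "interp_matrix"))
  window_start <- as.integer(window_start)
  ng <- mat$n_grid
  if (window_start < 0 || window_start >= ng)
    stop("window_start must be in [0, n_grid - 1]")
  ids <- c(target_id, assignments$regulator)
  missing <- setdiff(ids, gene_ids(mat))
  if (length(missing))
    stop("gene(s) not in matrix: ", paste(missing, collapse = ", "))
  if (nrow(assignments) && any(assignments$delay_steps > window_start))
    stop("delay exceeds window_start (", window_start, ")")
  rows <- seq.int(window_start + 1L, ng)
  y <- mat$values[target_id, rows]
  X <- matrix(0, length(rows), nrow(assignments))
  if (nrow(assignments)) {
    for (j in seq_len(nrow(assignments))) {
      d <- assignments$delay_steps[j]
      X[, j] <- mat$values[assignments$regulator[j], rows - d]
    }
    colnames(X) <- assignments$regulator
  }
  list(y = unname(y), X = X, n = length(rows))
}

#' Akaike information criterion for a Gaussian least-squares fit
#'
#' Uses the profile form `n * log(RSS / n) + 2 * k_params` with additive
#' constants dropped; all comparisons within one target use the same `n`,
#' so any affine-equivalent variant selects identically. A saturated fit
#' (`RSS <= 0`) has its RSS floored at `n * 1e-12` so the criterion stays
#' finite and the perfect model still wins every comparison.
#'
#' @param rss Residual sum of squares.
#' @param n Sample size.
#' @param k_params Number of estimated parameters (regulators + intercept +
#'   residual variance).
#' @return The AIC value (numeric scalar).
#' @export
compute_aic <- function(rss, n, k_params) {
  stopifnot(n > 0, k_params >= 1)
  if (rss <= n * RSS_FLOOR_PER_OBS) rss <- n * RSS_FLOOR_PER_OBS
  n * log(rss / n) + 2 * k_params
}

#' Adjusted coefficient of determination
#'
#' `1 - (1 - r2) * (k_s - 1) / (k_s - n_r - 1)`, penalising R-squared for
#' the number of explanatory terms. Undefined when `k_s <= n_r + 1`;
#' returns `NA`, which fails any cutoff comparison.
#'
#' @param r2 R-squared in `[0, 1]`.
#' @param k_s Sample size.
#' @param n_r Number of regulators in the model.
#' @return Adjusted R-squared, or `NA_real_` when not computable.
#' @export
compute_adj_r2 <- function(r2, k_s, n_r) {
  if (k_s <= n_r + 1) return(NA_real_)
  1 - (1 - r2) * (k_s - 1) / (k_s - n_r - 1)
}

#' Fit the time-delay linear model for a fixed set of delay assignments
#'
#' Ordinary least squares of the delay-aligned target on the delay-aligned
#' regulators plus an intercept. Rank-deficient designs (a regulator
#' duplicated at the same delay, a constant column) have the aliased
#' columns dropped with a warning.
#'
#' @inheritParams shift_align
#' @return An object of class `delay_fit`: a list with `target_id`,
#'   `assignments` (the columns actually retained), `intercept`,
#'   `coefficients` (named by regulator), `rss`, `n`, `k_params`
#'   (regulators + 2), `aic`, `r2`, `adj_r2`, `saturated`, `dropped`
#'   (identifiers of aliased regulators, if any).
#' @export
fit_delay_model <- function(mat, target_id, assignments, window_start) {
  al <- shift_align(mat, target_id, assignments, window_start)
  Xf <- cbind(`(Intercept)` = 1, al$X)
  fit <- stats::lm.fit(Xf, al$y)
  coefs <- fit$coefficients
  dropped <- character(0)
  if (anyNA(coefs)) {
    aliased <- which(is.na(coefs)) - 1L  # regressor positions, intercept is 1
    dropped <- assignments$regulator[aliased]
    warning("rank-deficient design for target '", target_id,
            "'; dropping: ", paste(dropped, collapse = ", "))
    assignments <- assignments[-aliased, , drop = FALSE]
    coefs <- coefs[!is.na(coefs)]
  }
  res <- al$y - Xf[, names(coefs), drop = FALSE] %*% coefs
  rss <- sum(res^2)
  tss <- sum((al$y - mean(al$y))^2)
  r2 <- if (tss > 0) max(0, min(1, 1 - rss / tss)) else 0
  n_r <- nrow(assignments)
  k_params <- n_r + 2L
  structure(list(
    target_id = target_id,
    assignments = assignments,
    intercept = unname(coefs[1]),
    coefficients = stats::setNames(as.numeric(coefs[-1]),
                                   assignments$regulator),
    rss = rss, n = al$n, k_params = k_params,
    aic = compute_aic(rss, al$n, k_params),
    r2 = r2,
    adj_r2 = compute_adj_r2(r2, al$n, n_r),
    saturated = rss <= al$n * RSS_FLOOR_PER_OBS,
    dropped = dropped
  ), class = "delay_fit")
}

#' @export
print.delay_fit <- function(x, ...) {
  cat(sprintf("<delay_fit> target %s: %d regulator(s), AIC %.4f, adj.R2 %s\n",
              x$target_id, nrow(x$assignments), x$aic,
              ifelse(is.na(x$adj_r2), "NA", sprintf("%.6f", x$adj_r2))))
  if (nrow(x$assignments))
    print(cbind(x$assignments, coefficient = unname(x$coefficients)))
  invisible(x)
}

#' Find the best delay for a single regulator
#'
#' Fits one single-regulator model per delay in `0 .. max_delay_steps` and
#' returns the delay minimising AIC (ties broken toward the smaller delay,
#' i.e. toward the simpler temporal explanation).
#'
#' @inheritParams shift_align
#' @param regulator_id Candidate regulator (must differ from the target).
#' @param max_delay_steps Largest delay to consider, in grid steps.
#' @param window_start Fixed window start; defaults to `max_delay_steps` so
#'   every delay is fitted on the same sample.
#' @return A list with `assignment` (one-row [delay_assignments()] frame)
#'   and `fit` (the winning [fit_delay_model()] result).
#' @export
scan_single_regulator <- function(mat, target_id, regulator_id,
                                  max_delay_steps,
                                  window_start = max_delay_steps) {
  if (identical(regulator_id, target_id))
    stop("regulator and target are the same gene: ", target_id)
  if (max_delay_steps > window_start)
    stop("max_delay_steps must not exceed window_start")
  best <- NULL
  for (d in 0:max_delay_steps) {
    f <- fit_delay_model(mat, target_id,
                         delay_assignments(regulator_id, d), window_start)
    if (is.null(best) || f$aic < best$fit$aic)
      best <- list(assignment = delay_assignments(regulator_id, d), fit = f)
  }
  best
}
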