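# The two-step model-selection procedure.
#
# Step 1 screens every candidate regulator by its best single-regulator,
# best-delay fit: candidates whose adjusted R2 misses the single-regulator
# cutoff are considered irrelevant to the target and dropped, survivors are
# ranked by their smallest AIC.  Step 2 forward-selects regulators in rank
# order, traversing all delays for each new candidate while holding the
# delays of the already-selected set fixed, accepting an addition only when
# it strictly lowers the AIC.  The final model is kept only if its adjusted
# R2 clears the multiple-regression cutoff and every coefficient magnitude
# lies inside the configured bounds.

#' Selection parameters
#'
#' Defaults reproduce the published operating point: single-regulator
#' screening cutoff 0.8, final-model cutoff 0.9, maximum delay one tenth of
#' the interpolated grid, and coefficient magnitudes confined to
#' `[0.25, 4]`.
#'
#' @param single_adj_r2 Adjusted-R2 cutoff a candidate's best single-
#'   regulator fit must reach to enter the ranking. Default 0.8.
#' @param multiple_adj_r2 Adjusted-R2 cutoff the final multi-regulator
#'   model must reach to be reported. Default 0.9.
#' @param max_delay_steps Largest delay considered, in grid steps. `NULL`
#'   (default) resolves to `floor(0.1 * n_grid)` at fit time.
#' @param min_coef,max_coef Bounds on coefficient magnitude; regulators
#'   with fitted `|coefficient|` outside `[min_coef, max_coef]` are removed
#'   and the model refitted. Defaults 0.25 and 4.
#' @param restart_prefixes If `TRUE`, rerun the forward pass seeded with
#'   every prefix of the ranking (not just the top regulator) and keep the
#'   lowest-AIC result. Default `FALSE` (single pass).
#' @param bounds_during_selection If `TRUE`, also reject a candidate during
#'   forward selection when its own fitted coefficient falls outside the
#'   bounds, instead of only pruning after selection. Default `FALSE`.
#' @return A list of class `selection_params`.
#' @export
selection_params <- function(single_adj_r2 = 0.8,
                             multiple_adj_r2 = 0.9,
                             max_delay_steps = NULL,
                             min_coef = 0.25,
                             max_coef = 4,
                             restart_prefixes = FALSE,
                             bounds_during_selection = FALSE) {
  stopifnot(single_adj_r2 > 0, single_adj_r2 <= 1,
            multiple_adj_r2 > 0, multiple_adj_r2 <= 1,
            min_coef >= 0, min_coef < max_coef)
  if (!is.null(max_delay_steps)) stopifnot(max_delay_steps >= 0)
  structure(list(single_adj_r2 = single_adj_r2,
                 multiple_adj_r2 = multiple_adj_r2,
                 max_delay_steps = max_delay_steps,
                 min_coef = min_coef, max_coef = max_coef,
                 restart_prefixes = restart_prefixes,
                 bounds_during_selection = bounds_during_selection),
            class = "selection_params")
}

resolve_max_delay <- function(params, mat) {
  if (!is.null(params$max_delay_steps)) as.integer(params$max_delay_steps)
  else as.integer(floor(0.1 * mat$n_grid))
}

#' Screen and rank candidate regulators for one target
#'
#' For each candidate (the target itself is silently excluded), traverses
#' all delays and keeps the best single-regulator fit; candidates whose
#' best fit misses the single-regulator adjusted-R2 cutoff are filtered
#' out. Survivors are sorted by AIC ascending (stable on ties).
#'
#' @inheritParams shift_align
#' @param candidates Character vector of candidate regulator identifiers.
#' @param params A [selection_params()] object.
#' @param window_start Fixed fitting window; defaults to the resolved
#'   maximum delay.
#' @return An object of class `regulator_ranking`: list with `target_id`
#'   and `entries`, a data frame with columns `regulator`, `delay_steps`,
#'   `aic`, `adj_r2` sorted by `aic`.
#' @export
screen_and_rank <- function(mat, target_id, candidates, params = selection_params(),
                            window_start = NULL) {
  maxd <- resolve_max_delay(params, mat)
  if (is.null(window_start)) window_start <- maxd
  candidates <- setdiff(candidates, target_id)
  rows <- lapply(candidates, function(reg) {
    sc <- scan_single_regulator(mat, target_id, reg, maxd, window_start)
    data.frame(regulator = reg,
               delay_steps = sc$assignment$delay_steps,
               aic = sc$fit$aic, adj_r2 = sc$fit$adj_r2,
               stringsAsFactors = FALSE)
  })
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regulator = character(), delay_steps = integer(),
               aic = numeric(), adj_r2 = numeric())
  keep <- !is.na(entries$adj_r2) & entries$adj_r2 >= params$single_adj_r2
  entries <- entries[keep, , drop = FALSE]
  entries <- entries[order(entries$aic), , drop = FALSE]  # stable sort
  rownames(entries) <- NULL
  structure(list(target_id = target_id, entries = entries,
                 window_start = window_start, max_delay_steps = maxd),
            class = "regulator_ranking")
}

#' @export
print.regulator_ranking <- function(x, ...) {
  cat(sprintf("<regulator_ranking> target %s: %d candidate(s) pass screening\n",
              x$target_id, nrow(x$entries)))
  if (nrow(x$entries)) print(x$entries)
  invisible(x)
}

# One forward pass from a given seed assignment set. Candidates are tested
# in ranking order; for each, all delays are traversed with the current
# set's delays frozen, and the candidate joins only if its best addition
# strictly lowers the AIC. Additions that alias an existing column are
# discarded.
forward_pass <- function(mat, target_id, seed_assign, rest, params,
                         window_start, maxd, log) {
  cur <- fit_delay_model(mat, target_id, seed_assign, window_start)
  assign <- seed_assign
  for (i in seq_len(nrow(rest))) {
    reg <- rest$regulator[i]
    best <- NULL
    for (d in 0:maxd) {
      trial <- rbind(assign, delay_assignments(reg, d))
      f <- withCallingHandlers(
        fit_delay_model(mat, target_id, trial, window_start),
        warning = function(w) invokeRestart("muffleWarning"))
      if (reg %in% f$dropped) next  # aliased with the current set at this delay
      if (is.null(best) || f$aic < best$fit$aic)
        best <- list(d = d, fit = f)
    }
    if (is.null(best)) {
      log(sprintf("candidate %s discarded: rank-deficient at every delay", reg))
      next
    }
    in_bounds <- TRUE
    if (params$bounds_during_selection) {
      co <- abs(best$fit$coefficients[reg])
      in_bounds <- co >= params$min_coef && co <= params$max_coef
    }
    if (best$fit$aic < cur$aic && in_bounds) {
      assign <- rbind(assign, delay_assignments(reg, best$d))
      cur <- best$fit
    }
  }
  list(assignments = assign, fit = cur)
}

#' Forward-select regulators and delays for one target
#'
#' Seeds the selected set with the top-ranked regulator at its best single-
#' regulator delay, then tests the remaining ranked candidates in order:
#' for each, every delay `0 .. max_delay_steps` is traversed while the
#' delays of the already-selected regulators are held fixed, and the
#' candidate is accepted at its best delay only if that strictly lowers
#' the model AIC.
#'
#' @inheritParams shift_align
#' @param ranking A non-empty [screen_and_rank()] result.
#' @param params A [selection_params()] object.
#' @return A list with `assignments` (a [delay_assignments()] frame) and
#'   `fit` (the final [fit_delay_model()] result).
#' @export
forward_select <- function(mat, target_id, ranking, params = selection_params()) {
  stopifnot(inherits(ranking, "regulator_ranking"))
  e <- ranking$entries
  if (!nrow(e)) stop("ranking is empty; nothing to select")
  window_start <- ranking$window_start
  maxd <- ranking$max_delay_steps
  log <- function(msg) message("[", target_id, "] ", msg)
  seeds <- if (isTRUE(params$restart_prefixes)) seq_len(nrow(e)) else 1L
  best <- NULL
  for (m in seeds) {
    seed_assign <- delay_assignments(e$regulator[seq_len(m)],
                                     e$delay_steps[seq_len(m)])
    rest <- e[-seq_len(m), , drop = FALSE]
    res <- forward_pass(mat, target_id, seed_assign, rest, params,
                        window_start, maxd, log)
    if (is.null(best) || res$fit$aic < best$fit$aic) best <- res
  }
  best
}

#' Enforce coefficient-magnitude bounds by iterative refitting
#'
#' Regulators whose fitted coefficient magnitude falls outside
#' `[min_coef, max_coef]` are removed and the model refitted, repeatedly,
#' until all remaining coefficients are in bounds or no regulator remains.
#'
#' @inheritParams shift_align
#' @param fit The current [fit_delay_model()] result for `assignments`.
#' @param params A [selection_params()] object.
#' @return A list with `assignments` and `fit`, or `NULL` when every
#'   regulator was removed (no acceptable model).
#' @export
enforce_coef_bounds <- function(mat, target_id, assignments, fit,
                                params = selection_params(),
                                window_start = NULL) {
  if (is.null(window_start)) window_start <- fit$n_window_start %||% NULL
  if (is.null(window_start)) window_start <- max(assignments$delay_steps, 0)
  repeat {
    if (!nrow(assignments)) return(NULL)
    a <- abs(fit$coefficients)
    bad <- a < params$min_coef | a > params$max_coef
    if (!any(bad)) return(list(assignments = assignments, fit = fit))
    assignments <- assignments[!bad, , drop = FALSE]
    if (!nrow(assignments)) return(NULL)
    fit <- fit_delay_model(mat, target_id, assignments, window_start)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sentinel for "no acceptable model", carrying the gate that failed.
no_model <- function(reason) {
  structure(list(), class = "no_model", reason = reason)
}

#' Test whether a selection result is an accepted target model
#' @param x Result of [fit_target_model()].
#' @return `TRUE` for a `target_model`, `FALSE` for the no-model sentinel.
#' @export
is_target_model <- function(x) inherits(x, "target_model")

#' @export
print.no_model <- function(x, ...) {
  cat("<no_model> gate failed:", attr(x, "reason"), "\n")
  invisible(x)
}

#' Fit the complete time-delay model for one target
#'
#' Composes [screen_and_rank()], [forward_select()] and
#' [enforce_coef_bounds()]. A model is returned only when at least one
#' regulator survives and the final adjusted R2 reaches the
#' multiple-regression cutoff.
#'
#' @inheritParams screen_and_rank
#' @return An object of class `target_model` (list with `target_id`,
#'   `regulators` data frame with columns `regulator`, `delay_steps`,
#'   `delay_minutes`, `coefficient`; `intercept`; `aic`; `adj_r2`;
#'   `grid_spacing`), or a `no_model` sentinel when no acceptable model
#'   exists; the sentinel's `reason` attribute names the failed gate
#'   (`"screened_out"`, `"low_adj_r2"`, or `"coef_bounds"`). Test with
#'   [is_target_model()].
#' @export
fit_target_model <- function(mat, target_id, candidates,
                             params = selection_params()) {
  ranking <- screen_and_rank(mat, target_id, candidates, params)
  if (!nrow(ranking$entries))
    return(no_model("screened_out"))
  sel <- forward_select(mat, target_id, ranking, params)
  sel <- enforce_coef_bounds(mat, target_id, sel$assignments, sel$fit, params,
                             window_start = ranking$window_start)
  if (is.null(sel))
    return(no_model("coef_bounds"))
  fit <- sel$fit
  if (is.na(fit$adj_r2) || fit$adj_r2 < params$multiple_adj_r2)
    return(no_model("low_adj_r2"))
  structure(list(
    target_id = target_id,
    regulators = data.frame(
      regulator = sel$assignments$regulator,
      delay_steps = sel$assignments$delay_steps,
      delay_minutes = sel$assignments$delay_steps * mat$grid_spacing,
      coefficient = unname(fit$coefficients),
      stringsAsFactors = FALSE),
    intercept = fit$intercept,
    aic = fit$aic,
    adj_r2 = fit$adj_r2,
    grid_spacing = mat$grid_spacing
  ), class = "target_model")
}

#' @export
print.target_model <- function(x, ...) {
  cat(sprintf("<target_model> %s: intercept %.4f, AIC %.4f, adj.R2 %.6f\n",
              x$target_id, x$intercept, x$aic, x$adj_r2))
  print(x$regulators)
  invisible(x)
}

#' Fit time-delay models for a list of targets
#'
#' Applies [fit_target_model()] independently to every target. Targets for
#' which no acceptable model exists are omitted from the result but
#' recorded, with the gate that failed, in the `run_log` attribute.
#'
#' @inheritParams screen_and_rank
#' @param targets Character vector of target identifiers.
#' @param verbose Emit one progress message per target. Default `FALSE`.
#' @return A named list of [fit_target_model()] results (only the modelled
#'   targets), with attribute `run_log`: a data frame with columns
#'   `target`, `status` (`"modelled"` or the failed gate).
#' @export
fit_all_targets <- function(mat, targets, candidates,
                            params = selection_params(), verbose = FALSE) {
  unknown <- setdiff(c(targets, candidates), gene_ids(mat))
  if (length(unknown))
    stop("identifier(s) not in matrix: ", paste(unknown, collapse = ", "))
  models <- list()
  status <- character(length(targets))
  for (i in seq_along(targets)) {
    tg <- targets[i]
    m <- fit_target_model(mat, tg, candidates, params)
    if (is_target_model(m)) {
      status[i] <- "modelled"
      models[[tg]] <- m
    } else {
      status[i] <- attr(m, "reason") %||% "no_model"
    }
    if (verbose)
      message(sprintf("%s: %s", tg, status[i]))
  }
  structure(models,
            run_log = data.frame(target = targets, status = status,
                                 stringsAsFactors = FALSE))
}

#' Write one target model as tab-separated text
#'
#' Header lines (prefixed `#`) carry the intercept, AIC and adjusted R2;
#' the body has one row per regulator with its coefficient and delay in
#' grid steps and minutes.
#'
#' @param model A [fit_target_model()] result.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_target_model <- function(model, path) {
  stopifnot(inherits(model, "target_model"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# target\t%s", model$target_id),
    sprintf("# intercept\t%.10g", model$intercept),
    sprintf("# aic\t%.10g", model$aic),
    sprintf("# adj.r.squared\t%.10g", model$adj_r2)), con)
  utils::write.table(model$regulators, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
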