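# Preprocessing of raw time courses: baseline log-ratio transform,
# replicate merging on a shared lifeline, and cubic-spline expansion to a
# uniform grid.

#' Transform expression values to baseline-relative log2 ratios
#'
#' Optionally log2-transforms raw values, then subtracts each gene's
#' first-time-point value from every column so that the first column is
#' exactly zero and all later values are expression changes relative to the
#' start of the time course.
#'
#' @param expr An [expr_matrix] with at least two time points.
#' @param log_transform If `TRUE`, apply `log2` before baseline subtraction;
#'   requires strictly positive values. Use for raw-scale input. Default
#'   `FALSE` (input already on a log2 scale).
#' @return An [expr_matrix] with `scale = "log2_ratio"`.
#' @examples
#' m <- expr_matrix(matrix(c(1, 2, 4), 1, dimnames = list("g1", NULL)),
#'                  c(0, 10, 20), scale = "raw")
#' to_log_ratio(m, log_transform = TRUE)$values   # 0 1 2
#' @export
to_log_ratio <- function(expr, log_transform = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (ncol(expr$values) < 2)
    stop("at least two time points are required")
  if (expr$scale == "log2_ratio") {
    warning("input is already on the log2-ratio scale; returning unchanged")
    return(expr)
  }
  v <- expr$values
  if (log_transform) {
    if (any(v <= 0)) {
      bad <- rownames(v)[which(rowSums(v <= 0) > 0)[1]]
      stop("non-positive value for gene '", bad,
           "'; log2 transform requires positive values")
    }
    v <- log2(v)
  }
  v <- v - v[, 1]
  expr$values <- v
  expr$scale <- "log2_ratio"
  expr
}

#' Merge two replicate time courses on a shared lifeline
#'
#' Takes the union of the two time-point sets sorted ascending; where both
#' replicates were sampled at the same lifeline time (within `tol` minutes)
#' the merged column is the arithmetic mean of the two.
#'
#' @param a,b [expr_matrix] objects with identical gene sets (any row order)
#'   and the same scale.
#' @param tol Times closer than this (minutes) are treated as equal.
#' @return An [expr_matrix] over the merged time axis.
#' @export
merge_replicates <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "expr_matrix"), inherits(b, "expr_matrix"))
  if (a$scale != b$scale)
    stop("replicates are on different scales: ", a$scale, " vs ", b$scale)
  ga <- gene_ids(a); gb <- gene_ids(b)
  if (!setequal(ga, gb)) {
    diffs <- c(setdiff(ga, gb), setdiff(gb, ga))
    stop("replicate gene sets differ; symmetric difference: ",
         paste(diffs, collapse = ", "))
  }
  if (length(b$time_points) == 0) return(a)
  if (length(a$time_points) == 0) return(b)
  vb <- b$values[ga, , drop = FALSE]

  times <- c(a$time_points, b$time_points)
  src <- rep(c(1L, 2L), c(length(a$time_points), length(b$time_points)))
  idx <- c(seq_along(a$time_points), seq_along(b$time_points))
  o <- order(times)
  times <- times[o]; src <- src[o]; idx <- idx[o]

  cols <- list(); out_t <- numeric(0)
  i <- 1
  while (i <= length(times)) {
    if (i < length(times) && abs(times[i + 1] - times[i]) <= tol) {
      c1 <- if (src[i] == 1) a$values[, idx[i]] else vb[, idx[i]]
      c2 <- if (src[i + 1] == 1) a$values[, idx[i + 1]] else vb[, idx[i + 1]]
      cols[[length(cols) + 1]] <- (c1 + c2) / 2
      out_t <- c(out_t, (times[i] + times[i + 1]) / 2)
      i <- i + 2
    } else {
      cols[[length(cols) + 1]] <-
        if (src[i] == 1) a$values[, idx[i]] else vb[, idx[i]]
      out_t <- c(out_t, times[i])
      i <- i + 1
    }
  }
  v <- do.call(cbind, cols)
  rownames(v) <- ga
  expr_matrix(v, out_t, a$scale)
}

#' Expand a time course to a uniform grid by cubic-spline interpolation
#'
#' Fits, per gene, a cubic interpolating spline through the observed
#' (time, value) pairs and evaluates it at `n_out` uniformly spaced times
#' spanning the observed range. The default natural boundary condition makes
#' the spline reproduce affine trends exactly and keeps extrapolation (used
#' nowhere here, but by the simulator) linear.
#'
#' @param expr An [expr_matrix] with at least four time points.
#' @param n_out Number of output grid columns; must be at least the number
#'   of observed time points. Default 100.
#' @param method Spline boundary handling, passed to [stats::spline()]:
#'   `"natural"` (default) or `"fmm"`.
#' @param allow_linear With fewer than four observed points, fall back to
#'   linear interpolation instead of failing. Default `FALSE`.
#' @return An [interp_matrix] with `n_grid = n_out` and
#'   `grid_spacing = span / (n_out - 1)`.
#' @export
bspline_interpolate <- function(expr, n_out = 100,
                                method = c("natural", "fmm"),
                                allow_linear = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"))
  method <- match.arg(method)
  k <- length(expr$time_points)
  if (k < 4 && !allow_linear)
    stop("cubic spline interpolation needs at least 4 time points (got ", k,
         "); set allow_linear = TRUE for a linear fallback")
  if (n_out < k)
    stop("n_out (", n_out, ") must be at least the number of observed time points (",
         k, ")")
  grid <- seq(min(expr$time_points), max(expr$time_points), length.out = n_out)
  v <- t(apply(expr$values, 1, function(y) {
    if (k < 4)
      stats::approx(expr$time_points, y, xout = grid)$y
    else
      stats::spline(expr$time_points, y, xout = grid, method = method)$y
  }))
  rownames(v) <- gene_ids(expr)
  interp_matrix(v, grid, expr$scale)
}
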