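# Containers for time-course expression data.
#
# An `expr_matrix` holds a genes x time-points matrix on an explicit,
# strictly increasing time axis (minutes on the lifeline), together with a
# scale flag so downstream code knows whether values are raw intensities,
# log2 values, or baseline-relative log2 ratios.  An `interp_matrix` is the
# same thing on a uniform grid: the substrate on which integer-step delay
# shifts are defined.

#' Construct an expression matrix
#'
#' Bundles a numeric genes x time-points matrix with its time axis and a
#' scale flag. Row names of `values` are the gene (or probe) identifiers and
#' must be unique; `time_points` must be strictly increasing.
#'
#' @param values Numeric matrix, genes in rows, time points in columns.
#'   Must have unique, non-empty row names.
#' @param time_points Strictly increasing numeric vector of times (minutes),
#'   one per column of `values`.
#' @param scale One of `"raw"`, `"log2"`, `"log2_ratio"`. `"log2_ratio"`
#'   means baseline-relative log2 values (first time point subtracted).
#' @param drop_na Drop rows containing any missing value (with a message
#'   giving the count) rather than failing. Default `TRUE`.
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `time_points`, `scale`.
#' @export
expr_matrix <- function(values, time_points,
                        scale = c("raw", "log2", "log2_ratio"),
                        drop_na = TRUE) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  colnames(values) <- NULL  # the time axis lives in time_points
  time_points <- as.numeric(time_points)
  if (drop_na && anyNA(values)) {
    bad <- rowSums(is.na(values)) > 0
    message(sum(bad), " gene(s) with missing observations dropped")
    values <- values[!bad, , drop = FALSE]
  }
  x <- structure(list(values = values, time_points = time_points,
                      scale = scale),
                 class = "expr_matrix")
  validate_expr_matrix(x)
  x
}

validate_expr_matrix <- function(x) {
  v <- x$values
  tp <- x$time_points
  if (ncol(v) != length(tp))
    stop("number of columns (", ncol(v), ") does not match number of time points (",
         length(tp), ")")
  if (is.null(rownames(v)) || any(rownames(v) == ""))
    stop("all genes must have non-empty identifiers (matrix row names)")
  if (anyDuplicated(rownames(v)))
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", "))
  if (length(tp) >= 2 && any(diff(tp) <= 0))
    stop("time points must be strictly increasing")
  invisible(x)
}

#' Construct a uniformly gridded expression matrix
#'
#' An `interp_matrix` is an [expr_matrix] whose time axis is a uniform grid;
#' delay shifts are expressed in integer multiples of its `grid_spacing`.
#' Usually produced by [bspline_interpolate()]; this constructor checks grid
#' uniformity to within 1e-9 relative tolerance.
#'
#' @inheritParams expr_matrix
#' @return An object of class `c("interp_matrix", "expr_matrix")` with the
#'   additional fields `grid_spacing` (minutes between columns) and `n_grid`.
#' @export
interp_matrix <- function(values, time_points, scale = "log2_ratio",
                          drop_na = TRUE) {
  x <- expr_matrix(values, time_points, scale, drop_na = drop_na)
  d <- diff(x$time_points)
  spacing <- (max(x$time_points) - min(x$time_points)) / (length(x$time_points) - 1)
  if (any(abs(d - spacing) > 1e-9 * max(1, abs(spacing))))
    stop("time points are not a uniform grid")
  x$grid_spacing <- spacing
  x$n_grid <- length(x$time_points)
  class(x) <- c("interp_matrix", "expr_matrix")
  x
}

#' Reinterpret an expression matrix observed on a uniform grid
#'
#' @param expr An [expr_matrix] whose observed times happen to be uniform.
#' @return An [interp_matrix] sharing the data.
#' @export
as_interp_matrix <- function(expr) {
  stopifnot(inherits(expr, "expr_matrix"))
  if (inherits(expr, "interp_matrix")) return(expr)
  interp_matrix(expr$values, expr$time_points, expr$scale)
}

#' Gene identifiers of an expression matrix
#' @param x An [expr_matrix].
#' @return Character vector of gene/probe identifiers.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<%s> %d genes x %d time points [%g, %g] min, scale = %s\n",
              class(x)[1], nrow(x$values), ncol(x$values),
              min(x$time_points), max(x$time_points), x$scale))
  if (inherits(x, "interp_matrix"))
    cat(sprintf("  uniform grid, spacing %.6g min\n", x$grid_spacing))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Read an expression matrix from tab-separated text
#'
#' Expects the layout used throughout this package: a header row of numeric
#' time labels, then one row per gene whose first field is the identifier.
#'
#' @param path File path.
#' @param scale Scale flag to attach, see [expr_matrix()].
#' @return An [expr_matrix] (or [interp_matrix] if the times form a uniform
#'   grid and `as_grid = TRUE`).
#' @param as_grid Return an [interp_matrix] when the observed times are
#'   uniform. Default `FALSE`.
#' @export
read_expr_matrix <- function(path, scale = c("raw", "log2", "log2_ratio"),
                             as_grid = FALSE) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE, row.names = 1)
  tp <- suppressWarnings(as.numeric(colnames(tab)))
  if (anyNA(tp))
    stop("column headers of ", path, " must be numeric time labels")
  x <- expr_matrix(as.matrix(tab), tp, scale)
  if (as_grid) as_interp_matrix(x) else x
}

#' Write an expression matrix as tab-separated text
#'
#' Full precision (15 significant digits) so that write/read round-trips are
#' lossless for practical purposes.
#'
#' @param x An [expr_matrix].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_expr_matrix <- function(x, path) {
  stopifnot(inherits(x, "expr_matrix"))
  tab <- format(x$values, digits = 15, trim = TRUE, scientific = FALSE)
  out <- cbind(gene = rownames(x$values), tab)
  colnames(out) <- c("gene", format(x$time_points, digits = 15, trim = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
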