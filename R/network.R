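# Network assembly, serialization, ORF-level collapsing, and evaluation of
# predicted regulations against curated reference edge sets.

#' Assemble per-target models into a directed edge table
#'
#' One directed edge per (regulator, target) pair across all models. The
#' coefficient's sign encodes the regulation mode (positive = activation,
#' negative = repression), and each edge carries the delay in minutes and
#' the model's adjusted R2.
#'
#' @param models A list of [fit_target_model()] results (e.g. from
#'   [fit_all_targets()]); targets must be unique.
#' @return A `data.frame` with columns `regulator`, `target`,
#'   `coefficient`, `delay`, `adj.R.squared`.
#' @export
build_network <- function(models) {
  models <- Filter(function(m) !is.null(m) && !inherits(m, "no_model"),
                   models)
  targets <- vapply(models, function(m) m$target_id, character(1))
  if (anyDuplicated(targets))
    stop("duplicate target models: ",
         paste(unique(targets[duplicated(targets)]), collapse = ", "))
  rows <- lapply(models, function(m)
    data.frame(regulator = m$regulators$regulator,
               target = m$target_id,
               coefficient = m$regulators$coefficient,
               delay = m$regulators$delay_minutes,
               adj.R.squared = m$adj_r2,
               stringsAsFactors = FALSE))
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(regulator = character(), target = character(),
               coefficient = numeric(), delay = numeric(),
               adj.R.squared = numeric())
  rownames(out) <- NULL
  out
}

#' Export an edge table to TSV or GraphML
#'
#' The TSV layout (`regulator`, `target`, `coefficient`, `delay`,
#' `adj.R.squared`) round-trips exactly through [read_network()]. GraphML
#' output (via igraph) carries the three numeric attributes on directed
#' edges for use in external viewers.
#'
#' @param edges Edge table as produced by [build_network()].
#' @param path Output file path.
#' @param format `"tsv"` (default) or `"graphml"`.
#' @return Invisibly, `path`.
#' @export
export_network <- function(edges, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tab <- edges
    for (cl in c("coefficient", "delay", "adj.R.squared"))
      tab[[cl]] <- format(tab[[cl]], digits = 15, trim = TRUE,
                          scientific = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(edges, directed = TRUE)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Read an edge table written by [export_network()]
#'
#' @param path Path to a network TSV.
#' @return Edge `data.frame` with the standard five columns.
#' @export
read_network <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  need <- c("regulator", "target", "coefficient", "delay", "adj.R.squared")
  if (!all(need %in% colnames(tab)))
    stop("network file ", path, " lacks columns: ",
         paste(setdiff(need, colnames(tab)), collapse = ", "))
  tab[need]
}

# Probe identifiers of the form NAME_ORF_probe ("SWI5_YDR146C_1770349_at")
# carry the ORF as their second underscore-separated token.
parse_orf_from_probe <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  vapply(seq_along(ids), function(i) {
    p <- parts[[i]]
    if (length(p) >= 3) p[2] else NA_character_
  }, character(1))
}

#' Collapse probe-level edges to ORF level
#'
#' Replaces probe identifiers by ORF identifiers and deduplicates edges
#' that collapse onto the same ORF pair, keeping the one with the highest
#' adjusted R2. Without an explicit mapping, identifiers of the form
#' `NAME_ORF_probe` have their ORF parsed from the second token;
#' unparseable identifiers pass through unchanged with a warning.
#' Self-loops created by the collapse (two probes of one ORF) are dropped.
#'
#' @param edges Edge table as from [build_network()].
#' @param mapping Optional two-column `data.frame` (probe, orf) or named
#'   character vector mapping probe identifiers to ORFs.
#' @return Edge table at ORF level.
#' @export
collapse_to_orf <- function(edges, mapping = NULL) {
  if (!nrow(edges)) return(edges)
  ids <- unique(c(edges$regulator, edges$target))
  if (is.null(mapping)) {
    orf <- parse_orf_from_probe(ids)
  } else {
    if (is.data.frame(mapping))
      mapping <- stats::setNames(as.character(mapping[[2]]),
                                 as.character(mapping[[1]]))
    orf <- unname(mapping[ids])
  }
  unmapped <- is.na(orf)
  if (any(unmapped)) {
    warning("identifier(s) without ORF mapping pass through unchanged: ",
            paste(ids[unmapped], collapse = ", "))
    orf[unmapped] <- ids[unmapped]
  }
  map <- stats::setNames(orf, ids)
  out <- edges
  out$regulator <- unname(map[out$regulator])
  out$target <- unname(map[out$target])
  self <- out$regulator == out$target
  if (any(self)) {
    warning(sum(self), " self-loop(s) created by ORF collapse dropped")
    out <- out[!self, , drop = FALSE]
  }
  # deduplicate per ORF pair, keeping the highest adjusted R2 but
  # preserving the input row order
  key <- paste(out$regulator, out$target, sep = "\r")
  ord <- order(-out$adj.R.squared)
  keep <- sort(ord[!duplicated(key[ord])])
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Construct a reference edge set
#'
#' Known-interaction pairs against which predicted regulations are scored.
#' Directed references store pairs regulator -> target; undirected
#' references (e.g. association databases) match either orientation. The
#' universe -- the set of genes the reference knows about -- defaults to
#' every identifier appearing in the pairs, and determines which predicted
#' edges are scorable at all.
#'
#' @param pairs Two-column `data.frame` (regulator/id_a, target/id_b).
#' @param directed Logical; is the reference directional? Default `TRUE`.
#' @param name Label used in evaluation output.
#' @param universe Optional character vector of identifiers covered by the
#'   reference; defaults to all identifiers in `pairs`.
#' @return An object of class `reference_set`.
#' @export
reference_set <- function(pairs, directed = TRUE, name = "reference",
                          universe = NULL) {
  pairs <- data.frame(a = as.character(pairs[[1]]),
                      b = as.character(pairs[[2]]),
                      stringsAsFactors = FALSE)
  if (is.null(universe)) universe <- unique(c(pairs$a, pairs$b))
  if (!directed) {
    swap <- pairs$a > pairs$b  # store undirected pairs canonically
    tmp <- pairs$a[swap]; pairs$a[swap] <- pairs$b[swap]; pairs$b[swap] <- tmp
    pairs <- unique(pairs)
  }
  structure(list(name = name, pairs = pairs, directed = directed,
                 universe = unique(as.character(universe))),
            class = "reference_set")
}

#' Read a reference edge set from a two- or three-column TSV
#'
#' Columns: regulator, target, and an optional score (ignored). A header
#' row is detected when the first line's third field is non-numeric or the
#' first fields match `regulator`/`target`.
#'
#' @param path File path.
#' @inheritParams reference_set
#' @export
read_reference_set <- function(path, directed = TRUE, name = basename(path),
                               universe = NULL) {
  first <- utils::read.delim(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- any(tolower(unlist(first[1:2])) %in%
                  c("regulator", "target", "id_a", "id_b", "source",
                    "from"))
  tab <- utils::read.delim(path, header = header, stringsAsFactors = FALSE)
  reference_set(tab[1:2], directed = directed, name = name,
                universe = universe)
}

ref_has_pair <- function(ref, a, b) {
  if (ref$directed) {
    key <- paste(ref$pairs$a, ref$pairs$b, sep = "\r")
    paste(a, b, sep = "\r") %in% key
  } else {
    lo <- pmin(a, b); hi <- pmax(a, b)
    key <- paste(ref$pairs$a, ref$pairs$b, sep = "\r")
    paste(lo, hi, sep = "\r") %in% key
  }
}

#' Score predicted regulations against reference edge sets
#'
#' Each predicted edge gets, per reference, a flag: `1` if the pair is
#' present (either orientation for undirected references), `0` if both
#' endpoints belong to the reference's universe but the pair is absent,
#' and `NA` if the reference does not cover one of the genes. References
#' combine by OR: an edge with a `1` in any reference is a true
#' regulation, an edge with a `0` or `1` in any reference is a total
#' (scorable) regulation, and accuracy = true / total. Edges `NA` in every
#' reference are excluded from both counts.
#'
#' @param edges Edge table as from [build_network()].
#' @param refs A [reference_set] or list of them.
#' @return An object of class `network_evaluation`: list with `table` (the
#'   edge table plus one flag column per reference), `accuracy` (`NA` when
#'   no edge is scorable), `n_true`, `n_total`.
#' @export
evaluate_against_references <- function(edges, refs) {
  if (inherits(refs, "reference_set")) refs <- list(refs)
  if (!length(refs)) stop("at least one reference set is required")
  flags <- matrix(NA_integer_, nrow(edges), length(refs))
  colnames(flags) <- vapply(refs, `[[`, character(1), "name")
  for (j in seq_along(refs)) {
    ref <- refs[[j]]
    if (!nrow(edges)) next
    covered <- edges$regulator %in% ref$universe &
      edges$target %in% ref$universe
    hit <- ref_has_pair(ref, edges$regulator, edges$target)
    flags[, j] <- ifelse(covered, as.integer(hit), NA_integer_)
  }
  any1 <- apply(flags, 1, function(r) any(r == 1, na.rm = TRUE))
  scorable <- apply(flags, 1, function(r) any(!is.na(r)))
  n_true <- sum(any1 & scorable)
  n_total <- sum(scorable)
  structure(list(
    table = cbind(edges, as.data.frame(flags)),
    accuracy = if (n_total > 0) n_true / n_total else NA_real_,
    n_true = n_true, n_total = n_total
  ), class = "network_evaluation")
}

#' @export
print.network_evaluation <- function(x, ...) {
  if (is.na(x$accuracy))
    cat("<network_evaluation> no scorable regulations (accuracy undefined)\n")
  else
    cat(sprintf("<network_evaluation> %d true / %d total regulations, accuracy %.2f%%\n",
                x$n_true, x$n_total, 100 * x$accuracy))
  invisible(x)
}
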