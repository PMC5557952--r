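#' Construct a disease-specific miRNA interaction network (DMIN)
#'
#' A DMIN is a directed graph whose nodes are miRNAs, optionally annotated
#' with an expression score (the aggregated magnitude of the log2 fold
#' change), and whose edges carry a weight in \[0, 1\] -- either an inferred
#' confidence probability or, after weighting, an influence score used as an
#' activation probability by the Independent Cascade model.
#'
#' Self-loops are forbidden (a miRNA does not activate itself) and duplicate
#' directed edges are collapsed to the one with the maximum weight, which is
#' conservative toward retention at a high-confidence cutoff.
#'
#' @param edges data frame with columns `source`, `target`, `weight`
#'   (weight in \[0, 1\]); zero-row data frames are allowed.
#' @param nodes optional data frame with columns `mirna` and, optionally,
#'   `expression` (nonnegative score) and `signed_log2fc`. Defaults to the
#'   set of edge endpoints with no expression annotation.
#' @param disease_id identifier of the disease the network describes.
#' @param meta free-form list of provenance metadata.
#' @return An object of class `dmin` with fields `disease_id`, `nodes`,
#'   `edges`, `meta`.
#' @examples
#' g <- dmin(data.frame(source = "a", target = "b", weight = 0.95), disease_id = "d1")
#' dmin_n(g)
#' @export
dmin <- function(edges, nodes = NULL, disease_id = NA_character_, meta = list()) {
  if (!is.data.frame(edges))
    stop_validation("`edges` must be a data frame")
  need <- c("source", "target", "weight")
  miss <- setdiff(need, names(edges))
  if (length(miss))
    stop_format(sprintf("edge table is missing column(s): %s",
                        paste(miss, collapse = ", ")))
  edges <- data.frame(source = as.character(edges$source),
                      target = as.character(edges$target),
                      weight = as.numeric(edges$weight),
                      stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (anyNA(edges$weight) || any(edges$weight < 0 | edges$weight > 1))
      stop_validation("edge weights must be numeric and lie in [0, 1]")
    if (any(edges$source == edges$target))
      stop_validation("self-loops are not allowed in a DMIN")
    key <- edge_key(edges$source, edges$target)
    if (anyDuplicated(key)) {
      # keep the maximum weight among duplicates of the same directed edge
      o <- order(key, -edges$weight)
      edges <- edges[o, , drop = FALSE]
      dup <- duplicated(edge_key(edges$source, edges$target))
      message(sprintf("collapsed %d duplicate edge(s), keeping maximum weight",
                      sum(dup)))
      edges <- edges[!dup, , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  if (is.null(nodes)) {
    ids <- sort(unique(c(edges$source, edges$target)))
    nodes <- data.frame(mirna = ids, expression = NA_real_,
                        signed_log2fc = NA_real_, stringsAsFactors = FALSE)
  } else {
    if (!is.data.frame(nodes) || !"mirna" %in% names(nodes))
      stop_format("`nodes` must be a data frame with a `mirna` column")
    nodes <- data.frame(
      mirna = as.character(nodes$mirna),
      expression = if ("expression" %in% names(nodes))
        as.numeric(nodes$expression) else NA_real_,
      signed_log2fc = if ("signed_log2fc" %in% names(nodes))
        as.numeric(nodes$signed_log2fc) else NA_real_,
      stringsAsFactors = FALSE)
    if (anyDuplicated(nodes$mirna))
      stop_validation("duplicate node ids in `nodes`")
    stray <- setdiff(unique(c(edges$source, edges$target)), nodes$mirna)
    if (length(stray))
      stop_validation(sprintf("edge endpoint(s) not in node table: %s",
                              paste(stray, collapse = ", ")))
    if (any(!is.na(nodes$expression) & nodes$expression < 0))
      stop_validation("expression scores must be nonnegative")
    nodes <- nodes[order(nodes$mirna), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  if (nrow(nodes) < 1)
    stop_validation("a DMIN needs at least one node")
  structure(list(disease_id = disease_id, nodes = nodes, edges = edges,
                 meta = meta),
            class = "dmin")
}

#' Number of nodes in a DMIN
#' @param x a `dmin` object
#' @return integer node count
#' @export
dmin_n <- function(x) {
  stopifnot(inherits(x, "dmin"))
  nrow(x$nodes)
}

#' @export
print.dmin <- function(x, ...) {
  annot <- sum(!is.na(x$nodes$expression))
  cat(sprintf("DMIN '%s': %d nodes (%d with expression), %d directed edges\n",
              x$disease_id, nrow(x$nodes), annot, nrow(x$edges)))
  if (isTRUE(x$meta$weights_discarded))
    cat("  edge weights: discarded confidence scores (sentinel 1.0)\n")
  invisible(x)
}

#' @exportS3Method base::all.equal
all.equal.dmin <- function(target, current, tolerance = 1e-12, ...) {
  a <- target; b <- current
  msgs <- character()
  if (!identical(a$disease_id, b$disease_id)) msgs <- c(msgs, "disease_id differs")
  ea <- a$edges[order(a$edges$source, a$edges$target), , drop = FALSE]
  eb <- b$edges[order(b$edges$source, b$edges$target), , drop = FALSE]
  rownames(ea) <- rownames(eb) <- NULL
  if (!identical(ea$source, eb$source) || !identical(ea$target, eb$target))
    msgs <- c(msgs, "edge sets differ")
  else if (!isTRUE(all.equal(ea$weight, eb$weight, tolerance = tolerance)))
    msgs <- c(msgs, "edge weights differ")
  if (!identical(a$nodes$mirna, b$nodes$mirna))
    msgs <- c(msgs, "node sets differ")
  else if (!isTRUE(all.equal(a$nodes$expression, b$nodes$expression,
                             tolerance = tolerance)))
    msgs <- c(msgs, "expression scores differ")
  if (length(msgs)) msgs else TRUE
}
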