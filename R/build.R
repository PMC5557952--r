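#' Extract the high-confidence subnetwork (DMIN_HC)
#'
#' Keeps exactly the edges whose confidence probability is greater than or
#' equal to `threshold` (boundary inclusive) and drops nodes left without
#' any incident edge. Inference pipelines that predict miRNA-miRNA edges
#' from noisy expression data are only trustworthy at high confidence, and
#' the cascade model itself behaves better on sparse graphs, so a stringent
#' cutoff (default 0.90) is applied before any influence analysis.
#'
#' After filtering, the confidence probabilities have served their purpose
#' and are discarded: the retained values are moved to a `confidence`
#' metadata column, the working `weight` is set to a sentinel of 1.0, and
#' `meta$weights_discarded` is flagged. Downstream weighting
#' ([optimize_edge_weights()] or [rescore_constant()]) overwrites them.
#'
#' @param network a `dmin` with confidence-probability edge weights.
#' @param threshold retention cutoff in \[0, 1\]; default 0.90.
#' @return The filtered `dmin` (the DMIN_HC).
#' @examples
#' g <- dmin(data.frame(source = c("a", "b", "c"), target = c("b", "c", "a"),
#'                      weight = c(0.95, 0.90, 0.89)))
#' nrow(filter_high_confidence(g)$edges)  # 2: the 0.90 edge is kept
#' @export
filter_high_confidence <- function(network, threshold = 0.90) {
  stopifnot(inherits(network, "dmin"))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop_validation("`threshold` must be a single number in [0, 1]")
  keep <- network$edges$weight >= threshold
  edges <- network$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  if (!nrow(edges)) {
    warning(sprintf("no edge reaches confidence %.3g; network '%s' is empty",
                    threshold, network$disease_id))
    nodes <- network$nodes[0, , drop = FALSE]
  } else {
    nodes <- network$nodes[
      network$nodes$mirna %in% c(edges$source, edges$target), , drop = FALSE]
    rownames(nodes) <- NULL
  }
  out <- network
  out$edges <- edges
  out$edges$confidence <- edges$weight
  out$edges$weight <- rep(1.0, nrow(edges))
  out$nodes <- nodes
  out$meta$weights_discarded <- TRUE
  out$meta$hc_threshold <- threshold
  out
}

#' Attach expression scores to a high-confidence network (DMIN_HCE)
#'
#' Annotates every node of a DMIN_HC with its aggregated expression score
#' for the network's disease (see [aggregate_expression()]). Nodes with no
#' expression record for that disease are removed with a warning rather than
#' imputed: the flow optimization is undefined without a node score, and
#' inventing one would fabricate data.
#'
#' @param network a `dmin` whose nodes are not yet annotated.
#' @param table an `expression_table` containing records for
#'   `network$disease_id`.
#' @return The annotated `dmin` (the DMIN_HCE, prior to edge weighting).
#' @export
attach_expression <- function(network, table) {
  stopifnot(inherits(network, "dmin"), inherits(table, "expression_table"))
  if (any(!is.na(network$nodes$expression)))
    stop_validation("network already carries expression annotations")
  dz <- network$disease_id
  sub <- table[table$disease == dz, , drop = FALSE]
  have <- network$nodes$mirna %in% sub$mirna
  if (!all(have)) {
    warning(sprintf(
      "removing %d node(s) with no expression record for disease '%s': %s",
      sum(!have), dz, paste(network$nodes$mirna[!have], collapse = ", ")))
  }
  nodes <- network$nodes[have, , drop = FALSE]
  for (i in seq_len(nrow(nodes))) {
    sc <- aggregate_expression(table, nodes$mirna[i], dz)
    nodes$expression[i] <- as.numeric(sc)
    nodes$signed_log2fc[i] <- attr(sc, "signed_log2fc")
  }
  rownames(nodes) <- NULL
  keep_edge <- network$edges$source %in% nodes$mirna &
               network$edges$target %in% nodes$mirna
  out <- network
  out$nodes <- nodes
  out$edges <- network$edges[keep_edge, , drop = FALSE]
  rownames(out$edges) <- NULL
  out
}
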