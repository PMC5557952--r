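node_index <- function(network, node) {
  ix <- match(node, network$nodes$mirna)
  if (is.na(ix))
    stop_not_found(sprintf("node '%s' is not in network '%s'",
                           node, network$disease_id))
  ix
}

check_probabilities <- function(network) {
  w <- network$edges$weight
  if (nrow(network$edges) && (any(w < 0) || any(w > 1)))
    stop_validation("edge weights must be probabilities in [0, 1]")
}

#' Simulate one Independent Cascade realization
#'
#' Starting from an active seed node, propagation proceeds in breadth
#' (FIFO) order: each newly activated node performs one biased coin toss
#' per out-edge, succeeding with probability equal to the edge weight, and
#' successful tosses activate the target. An edge is attempted at most once
#' per realization, attempts into already-active targets are skipped, and
#' the cascade stops when no new activation is possible. Because every edge
#' fires independently, the final activated set does not depend on the
#' processing order -- only the attempt trace does.
#'
#' Coin tosses draw from R's global RNG (`set.seed()` gives reproducible
#' traces). Individual edges can be forced for didactic replays via
#' `forced_outcomes`.
#'
#' @param network a `dmin` with probability edge weights.
#' @param seed_node id of the initially active node.
#' @param forced_outcomes optional named logical vector forcing specific
#'   edges, names of the form `"source→target"` (see [edge_outcome_name()]).
#' @return A `cascade_realization`: list with `seed`, `activated`
#'   (character vector in activation order, excluding the seed), and
#'   `attempted_edges` (data frame `source`, `target`, `outcome`).
#' @examples
#' g <- fig4_fixture()
#' set.seed(1)
#' simulate_cascade(g, "1")
#' @export
simulate_cascade <- function(network, seed_node, forced_outcomes = NULL) {
  stopifnot(inherits(network, "dmin"))
  node_index(network, seed_node)
  check_probabilities(network)
  edges <- network$edges
  active <- seed_node
  frontier <- seed_node
  attempted <- list()
  while (length(frontier)) {
    v <- frontier[[1]]
    frontier <- frontier[-1]
    out <- which(edges$source == v)
    for (k in out) {
      u <- edges$target[k]
      if (u %in% active) next
      nm <- edge_key(v, u)
      success <- if (!is.null(forced_outcomes) && nm %in% names(forced_outcomes))
        isTRUE(forced_outcomes[[nm]])
      else
        runif(1) < edges$weight[k]
      attempted[[length(attempted) + 1L]] <-
        data.frame(source = v, target = u, outcome = success,
                   stringsAsFactors = FALSE)
      if (success) {
        active <- c(active, u)
        frontier <- c(frontier, u)
      }
    }
  }
  structure(list(seed = seed_node,
                 activated = setdiff(active, seed_node),
                 attempted_edges = if (length(attempted))
                   do.call(rbind, attempted)
                 else data.frame(source = character(), target = character(),
                                 outcome = logical())),
            class = "cascade_realization")
}

#' Name an edge for `forced_outcomes`
#' @param source,target edge endpoints
#' @return the string key used by [simulate_cascade()]'s `forced_outcomes`.
#' @export
edge_outcome_name <- function(source, target) edge_key(source, target)

#' Monte-Carlo coverage of one node
#'
#' Coverage COV(u) is the expected number of nodes (excluding u itself)
#' activated by cascades seeded at u. It is estimated as the mean activated
#' count over `n_sim` independent realizations (default 10000), run in
#' compiled code on a dedicated RNG stream derived from `(seed, node)` so
#' the estimate does not depend on which other nodes are evaluated.
#'
#' @param network a `dmin` with probability edge weights.
#' @param node seed node id.
#' @param n_sim number of Monte-Carlo cycles; default 10000.
#' @param seed master RNG seed (integer).
#' @return The estimated mean coverage, with attributes `var` (per-replicate
#'   sample variance) and `n_sim`.
#' @export
compute_coverage <- function(network, node, n_sim = 10000, seed = 1L) {
  stopifnot(inherits(network, "dmin"))
  if (!is.numeric(n_sim) || n_sim < 1)
    stop_validation("`n_sim` must be a positive integer")
  ix <- node_index(network, node)
  check_probabilities(network)
  ids <- network$nodes$mirna
  st <- ic_coverage_stats(match(network$edges$source, ids) - 1L,
                          match(network$edges$target, ids) - 1L,
                          network$edges$weight,
                          length(ids), ix - 1L, as.integer(n_sim),
                          as.numeric(seed), as.character(node))
  structure(st[1], var = st[2], n_sim = as.integer(n_sim))
}

#' Exact expected coverage by live-edge enumeration
#'
#' The Independent Cascade process is distributionally equivalent to
#' declaring each edge independently "live" with probability equal to its
#' weight and activating everything reachable from the seed through live
#' edges. Enumerating all `2^|E|` live/blocked configurations, weighting
#' each by its product probability, and summing reachable counts gives the
#' exact expectation that Monte-Carlo simulation estimates. Reachability is
#' computed by boolean-matrix transitive closure, a route entirely
#' independent of the simulation engine, which makes this function the
#' oracle in equivalence tests.
#'
#' Cost doubles per edge; a guard refuses networks with more than 20 edges.
#'
#' @param network a `dmin` with probability edge weights.
#' @param node seed node id, or `NULL` for all nodes at once (one
#'   enumeration pass instead of one per node).
#' @return Expected coverage: a scalar for one node, otherwise a named
#'   vector over all nodes.
#' @examples
#' g <- dmin(data.frame(source = c("1", "2"), target = c("2", "3"),
#'                      weight = c(0.5, 0.5)))
#' exact_expected_coverage(g, "1")  # 0.5 + 0.25
#' @export
exact_expected_coverage <- function(network, node = NULL) {
  stopifnot(inherits(network, "dmin"))
  check_probabilities(network)
  m <- nrow(network$edges)
  if (m > 20)
    stop_resource(sprintf(
      "%d edges means 2^%d configurations; use compute_coverage() instead",
      m, m))
  ids <- network$nodes$mirna
  n <- length(ids)
  if (!is.null(node)) node_index(network, node)
  if (m == 0) {
    cov <- setNames(rep(0, n), ids)
    return(if (is.null(node)) cov else cov[[node]])
  }
  si <- match(network$edges$source, ids)
  ti <- match(network$edges$target, ids)
  w <- network$edges$weight

  cfg <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), m)))
  lw  <- log(pmax(w, .Machine$double.xmin))
  lb  <- log(pmax(1 - w, .Machine$double.xmin))
  logp <- cfg %*% lw + (!cfg) %*% lb
  prob <- as.numeric(exp(logp))
  prob[(cfg %*% (w == 0)) > 0] <- 0        # live edge of weight 0
  prob[((!cfg) %*% (w == 1)) > 0] <- 0     # blocked edge of weight 1

  cov <- setNames(rep(0, n), ids)
  for (c_ix in seq_len(nrow(cfg))) {
    p <- prob[c_ix]
    if (p == 0) next
    A <- matrix(FALSE, n, n)
    live <- cfg[c_ix, ]
    A[cbind(si[live], ti[live])] <- TRUE
    R <- diag(TRUE, n)
    repeat {
      R2 <- R | ((R %*% A) > 0)
      if (identical(R2, R)) break
      R <- R2
    }
    cov <- cov + p * (rowSums(R) - 1)
  }
  if (is.null(node)) cov else cov[[node]]
}

#' Map mean coverage to a coverage percentage
#'
#' A node with coverage-percentage 70 influences, in expectation, 70% of
#' the nodes of its network. The denominator is the full node count `n`,
#' matching the "share of the network" reading of the percentage.
#'
#' @param mean_coverage expected coverage, in `[0, n - 1]`.
#' @param n node count of the network the coverage was measured on.
#' @return `mean_coverage / n * 100`. Vectorized over `mean_coverage`.
#' @export
coverage_percentage <- function(mean_coverage, n) {
  if (!is.numeric(n) || length(n) != 1 || n < 1)
    stop_validation("`n` must be a positive integer")
  if (any(is.na(mean_coverage)) ||
      any(mean_coverage < 0 | mean_coverage > n - 1))
    stop_validation("`mean_coverage` must lie in [0, n - 1]")
  mean_coverage / n * 100
}

#' Rank every node of a network by Monte-Carlo coverage
#'
#' Estimates each node's coverage with [compute_coverage()] (per-node RNG
#' substreams of one master seed), sorts in decreasing coverage, breaks
#' ties lexicographically on the miRNA id (C collation) so output is
#' deterministic, and attaches coverage percentages.
#'
#' @inheritParams compute_coverage
#' @return A `coverage_result`: data frame `mirna`, `mean_coverage`,
#'   `coverage_percentage`, `rank`, with attributes `n_sim`, `seed`, `n`.
#' @export
rank_all_nodes <- function(network, n_sim = 10000, seed = 1L) {
  stopifnot(inherits(network, "dmin"))
  if (!nrow(network$nodes))
    stop_validation("cannot rank an empty network")
  ids <- network$nodes$mirna
  cov <- vapply(ids, function(v)
    as.numeric(compute_coverage(network, v, n_sim = n_sim, seed = seed)),
    numeric(1))
  o <- order(-cov, ids, method = "radix")
  res <- data.frame(mirna = ids[o],
                    mean_coverage = cov[o],
                    coverage_percentage =
                      coverage_percentage(cov[o], length(ids)),
                    rank = seq_along(ids),
                    stringsAsFactors = FALSE)
  attr(res, "n_sim") <- as.integer(n_sim)
  attr(res, "seed") <- seed
  attr(res, "n") <- length(ids)
  class(res) <- c("coverage_result", "data.frame")
  res
}
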