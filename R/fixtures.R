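#' The five-node didactic cascade network
#'
#' A small directed network used throughout examples and tests: edges
#' 1→2 (weight 0.5), 1→3 (0.9), 3→4, 3→5, 5→4. The three weights on the
#' lower edges default to 0.5 and can be overridden; tests that replay a
#' particular cascade force the coin tosses directly instead of relying on
#' them.
#'
#' @param lower_weights weights for edges 3→4, 3→5, 5→4, in that order.
#' @return A 5-node, 5-edge `dmin`.
#' @export
fig4_fixture <- function(lower_weights = c(0.5, 0.5, 0.5)) {
  stopifnot(length(lower_weights) == 3)
  dmin(data.frame(
    source = c("1", "1", "3", "3", "5"),
    target = c("2", "3", "4", "5", "4"),
    weight = c(0.5, 0.9, lower_weights),
    stringsAsFactors = FALSE), disease_id = "toy")
}

#' Generate a random synthetic DMIN
#'
#' Erdos-Renyi-style directed graph: each ordered pair of distinct nodes
#' receives an edge independently with probability `edge_density`. Edge
#' weights and node expression scores are drawn per the requested
#' distributions; expression scores are magnitudes of log2 fold changes
#' whose fold changes are log-normal, mimicking a mix of up- and
#' down-regulated miRNAs.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param edge_density probability of each ordered pair, in (0, 1\].
#' @param weight_distribution `"uniform01"`, `"constant"` or
#'   `"high_confidence"` (uniform on \[0.9, 1\]).
#' @param constant_weight weight used when `weight_distribution` is
#'   `"constant"`.
#' @param expression_distribution `"lognormal"` fold changes (parameters
#'   `meanlog`, `sdlog`) or `"fixed"` (every node gets
#'   `|log2(fixed_fold_change)|`).
#' @param meanlog,sdlog log-normal parameters of the fold-change draw.
#' @param fixed_fold_change fold change used under `"fixed"`.
#' @param seed RNG seed; identical seeds give identical graphs.
#' @param disease_id optional disease label; defaults to one derived from
#'   the seed.
#' @return A `dmin` with annotated nodes `sprintf("m%03d", 1:n_nodes)`.
#' @export
generate_random_dmin <- function(n_nodes, edge_density = 0.3,
                                 weight_distribution = c("uniform01", "constant",
                                                         "high_confidence"),
                                 constant_weight = 0.01,
                                 expression_distribution = c("lognormal", "fixed"),
                                 meanlog = 0, sdlog = 1,
                                 fixed_fold_change = 4,
                                 seed = 1L, disease_id = NULL) {
  weight_distribution <- match.arg(weight_distribution)
  expression_distribution <- match.arg(expression_distribution)
  if (!is.numeric(n_nodes) || n_nodes < 2)
    stop_validation("`n_nodes` must be at least 2")
  if (edge_density <= 0 || edge_density > 1)
    stop_validation("`edge_density` must be in (0, 1]")
  n_nodes <- as.integer(n_nodes)
  if (n_nodes <= 3 && edge_density * n_nodes * (n_nodes - 1) < 1)
    warning("expected edge count below 1; the graph may be edgeless")
  ids <- sprintf("m%03d", seq_len(n_nodes))
  pairs <- expand.grid(source = ids, target = ids,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  keep <- runif(nrow(pairs)) < edge_density
  edges <- pairs[keep, , drop = FALSE]
  m <- nrow(edges)
  edges$weight <- switch(weight_distribution,
    uniform01 = runif(m),
    constant = rep(constant_weight, m),
    high_confidence = runif(m, 0.9, 1))
  fc <- switch(expression_distribution,
    lognormal = rlnorm(n_nodes, meanlog, sdlog),
    fixed = rep(fixed_fold_change, n_nodes))
  nodes <- data.frame(mirna = ids,
                      expression = abs(log2(fc)),
                      signed_log2fc = log2(fc),
                      stringsAsFactors = FALSE)
  if (is.null(disease_id)) disease_id <- sprintf("synthetic_seed%d", seed)
  dmin(edges, nodes = nodes, disease_id = disease_id)
}

#' Planted-influencer network with known ground truth
#'
#' Builds a network containing one hub with `hub_out_degree` out-edges of
#' high activation probability `hub_p`, over a sparse background of edges
#' with low probability `background_p`. By construction the hub's expected
#' cascade spread dominates every other node's, so influence ranking should
#' recover it at rank 1 -- the recovery rate is a direct functional test of
#' the coverage estimator.
#'
#' @param n_nodes total nodes; the hub is the first id.
#' @param hub_out_degree out-degree of the hub (<= `n_nodes` - 1).
#' @param hub_p activation probability on hub edges.
#' @param background_p activation probability on background edges; must be
#'   strictly less than `hub_p` (0 allowed: inert background).
#' @param background_density probability that each non-hub ordered pair
#'   carries a background edge; default 0.1.
#' @param seed RNG seed.
#' @return A list with `network` (a `dmin`) and `hub_id`.
#' @export
planted_influencer_network <- function(n_nodes = 20, hub_out_degree = 15,
                                       hub_p = 0.9, background_p = 0.05,
                                       background_density = 0.1, seed = 1L) {
  if (hub_out_degree > n_nodes - 1)
    stop_validation("`hub_out_degree` cannot exceed n_nodes - 1")
  if (!(hub_p > background_p))
    stop_validation("`hub_p` must be strictly greater than `background_p`")
  if (hub_p <= 0 || hub_p > 1 || background_p < 0)
    stop_validation("probabilities must satisfy 0 <= background_p < hub_p <= 1")
  ids <- sprintf("m%03d", seq_len(n_nodes))
  hub <- ids[1]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  hub_targets <- sample(ids[-1], hub_out_degree)
  edges <- data.frame(source = hub, target = hub_targets,
                      weight = hub_p, stringsAsFactors = FALSE)
  others <- expand.grid(source = ids[-1], target = ids[-1],
                        stringsAsFactors = FALSE)
  others <- others[others$source != others$target, , drop = FALSE]
  bg <- others[runif(nrow(others)) < background_density, , drop = FALSE]
  if (nrow(bg)) {
    bg$weight <- background_p
    edges <- rbind(edges, bg)
  }
  nodes <- data.frame(mirna = ids, expression = NA_real_,
                      signed_log2fc = NA_real_, stringsAsFactors = FALSE)
  list(network = dmin(edges, nodes = nodes,
                      disease_id = sprintf("planted_seed%d", seed)),
       hub_id = hub)
}

#' Generate a synthetic expression table
#'
#' Emulates the structure of curated fold-change tables: one row per
#' (miRNA, disease, study) observation, fold changes drawn log-normally so
#' both up-regulation (> 1) and down-regulation (< 1) occur, and a
#' configurable fraction of (miRNA, disease) pairs replicated across
#' multiple studies.
#'
#' @param diseases character vector of disease ids.
#' @param mirnas_per_disease number of miRNAs per disease.
#' @param replicates rows given to each replicated pair (>= 1).
#' @param replicate_fraction fraction of pairs receiving `replicates` rows.
#' @param distribution `"lognormal"` (parameters `meanlog`, `sdlog`) or
#'   `"fixed"` (every fold change equals `fixed_fold_change`).
#' @param meanlog,sdlog log-normal parameters.
#' @param fixed_fold_change constant fold change under `"fixed"`.
#' @param seed RNG seed.
#' @return An `expression_table`.
#' @export
generate_expression_table <- function(diseases, mirnas_per_disease,
                                      replicates = 3L, replicate_fraction = 0.2,
                                      distribution = c("lognormal", "fixed"),
                                      meanlog = 0, sdlog = 1,
                                      fixed_fold_change = 4, seed = 1L) {
  distribution <- match.arg(distribution)
  if (!length(diseases) || mirnas_per_disease < 1 || replicates < 1)
    stop_validation("all counts must be at least 1")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  ids <- sprintf("m%03d", seq_len(mirnas_per_disease))
  rows <- list()
  for (dz in diseases) {
    reps <- ifelse(runif(length(ids)) < replicate_fraction, replicates, 1L)
    for (i in seq_along(ids)) {
      k <- reps[i]
      fc <- switch(distribution,
                   lognormal = rlnorm(k, meanlog, sdlog),
                   fixed = rep(fixed_fold_change, k))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna = ids[i], disease = dz, fold_change = fc,
        regulation = ifelse(fc >= 1, "up", "down"),
        study = sprintf("study%02d", seq_len(k)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("expression_table", "data.frame")
  out
}
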