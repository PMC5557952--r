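#' Derive influence edge weights by slack-minimizing linear programming
#'
#' Given a DMIN_HCE whose nodes carry nonnegative expression scores `e_i`,
#' solves for per-edge influence flows `X_ij >= 0` under two constraint
#' families, minimizing the total slack `sum |s_i|`:
#'
#' * **Incoming** (equality, for every node with at least one in-edge):
#'   `sum_j e_j * X_ji = e_i` -- a miRNA's expression is modelled as the
#'   cumulative result of its regulators' expression flowing in.
#' * **Outgoing** (equality with slack, for every node):
#'   `e_i * sum_j X_ij + s_i = e_i` -- a miRNA's outgoing influence is tied
#'   to its own expression, relaxed by a free-signed slack `s_i` without
#'   which the system is generally unsolvable.
#'
#' `|s_i|` is linearized exactly as `s_i = s_i^+ - s_i^-` with both parts
#' nonnegative and `s_i^+ + s_i^-` in the objective. Flow variables exist
#' only for edges present in the network. The Incoming equality is dropped
#' for in-degree-0 nodes, which are treated as exogenous drivers: with no
#' regulator, the constraint `0 = e_i` would make any expressed source node
#' infeasible. Dropped nodes are reported in the solution.
#'
#' The optimal flows become the returned network's edge weights; because
#' the cascade model needs activation probabilities, flows above 1 are
#' clipped to 1 and the clip count is reported.
#'
#' @param network a `dmin` whose every node has a nonnegative expression
#'   score and with at least one edge.
#' @return A list with components `network` (the weighted `dmin`) and
#'   `solution` (an `lp_solution`: `flows` data frame with per-edge `flow`,
#'   named `slacks` vector, `objective`, `status`, `relaxed_nodes`,
#'   `clipped_edges`).
#' @examples
#' g <- dmin(data.frame(source = "A", target = "B", weight = 1),
#'           nodes = data.frame(mirna = c("A", "B"), expression = c(2, 2)))
#' optimize_edge_weights(g)$solution$objective  # 2: the sink's expression
#' @export
optimize_edge_weights <- function(network) {
  stopifnot(inherits(network, "dmin"))
  nodes <- network$nodes
  edges <- network$edges
  if (!nrow(edges))
    stop_validation("network has no edges to weight")
  if (anyNA(nodes$expression))
    stop_validation(sprintf(
      "node(s) without expression score: %s",
      paste(nodes$mirna[is.na(nodes$expression)], collapse = ", ")))
  e <- setNames(nodes$expression, nodes$mirna)
  if (any(e == 0))
    warning(sprintf(
      "zero-expression node(s) %s: their outgoing edges carry no influence",
      paste(names(e)[e == 0], collapse = ", ")))
  ids <- nodes$mirna
  n <- length(ids)
  m <- nrow(edges)

  indeg <- table(factor(edges$target, levels = ids))
  constrained <- ids[indeg > 0]
  relaxed <- ids[indeg == 0]

  # Detect the analytically forced infeasibility up front so the error can
  # name the violating node: every regulator of i has e_j = 0 but e_i > 0.
  for (v in constrained) {
    src <- edges$source[edges$target == v]
    if (all(e[src] == 0) && e[v] > 0)
      stop_infeasible(sprintf(
        "incoming constraint at node '%s' is unsatisfiable: its regulators all have zero expression but e = %g",
        v, e[v]))
  }

  # Variable layout: X (one per edge), then s+ and s- (one pair per node).
  nv <- m + 2L * n
  obj <- c(rep(0, m), rep(1, 2L * n))
  n_in <- length(constrained)
  A3 <- matrix(0, n_in + n, nv)
  b3 <- numeric(n_in + n)
  for (k in seq_along(constrained)) {
    v <- constrained[k]
    ix <- which(edges$target == v)
    A3[k, ix] <- e[edges$source[ix]]
    b3[k] <- e[v]
  }
  for (k in seq_len(n)) {
    v <- ids[k]
    ix <- which(edges$source == v)
    row <- n_in + k
    A3[row, ix] <- e[v]
    A3[row, m + k] <- 1          # s+
    A3[row, m + n + k] <- -1     # s-
    b3[row] <- e[v]
  }
  sol <- boot::simplex(a = obj, A3 = A3, b3 = b3, maxi = FALSE,
                       eps = 1e-8, n.iter = 50L * nv)
  if (sol$solved != 1)
    stop_infeasible(sprintf(
      "linear program did not reach an optimal solution (solver status %d)",
      sol$solved))
  x <- as.numeric(sol$soln)
  flows <- x[seq_len(m)]
  slacks <- setNames(x[m + seq_len(n)] - x[m + n + seq_len(n)], ids)

  clipped <- sum(flows > 1)
  if (clipped)
    message(sprintf("clipped %d flow(s) above 1 to 1 for use as probabilities",
                    clipped))
  out <- network
  out$edges$weight <- pmin(flows, 1)
  out$meta$weights_discarded <- NULL
  out$meta$weight_mode <- "optimize"
  out$meta$relaxed_nodes <- relaxed

  solution <- structure(list(
    flows = data.frame(source = edges$source, target = edges$target,
                       flow = flows, stringsAsFactors = FALSE),
    slacks = slacks,
    objective = sum(abs(slacks)),
    status = "optimal",
    relaxed_nodes = relaxed,
    clipped_edges = clipped), class = "lp_solution")
  list(network = out, solution = solution)
}

#' Rescore every edge to a constant weight
#'
#' Replaces all edge weights by one constant (default 0.01), discarding any
#' node-expression information from the weighting. This mode probes the
#' purely topological pressure points of the network: with equal, low
#' activation probability on every edge, only well-placed nodes accumulate
#' coverage. Low constants are preferred because on dense high-confidence
#' networks large probabilities let nearly every node activate the whole
#' graph, collapsing the ranking.
#'
#' @param network a `dmin`.
#' @param weight constant in (0, 1\]; default 0.01.
#' @return The rescored `dmin`; topology unchanged.
#' @export
rescore_constant <- function(network, weight = 0.01) {
  stopifnot(inherits(network, "dmin"))
  if (!is.numeric(weight) || length(weight) != 1 || is.na(weight) ||
      weight <= 0 || weight > 1)
    stop_validation("`weight` must be a single number in (0, 1]")
  out <- network
  out$edges$weight <- rep(weight, nrow(out$edges))
  out$meta$weights_discarded <- NULL
  out$meta$weight_mode <- "constant"
  out$meta$constant_weight <- weight
  out
}

#' Independently verify a flow solution against the network constraints
#'
#' Recomputes the residual of every Incoming and Outgoing constraint from
#' the solution's flows and slacks, without consulting the solver. Missing
#' flows are treated as zero and counted.
#'
#' @param network the `dmin` the solution was computed for.
#' @param sol an `lp_solution` with `status == "optimal"`.
#' @param tol residual tolerance; default `1e-6`.
#' @return A list: per-family residual vectors (`incoming`, `outgoing`),
#'   `objective_residual`, `max_residual`, `n_missing_flows`, and logical
#'   `pass`.
#' @export
verify_lp_solution <- function(network, sol, tol = 1e-6) {
  stopifnot(inherits(network, "dmin"), inherits(sol, "lp_solution"))
  if (!identical(sol$status, "optimal"))
    stop_validation("can only verify a solution with status 'optimal'")
  nodes <- network$nodes
  edges <- network$edges
  e <- setNames(nodes$expression, nodes$mirna)
  key_net <- edge_key(edges$source, edges$target)
  key_sol <- edge_key(sol$flows$source, sol$flows$target)
  flow <- setNames(rep(0, nrow(edges)), key_net)
  hit <- match(key_net, key_sol)
  flow[!is.na(hit)] <- sol$flows$flow[hit[!is.na(hit)]]
  n_missing <- sum(is.na(hit))

  ids <- nodes$mirna
  incoming <- outgoing <- setNames(numeric(0), character(0))
  for (v in ids) {
    ix_in <- which(edges$target == v)
    if (length(ix_in)) {
      lhs <- sum(e[edges$source[ix_in]] * flow[key_net[ix_in]])
      incoming[v] <- abs(lhs - e[v])
    }
    ix_out <- which(edges$source == v)
    s_v <- if (v %in% names(sol$slacks)) sol$slacks[[v]] else 0
    lhs <- e[[v]] * sum(flow[key_net[ix_out]]) + s_v
    outgoing[v] <- abs(lhs - e[[v]])
  }
  obj_res <- abs(sol$objective - sum(abs(sol$slacks)))
  max_res <- max(c(incoming, outgoing, obj_res, 0))
  list(incoming = incoming, outgoing = outgoing,
       objective_residual = obj_res, max_residual = max_res,
       n_missing_flows = n_missing,
       pass = max_res <= tol && n_missing == 0)
}
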