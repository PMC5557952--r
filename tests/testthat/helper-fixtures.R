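# Shared in-code fixtures: everything is generated, nothing is stored.

make_dmin <- function(source, target, weight, expression = NULL,
                      disease_id = "test") {
  edges <- data.frame(source = source, target = target, weight = weight,
                      stringsAsFactors = FALSE)
  nodes <- NULL
  if (!is.null(expression))
    nodes <- data.frame(mirna = names(expression),
                        expression = as.numeric(expression),
                        stringsAsFactors = FALSE)
  dmin(edges, nodes = nodes, disease_id = disease_id)
}

make_expression_table <- function(mirna, disease, fold_change) {
  out <- data.frame(mirna = mirna, disease = disease,
                    fold_change = fold_change,
                    regulation = "unspecified", study = NA_character_,
                    stringsAsFactors = FALSE)
  class(out) <- c("expression_table", "data.frame")
  out
}

write_expression_csv <- function(lines, path = tempfile(fileext = ".csv")) {
  writeLines(lines, path)
  path
}

# Random directed graph with at most `max_edges` edges and uniform(0,1)
# weights, sized for the exact live-edge oracle.
random_small_graph <- function(seed, max_nodes = 6, max_edges = 10) {
  set.seed(seed)
  n <- sample(3:max_nodes, 1)
  ids <- as.character(seq_len(n))
  pairs <- expand.grid(source = ids, target = ids, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, , drop = FALSE]
  keep <- which(runif(nrow(pairs)) < 0.35)
  if (length(keep) > max_edges) keep <- keep[seq_len(max_edges)]
  edges <- pairs[keep, , drop = FALSE]
  edges$weight <- runif(nrow(edges))
  nodes <- data.frame(mirna = ids, stringsAsFactors = FALSE)
  dmin(edges, nodes = nodes, disease_id = sprintf("small%d", seed))
}

# Random LP instance that is feasible by construction: a layered DAG where
# downstream expression is defined as the flow the chosen X values deliver,
# so the Incoming equalities hold exactly at those X.
random_feasible_instance <- function(seed, n_layers = 3, per_layer = 2) {
  set.seed(seed)
  layers <- split(sprintf("n%02d", seq_len(n_layers * per_layer)),
                  rep(seq_len(n_layers), each = per_layer))
  e <- setNames(runif(per_layer, 0.5, 3), layers[[1]])
  edges <- NULL
  for (l in seq_len(n_layers - 1)) {
    for (tgt in layers[[l + 1]]) {
      srcs <- sample(layers[[l]], sample(1:per_layer, 1))
      x <- runif(length(srcs), 0.1, 1)
      e[tgt] <- sum(e[srcs] * x)
      edges <- rbind(edges, data.frame(source = srcs, target = tgt,
                                       weight = 1, stringsAsFactors = FALSE))
    }
  }
  nodes <- data.frame(mirna = names(e), expression = as.numeric(e),
                      stringsAsFactors = FALSE)
  dmin(edges, nodes = nodes, disease_id = sprintf("lp%d", seed))
}

fig4_forced_outcomes <- function() {
  setNames(c(FALSE, TRUE, FALSE, TRUE, TRUE),
           c(edge_outcome_name("1", "2"), edge_outcome_name("1", "3"),
             edge_outcome_name("3", "4"), edge_outcome_name("3", "5"),
             edge_outcome_name("5", "4")))
}
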