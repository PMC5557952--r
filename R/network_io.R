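#' Write / read a DMIN as CSV
#'
#' The edge list is written to `path` with header `source,target,weight`.
#' If any node carries an expression score (or the graph has isolated
#' nodes), a companion node-annotation file with header `mirna,expression`
#' is written next to it, named by inserting `.nodes` before the extension.
#' Numbers are serialized with 15 significant digits so that a write/read
#' round trip preserves weights and expression scores to at least 12
#' significant digits.
#'
#' @param network a `dmin`.
#' @param path path of the edge CSV to write.
#' @return `write_network()` returns `path` invisibly; `read_network()`
#'   returns a `dmin`.
#' @examples
#' f <- file.path(tempdir(), "net.csv")
#' write_network(fig4_fixture(), f)
#' read_network(f)
#' @export
write_network <- function(network, path) {
  stopifnot(inherits(network, "dmin"))
  e <- network$edges
  df <- data.frame(source = e$source, target = e$target,
                   weight = format(e$weight, digits = 15, scientific = FALSE,
                                   trim = TRUE),
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  np <- nodes_path(path)
  isolated <- setdiff(network$nodes$mirna, c(e$source, e$target))
  if (any(!is.na(network$nodes$expression)) || length(isolated)) {
    nd <- data.frame(mirna = network$nodes$mirna,
                     expression = ifelse(is.na(network$nodes$expression), "",
                                         format(network$nodes$expression,
                                                digits = 15,
                                                scientific = FALSE, trim = TRUE)),
                     stringsAsFactors = FALSE)
    write.csv(nd, np, row.names = FALSE, quote = FALSE)
  } else if (file.exists(np)) {
    unlink(np)
  }
  invisible(path)
}

nodes_path <- function(path) {
  sub("(\\.[A-Za-z0-9]+)?$", ".nodes\\1", path)
}

#' @rdname write_network
#' @param disease_id disease identifier to stamp on the loaded network;
#'   defaults to the file name without extension.
#' @export
read_network <- function(path, disease_id = NULL) {
  if (!file.exists(path))
    stop_not_found(sprintf("network file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("source", "target", "weight"))
    if (!col %in% names(df))
      stop_format(sprintf("network file %s is missing column '%s'", path, col))
  w <- suppressWarnings(as.numeric(df$weight))
  bad <- which(is.na(w) | w < 0 | w > 1)
  if (length(bad))
    stop_format(sprintf(
      "%s: edge weight must be a number in [0, 1]; offending line(s): %s",
      path, paste(bad + 1L, collapse = ", ")))  # +1 for the header line
  edges <- data.frame(source = df$source, target = df$target, weight = w,
                      stringsAsFactors = FALSE)
  nodes <- NULL
  np <- nodes_path(path)
  if (file.exists(np)) {
    nd <- read.csv(np, stringsAsFactors = FALSE, colClasses = "character")
    for (col in c("mirna", "expression"))
      if (!col %in% names(nd))
        stop_format(sprintf("node file %s is missing column '%s'", np, col))
    expr <- suppressWarnings(as.numeric(nd$expression))
    bad <- which(!is.na(expr) & expr < 0)
    if (length(bad))
      stop_format(sprintf("%s: negative expression on line(s): %s",
                          np, paste(bad + 1L, collapse = ", ")))
    nodes <- data.frame(mirna = nd$mirna, expression = expr,
                        stringsAsFactors = FALSE)
  }
  if (is.null(disease_id))
    disease_id <- sub("\\.[A-Za-z0-9]+$", "", basename(path))
  dmin(edges, nodes = nodes, disease_id = disease_id)
}
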