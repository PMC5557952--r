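#' Group disease networks into a category
#'
#' Disease categories (e.g. gastrointestinal cancers, leukemias) group 1-5
#' weighted disease networks so that influence can be aggregated across
#' related conditions, either by edge-wise intersection or by cumulative
#' union of coverage percentages.
#'
#' @param category_id label for the category.
#' @param dmins list of 1-5 weighted `dmin` objects.
#' @param mode `"intersection"` or `"cumulative_union"`.
#' @param max_networks size cap, 5 by default to match the published tool's
#'   category builder; raise deliberately if needed.
#' @return A `category_spec`.
#' @export
category_spec <- function(category_id, dmins,
                          mode = c("intersection", "cumulative_union"),
                          max_networks = 5L) {
  mode <- match.arg(mode)
  if (!is.list(dmins) || !length(dmins) ||
      !all(vapply(dmins, inherits, logical(1), "dmin")))
    stop_validation("`dmins` must be a non-empty list of dmin objects")
  if (length(dmins) > max_networks)
    stop_validation(sprintf("a category holds at most %d disease networks, got %d",
                            max_networks, length(dmins)))
  structure(list(category_id = category_id, dmins = dmins, mode = mode),
            class = "category_spec")
}

#' Logical-AND / Intersection aggregation of a disease category
#'
#' Retains only the directed edges present (by exact endpoint identity) in
#' every member disease network; each retained edge's weight is the product
#' of its per-disease weights, i.e. the probability that the interaction
#' fires in all member diseases at once. Influence ranking is then computed
#' on the merged network, and every miRNA with positive mean coverage is
#' reported.
#'
#' @param spec a `category_spec` with at least two member networks.
#' @param n_sim Monte-Carlo cycles per node; default 10000.
#' @param seed master RNG seed.
#' @return A `category_result` with `ranking` (positive-coverage miRNAs),
#'   `merged_network`, `mode`, `category_id`.
#' @export
intersect_category <- function(spec, n_sim = 10000, seed = 1L) {
  stopifnot(inherits(spec, "category_spec"))
  nets <- spec$dmins
  if (length(nets) < 2)
    stop_validation("intersection needs at least 2 member networks")
  keys <- lapply(nets, function(g) edge_key(g$edges$source, g$edges$target))
  common <- Reduce(intersect, keys)
  if (!length(common)) {
    warning(sprintf("category '%s': no edge is shared by all %d networks",
                    spec$category_id, length(nets)))
    merged <- NULL
    ranking <- data.frame(mirna = character(), score = numeric(),
                          diseases_present = character(),
                          stringsAsFactors = FALSE)
  } else {
    base <- nets[[1]]$edges[match(common, keys[[1]]), c("source", "target")]
    wt <- rep(1, length(common))
    for (i in seq_along(nets))
      wt <- wt * nets[[i]]$edges$weight[match(common, keys[[i]])]
    merged <- dmin(data.frame(base, weight = wt, stringsAsFactors = FALSE),
                   disease_id = spec$category_id)
    res <- rank_all_nodes(merged, n_sim = n_sim, seed = seed)
    res <- res[res$mean_coverage > 0, , drop = FALSE]
    ranking <- data.frame(
      mirna = res$mirna,
      score = res$mean_coverage,
      diseases_present = vapply(res$mirna, function(m) paste(
        vapply(nets[vapply(nets, function(g) m %in% g$nodes$mirna, logical(1))],
               function(g) g$disease_id, character(1)), collapse = ";"),
        character(1)),
      stringsAsFactors = FALSE)
    rownames(ranking) <- NULL
  }
  structure(list(category_id = spec$category_id, mode = "intersection",
                 ranking = ranking, merged_network = merged),
            class = "category_result")
}

#' Cumulative-Union aggregation of a disease category
#'
#' Runs the full influence ranking within each member disease network, maps
#' each node's mean coverage to a percentage of that network's own node
#' count, averages the percentages of each miRNA over the diseases in which
#' it occurs (absent diseases do not contribute zeros), and ranks the
#' miRNAs by the averaged percentage, reporting the top `top_k`.
#'
#' @param spec a `category_spec` (one or more member networks).
#' @param n_sim Monte-Carlo cycles per node; default 10000.
#' @param seed master RNG seed.
#' @param top_k number of miRNAs to report; default 10.
#' @return A `category_result` with `ranking` (top `top_k` rows of
#'   `mirna`, `score`, `diseases_present`) and `per_disease` (the full
#'   per-disease percentage table).
#' @export
cumulative_union <- function(spec, n_sim = 10000, seed = 1L, top_k = 10L) {
  stopifnot(inherits(spec, "category_spec"))
  if (!is.numeric(top_k) || top_k < 1)
    stop_validation("`top_k` must be a positive integer")
  per <- do.call(rbind, lapply(spec$dmins, function(g) {
    r <- rank_all_nodes(g, n_sim = n_sim, seed = seed)
    data.frame(disease = g$disease_id, mirna = r$mirna,
               coverage_percentage = r$coverage_percentage,
               stringsAsFactors = FALSE)
  }))
  agg <- aggregate(coverage_percentage ~ mirna, data = per, FUN = mean)
  dz  <- aggregate(disease ~ mirna, data = per,
                   FUN = function(d) paste(sort(d), collapse = ";"))
  tab <- merge(agg, dz, by = "mirna")
  o <- order(-tab$coverage_percentage, tab$mirna, method = "radix")
  tab <- tab[o, , drop = FALSE]
  ranking <- data.frame(mirna = tab$mirna,
                        score = tab$coverage_percentage,
                        diseases_present = tab$disease,
                        stringsAsFactors = FALSE)[
    seq_len(min(top_k, nrow(tab))), , drop = FALSE]
  rownames(ranking) <- NULL
  structure(list(category_id = spec$category_id, mode = "cumulative_union",
                 ranking = ranking, per_disease = per),
            class = "category_result")
}

#' @export
print.category_result <- function(x, ...) {
  cat(sprintf("category '%s' (%s): %d ranked miRNA(s)\n",
              x$category_id, x$mode, nrow(x$ranking)))
  print(utils::head(x$ranking, 10))
  invisible(x)
}

#' Load disease networks and aggregate a category end to end
#'
#' Reads 1-5 weighted network CSVs (see [read_network()]), builds a
#' [category_spec()], dispatches on `mode`, and writes the ranking CSV
#' (`mirna,score,mode,diseases_present`) plus a provenance JSON recording
#' inputs, parameters and seed.
#'
#' @param network_paths character vector of 1-5 network CSV paths.
#' @param mode `"intersection"` or `"cumulative_union"`.
#' @param out_dir output directory (created if missing).
#' @param category_id label; default `"category"`.
#' @param n_sim,seed,top_k forwarded to the aggregation.
#' @return The `category_result`, invisibly; files are the main output.
#' @export
build_category <- function(network_paths,
                           mode = c("intersection", "cumulative_union"),
                           out_dir, category_id = "category",
                           n_sim = 10000, seed = 1L, top_k = 10L) {
  mode <- match.arg(mode)
  if (length(network_paths) > 5)
    stop_validation(sprintf(
      "a category combines at most 5 diseases, got %d", length(network_paths)))
  for (p in network_paths)
    if (!file.exists(p))
      stop_not_found(sprintf("cannot read network file: %s", p))
  nets <- lapply(network_paths, read_network)
  spec <- category_spec(category_id, nets, mode)
  res <- if (mode == "intersection")
    intersect_category(spec, n_sim = n_sim, seed = seed)
  else
    cumulative_union(spec, n_sim = n_sim, seed = seed, top_k = top_k)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rk <- res$ranking
  out <- data.frame(mirna = rk$mirna,
                    score = format(rk$score, digits = 15, trim = TRUE),
                    mode = mode,
                    diseases_present = rk$diseases_present,
                    stringsAsFactors = FALSE)
  csv <- file.path(out_dir, sprintf("%s_ranking.csv", category_id))
  write.csv(out, csv, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(category_id = category_id, mode = mode,
         inputs = as.character(network_paths),
         n_sim = as.integer(n_sim), seed = as.integer(seed),
         top_k = as.integer(top_k),
         input_md5 = vapply(network_paths, function(p)
           as.character(tools::md5sum(p)), character(1))),
    file.path(out_dir, sprintf("%s_provenance.json", category_id)),
    auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}
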