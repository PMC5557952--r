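#' Pipeline run configuration
#'
#' Bundles the tunable parameters of the end-to-end workflow. The defaults
#' are the method's standard operating point: confidence cutoff 0.90,
#' constant rescoring weight 0.01, 10000 Monte-Carlo cycles, top-10
#' reporting.
#'
#' @param threshold high-confidence edge cutoff in \[0, 1\].
#' @param weight_mode `"optimize"` (expression-driven LP) or `"constant"`.
#' @param constant_weight constant used in `"constant"` mode, in (0, 1\].
#' @param n_sim Monte-Carlo cycles per node.
#' @param rng_seed master RNG seed.
#' @param top_k miRNAs reported in summaries.
#' @return A validated `run_config` list.
#' @export
run_config <- function(threshold = 0.90,
                       weight_mode = c("optimize", "constant"),
                       constant_weight = 0.01,
                       n_sim = 10000, rng_seed = 1L, top_k = 10L) {
  weight_mode <- match.arg(weight_mode)
  if (!is.numeric(threshold) || threshold < 0 || threshold > 1)
    stop_validation("`threshold` must be in [0, 1]")
  if (!is.numeric(constant_weight) || constant_weight <= 0 || constant_weight > 1)
    stop_validation("`constant_weight` must be in (0, 1]")
  if (!is.numeric(n_sim) || n_sim < 1)
    stop_validation("`n_sim` must be a positive integer")
  if (!is.numeric(top_k) || top_k < 1)
    stop_validation("`top_k` must be a positive integer")
  structure(list(threshold = threshold, weight_mode = weight_mode,
                 constant_weight = constant_weight,
                 n_sim = as.integer(n_sim), rng_seed = as.integer(rng_seed),
                 top_k = as.integer(top_k)),
            class = "run_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    mc_stop(sprintf("stage %s: %s", name, conditionMessage(e)),
            "mircascade_stage_error")
  })
}

#' Run the full single-disease influence pipeline
#'
#' Composes the workflow: read the probabilistic edge list and the
#' expression table, extract the high-confidence subnetwork, attach
#' aggregated expression scores, weight the edges (LP optimization or
#' constant rescoring), and rank every node by Monte-Carlo coverage.
#' Outputs written to `out_dir`: `dmin_hc.csv` (filtered topology, with the
#' retained confidence scores), `dmin_hce.csv` (+ `.nodes.csv`) for the
#' weighted network, `ranking.csv`, and `provenance.json` (configuration
#' echo, input digests, and the warnings that matter for interpretation:
#' removed nodes, clipped flows, relaxed source nodes).
#'
#' @param config a [run_config()].
#' @param expression_path CSV for [read_expression_table()].
#' @param edges_path CSV for [read_network()] (confidence-weighted edges).
#' @param out_dir output directory, created if missing.
#' @param disease_id disease the run concerns; defaults to the edge file
#'   name.
#' @return Invisibly, a list with the ranking, the weighted network and the
#'   output paths. Identical config and seed give byte-identical outputs.
#' @export
run_pipeline <- function(config, expression_path, edges_path, out_dir,
                         disease_id = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  notes <- character()
  note <- function(w) { notes <<- c(notes, conditionMessage(w))
                        invokeRestart("muffleWarning") }

  tab <- stage("read_expression_table",
               read_expression_table(expression_path))
  raw <- stage("read_network", read_network(edges_path, disease_id = disease_id))
  hc <- stage("filter_high_confidence", withCallingHandlers(
    filter_high_confidence(raw, config$threshold), warning = note))
  hce <- stage("attach_expression", withCallingHandlers(
    attach_expression(hc, tab), warning = note))

  clipped <- 0L; relaxed <- character(); objective <- NA_real_
  weighted <- stage("edge_weighting", {
    if (config$weight_mode == "optimize") {
      fit <- withCallingHandlers(optimize_edge_weights(hce), warning = note)
      clipped <- fit$solution$clipped_edges
      relaxed <- fit$solution$relaxed_nodes
      objective <- fit$solution$objective
      fit$network
    } else {
      rescore_constant(hce, config$constant_weight)
    }
  })
  ranking <- stage("rank_all_nodes",
                   rank_all_nodes(weighted, n_sim = config$n_sim,
                                  seed = config$rng_seed))

  paths <- list(
    dmin_hc = file.path(out_dir, "dmin_hc.csv"),
    dmin_hce = file.path(out_dir, "dmin_hce.csv"),
    ranking = file.path(out_dir, "ranking.csv"),
    provenance = file.path(out_dir, "provenance.json"))
  hc_out <- hc
  hc_out$edges$weight <- hc_out$edges$confidence  # export retained confidences
  write_network(hc_out, paths$dmin_hc)
  write_network(weighted, paths$dmin_hce)
  rk <- data.frame(mirna = ranking$mirna,
                   mean_coverage = format(ranking$mean_coverage, digits = 15,
                                          trim = TRUE),
                   coverage_percentage = format(ranking$coverage_percentage,
                                                digits = 15, trim = TRUE),
                   rank = ranking$rank, stringsAsFactors = FALSE)
  write.csv(rk, paths$ranking, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(
    config = unclass(config),
    inputs = list(
      expression = expression_path, edges = edges_path,
      expression_md5 = as.character(tools::md5sum(expression_path)),
      edges_md5 = as.character(tools::md5sum(edges_path))),
    disease_id = weighted$disease_id,
    n_nodes = dmin_n(weighted), n_edges = nrow(weighted$edges),
    lp_objective = objective, clipped_edges = clipped,
    relaxed_nodes = as.character(relaxed),
    warnings = notes),
    paths$provenance, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(ranking = ranking, network = weighted, paths = paths,
                 status = 0L))
}
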