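#' Read a miRNA expression table from CSV
#'
#' The table records per-(miRNA, disease) fold-change observations.
#' A (miRNA, disease) pair may appear on several rows when several studies
#' report it; [aggregate_expression()] averages such replicates.
#'
#' Required columns: `mirna`, `disease`, `fold_change` (strictly positive).
#' Optional columns: `regulation` (one of `up`, `down`, `unspecified`) and
#' `study`.
#'
#' @param path path to a UTF-8, comma-delimited CSV file.
#' @return A data frame of class `expression_table` with columns `mirna`,
#'   `disease`, `fold_change`, `regulation`, `study`; row order preserved.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("mirna,disease,fold_change", "m1,d1,2.0", "m2,d1,8.0"), f)
#' read_expression_table(f)
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path))
    stop_not_found(sprintf("expression file not found: %s", path))
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  for (col in c("mirna", "disease", "fold_change"))
    if (!col %in% names(df))
      stop_format(sprintf("expression table %s is missing required column '%s'",
                          path, col))
  fc <- suppressWarnings(as.numeric(df$fold_change))
  bad <- which(is.na(fc) | fc <= 0)
  if (length(bad))
    stop_validation(sprintf(
      "fold_change must be a positive number; offending row(s): %s",
      paste(bad, collapse = ", ")))
  out <- data.frame(
    mirna = df$mirna,
    disease = df$disease,
    fold_change = fc,
    regulation = if ("regulation" %in% names(df)) df$regulation
                 else rep("unspecified", nrow(df)),
    study = if ("study" %in% names(df)) df$study else rep(NA_character_, nrow(df)),
    stringsAsFactors = FALSE)
  if (nrow(out)) {
    ok <- out$regulation %in% c("up", "down", "unspecified")
    if (!all(ok))
      stop_validation(sprintf(
        "regulation must be 'up', 'down' or 'unspecified'; offending row(s): %s",
        paste(which(!ok), collapse = ", ")))
  }
  class(out) <- c("expression_table", "data.frame")
  out
}

#' Aggregate replicated fold changes into one expression score
#'
#' Each matching record's fold change is log2-transformed, its magnitude is
#' taken, and the magnitudes are averaged arithmetically. The magnitude is
#' used because downstream influence modelling treats up- and down-regulation
#' symmetrically: a strongly down-regulated miRNA is as much a driver of its
#' neighbourhood as a strongly up-regulated one, and the flow formulation
#' requires nonnegative node scores. Taking magnitudes per record (rather
#' than of the averaged signed value) keeps replicates that disagree in
#' direction from cancelling to an artificial zero.
#'
#' @param table an `expression_table`.
#' @param mirna_id,disease_id the pair to aggregate.
#' @return Scalar expression score `mean(|log2 fold change|)`, with the
#'   mean of the signed log2 values attached as attribute `signed_log2fc`.
#' @examples
#' tab <- data.frame(mirna = c("m1", "m1"), disease = "d1",
#'                   fold_change = c(2, 8), regulation = "up", study = NA)
#' class(tab) <- c("expression_table", "data.frame")
#' aggregate_expression(tab, "m1", "d1")  # mean(1, 3) = 2
#' @export
aggregate_expression <- function(table, mirna_id, disease_id) {
  stopifnot(inherits(table, "expression_table"))
  hit <- table$mirna == mirna_id & table$disease == disease_id
  if (!any(hit))
    stop_not_found(sprintf("no expression record for (%s, %s)",
                           mirna_id, disease_id))
  l2 <- log2(table$fold_change[hit])
  structure(mean(abs(l2)), signed_log2fc = mean(l2))
}
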