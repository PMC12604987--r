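## Plain-text I/O: clinical CSV, gene-by-patient expression TSV, graph edge
## lists, risk scores, contours and rankings. All matrices are written with
## row ids in the first column so round-trips are lossless.

#' Read a clinical table CSV
#'
#' Expects columns `patient_id`, covariates, `time`, `event`.
#' @param path CSV path.
#' @return Data frame.
#' @export
read_clinical <- function(path) {
  cl <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_that(all(c("patient_id", "time", "event") %in% names(cl)),
              "clinical CSV needs patient_id, time and event columns")
  cl
}

#' Read a gene-by-patient expression TSV
#'
#' First column holds gene ids; remaining columns are patients.
#' @param path TSV path.
#' @param scale Scale tag to attach (`"raw"`, `"log2"`, `"standardized"`).
#' @return Numeric matrix with a `scale` attribute.
#' @export
read_expression <- function(path, scale = "log2") {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  attr(m, "scale") <- scale
  m
}

#' Write a gene-by-patient expression TSV
#' @param expr Matrix with gene rownames.
#' @param path Output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a patient graph as a TSV edge list
#' @param graph A `patient_graph`.
#' @param path Output path (columns source, target, weight, provenance).
#' @export
write_graph <- function(graph, path) {
  e <- graph$edges
  utils::write.table(
    data.frame(source = e$from, target = e$to, weight = e$weight,
               provenance = e$provenance),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a patient graph from a TSV edge list
#' @param path Edge-list path written by [write_graph()].
#' @param ids Optional full id universe (isolated ids are not representable
#'   in an edge list).
#' @return A `patient_graph`.
#' @export
read_graph <- function(path, ids = NULL) {
  e <- utils::read.delim(path, stringsAsFactors = FALSE)
  edges <- data.frame(from = e$source, to = e$target, weight = e$weight,
                      provenance = e$provenance, stringsAsFactors = FALSE)
  if (is.null(ids)) ids <- sort(unique(c(edges$from, edges$to)))
  new_patient_graph(ids, edges)
}

#' Write a synthetic cohort to a directory
#'
#' Writes `clinical.csv`, `expression.tsv`, `signatures.gmt` and
#' `ground_truth.json` (fractions, linear predictor, generator settings).
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$clinical, file.path(dir, "clinical.csv"),
                   row.names = FALSE)
  write_expression(cohort$expression, file.path(dir, "expression.tsv"))
  write_gmt(cohort$signatures, file.path(dir, "signatures.gmt"))
  gt <- list(
    true_fractions = as.data.frame(cohort$true_fractions),
    true_linear_predictor = as.list(cohort$true_linear_predictor),
    beta = as.list(cohort$config$beta),
    seed = cohort$config$seed)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Write risk scores as CSV
#' @param risk Named per-patient risk vector.
#' @param path Output path (columns patient_id, risk).
#' @export
write_risk <- function(risk, path) {
  utils::write.csv(data.frame(patient_id = names(risk), risk = as.numeric(risk)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a hazard contour as long-format CSV
#' @param contour A `hazard_contour`.
#' @param path Output path (columns gene, z_self, z_neigh, hazard).
#' @export
write_contour <- function(contour, path) {
  utils::write.csv(data.frame(gene = contour$gene, contour$surface),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write an attribution ranking as CSV
#' @param ranking An `attribution_ranking`.
#' @param path Output path (columns rank, gene, magnitude, class).
#' @export
write_ranking <- function(ranking, path) {
  tab <- ranking$table
  utils::write.csv(data.frame(rank = seq_len(nrow(tab)), gene = tab$gene,
                              magnitude = tab$magnitude, class = tab$class),
                   path, row.names = FALSE)
  invisible(path)
}
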