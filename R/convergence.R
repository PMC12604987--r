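## Rule-based companion statistics: reference-thresholded CNV-score tumour
## calling, relative-expression-ordering (REO) reversal testing with Fisher's
## exact test, dual-corroborated DEG filtering, multi-evidence gene-set
## convergence, and the immunohistochemistry composite score.

#' Threshold CNV scores against a normal reference
#'
#' Labels an observation `tumor` when its copy-number score strictly exceeds
#' the reference mean plus `k_sd` sample standard deviations. The single-cell
#' convention uses `k_sd = 1.5`; the spatial convention uses `k_sd = 2`.
#'
#' @param scores Named numeric vector of per-cell (or per-spot) CNV scores.
#' @param reference_ids Ids (>= 2) of the normal reference observations,
#'   all present in `scores`.
#' @param k_sd Positive multiplier on the reference standard deviation.
#' @return A `cnv_call_result`: data frame `calls` (`id`, `score`, `label`),
#'   `threshold`, `reference_ids`, `k_sd`.
#' @export
cnv_call <- function(scores, reference_ids, k_sd = 1.5) {
  assert_that(!is.null(names(scores)), "scores must be named by id")
  assert_that(all(reference_ids %in% names(scores)),
              "reference_ids must be a subset of the score ids")
  assert_that(length(reference_ids) >= 2,
              "need at least 2 reference observations")
  assert_that(is_scalar_num(k_sd) && k_sd > 0, "k_sd must be a positive real")
  ref <- scores[reference_ids]
  threshold <- mean(ref) + k_sd * stats::sd(ref)
  calls <- data.frame(id = names(scores), score = as.numeric(scores),
                      label = ifelse(scores > threshold, "tumor", "normal"),
                      stringsAsFactors = FALSE)
  structure(list(calls = calls, threshold = threshold,
                 reference_ids = reference_ids, k_sd = k_sd),
            class = "cnv_call_result")
}

## counts[a, b] = number of samples in which gene a < gene b (strict).
pairwise_below_counts <- function(mat) {
  G <- nrow(mat)
  counts <- matrix(0L, G, G, dimnames = list(rownames(mat), rownames(mat)))
  for (s in seq_len(ncol(mat))) {
    v <- mat[, s]
    counts <- counts + outer(v, v, `<`)
  }
  counts
}

#' Stable relative expression orderings in a reference condition
#'
#' An ordered gene pair `(a, b)` enters the background when `a < b` holds in
#' at least `stability_fraction` of reference samples; exact ties count
#' against stability. At most one orientation of a pair can qualify.
#'
#' @param reference_matrix Gene-by-sample matrix (>= 3 samples).
#' @param stability_fraction Required fraction in `(0.5, 1]`; default 0.99.
#' @return A `reo_background`: data frame `pairs` (`low`, `high`), `genes`,
#'   `stability_fraction`.
#' @export
reo_stable_pairs <- function(reference_matrix, stability_fraction = 0.99) {
  assert_that(ncol(reference_matrix) >= 3, "need at least 3 reference samples")
  assert_that(is_scalar_num(stability_fraction) && stability_fraction > 0.5 &&
                stability_fraction <= 1,
              "stability_fraction must lie in (0.5, 1]")
  counts <- pairwise_below_counts(reference_matrix)
  need <- stability_fraction * ncol(reference_matrix)
  keep <- which(counts >= need, arr.ind = TRUE)
  genes <- rownames(reference_matrix)
  pairs <- data.frame(low = genes[keep[, 1]], high = genes[keep[, 2]],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$low, pairs$high), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, genes = genes,
                 stability_fraction = stability_fraction),
            class = "reo_background")
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Standard two-sided convention: the p-value sums, over the hypergeometric
#' support with the observed margins, all tables whose point probability does
#' not exceed the observed table's. A table with any zero margin yields
#' `p = 1`.
#'
#' @param table 2x2 matrix of non-negative integers.
#' @return Two-sided p-value.
#' @export
fisher_exact <- function(table) {
  table <- as.matrix(table)
  assert_that(all(dim(table) == c(2L, 2L)), "table must be 2x2")
  assert_that(all(table >= 0) && all(table == round(table)),
              "table entries must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) return(1)
  stats::fisher.test(table)$p.value
}

#' REO rank-reversal differential expression test
#'
#' For each gene, partners from the stable background are split into
#' (gene below partner) vs (gene above partner), the same split is recomputed
#' from orderings stable in the case samples, and the resulting 2x2 table is
#' tested with Fisher's exact test. P-values are Benjamini-Hochberg adjusted
#' across genes. Direction is `up` when the gene gains above-partner
#' relations in cases, `down` when it loses them, `ambiguous` on exact ties.
#' A gene with no background partners is reported with `p = 1` and flagged.
#'
#' @param case_matrix Gene-by-sample case matrix sharing the background's
#'   gene universe.
#' @param background A `reo_background` from [reo_stable_pairs()].
#' @param stability_fraction Stability required of case orderings; defaults
#'   to the background's fraction.
#' @return A `reo_result` data frame: per gene the table counts
#'   (`ref_below`, `ref_above`, `case_below`, `case_above`), `p`, `q`,
#'   `direction`, `no_partners`.
#' @export
reo_reversal_test <- function(case_matrix, background,
                              stability_fraction = NULL) {
  assert_that(inherits(background, "reo_background"),
              "background must come from reo_stable_pairs()")
  genes <- background$genes
  assert_that(all(genes %in% rownames(case_matrix)),
              "case matrix must cover the background gene universe")
  if (is.null(stability_fraction)) {
    stability_fraction <- background$stability_fraction
  }
  case_counts <- pairwise_below_counts(case_matrix[genes, , drop = FALSE])
  need <- stability_fraction * ncol(case_matrix)
  case_stable <- case_counts >= need  # [a, b]: a < b stable in cases

  pr <- background$pairs
  res <- data.frame(gene = genes, ref_below = 0L, ref_above = 0L,
                    case_below = 0L, case_above = 0L, p = 1,
                    direction = "ambiguous", no_partners = TRUE,
                    stringsAsFactors = FALSE)
  rownames(res) <- genes
  below_partners <- split(pr$high, factor(pr$low, levels = genes))
  above_partners <- split(pr$low, factor(pr$high, levels = genes))
  for (g in genes) {
    lo <- below_partners[[g]]  # partners g is stably below in reference
    hi <- above_partners[[g]]  # partners g is stably above in reference
    partners <- c(lo, hi)
    if (!length(partners)) next
    res[g, "no_partners"] <- FALSE
    res[g, "ref_below"] <- length(lo)
    res[g, "ref_above"] <- length(hi)
    cb <- sum(case_stable[g, partners])
    ca <- sum(case_stable[partners, g])
    res[g, "case_below"] <- cb
    res[g, "case_above"] <- ca
    tab <- matrix(c(length(lo), length(hi), cb, ca), nrow = 2, byrow = TRUE)
    res[g, "p"] <- fisher_exact(tab)
    ref_prop <- length(hi) / length(partners)
    case_tot <- cb + ca
    case_prop <- if (case_tot > 0) ca / case_tot else ref_prop
    res[g, "direction"] <- if (case_prop > ref_prop) "up"
      else if (case_prop < ref_prop) "down" else "ambiguous"
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  rownames(res) <- NULL
  class(res) <- c("reo_result", "data.frame")
  res
}

#' Dual-corroborated differentially expressed genes
#'
#' Exact intersection of two DEG calls (e.g. a moderated-linear-model call
#' and a REO reversal call); only genes supported by both are retained.
#'
#' @param set_a,set_b Gene-id vectors.
#' @return Sorted character vector of genes present in both.
#' @export
corroborated_degs <- function(set_a, set_b) {
  sort(intersect(unique(as.character(set_a)), unique(as.character(set_b))))
}

#' Converge evidence layers to a core gene set
#'
#' Builds a gene-by-layer membership table over >= 2 named evidence layers
#' and reports the exact all-layer intersection as the core set, plus
#' per-gene layer counts for near-core inspection. An empty layer is allowed
#' (the core is then empty) with a warning.
#'
#' @param layers Named list of gene-id vectors.
#' @return An `evidence_ledger`: `membership` (logical gene x layer matrix),
#'   `core` (genes in all layers), `layer_counts` (named integer per gene).
#' @export
intersect_evidence <- function(layers) {
  assert_that(is.list(layers) && length(layers) >= 2 && !is.null(names(layers)),
              "layers must be a named list with at least 2 elements")
  empty <- names(layers)[lengths(layers) == 0]
  if (length(empty)) {
    warning("empty evidence layer(s): ", paste(empty, collapse = ", "))
  }
  genes <- sort(unique(unlist(layers, use.names = FALSE)))
  membership <- vapply(layers, function(l) genes %in% l,
                       logical(length(genes)))
  if (length(genes) == 1L) membership <- matrix(membership, nrow = 1)
  rownames(membership) <- genes
  counts <- if (length(genes)) rowSums(membership) else integer(0)
  core <- genes[counts == length(layers)]
  structure(list(membership = membership, core = core,
                 layer_counts = stats::setNames(as.integer(counts), genes)),
            class = "evidence_ledger")
}

#' Immunohistochemistry composite score
#'
#' Product of staining intensity (0 = negative to 3 = strong) and the
#' proportion-of-positive-cells category (1: <10%, 2: 11-50%, 3: 51-80%,
#' 4: >80%), giving a composite score between 0 and 12.
#'
#' @param intensity Integer(s) in 0..3.
#' @param proportion_category Integer(s) in 1..4.
#' @return Integer score(s) in 0..12.
#' @export
ihc_score <- function(intensity, proportion_category) {
  assert_that(all(intensity %in% 0:3),
              "intensity must be an integer between 0 and 3")
  assert_that(all(proportion_category %in% 1:4),
              "proportion_category must be an integer between 1 and 4")
  as.integer(intensity) * as.integer(proportion_category)
}
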