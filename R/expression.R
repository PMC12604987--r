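## Expression-side preprocessing for the survival model: one-vs-rest marker
## selection by rank-sum test, leakage-free standardization using training-set
## statistics, and the binary gene-by-signature mask feeding the projector.

#' Cell-type marker selection by Wilcoxon rank-sum test
#'
#' For each group label, genes are tested one-vs-rest with a two-sided
#' Wilcoxon rank-sum test on the log2 scale; a gene is retained as a marker
#' when its log2 fold-change (mean difference) exceeds `log2fc_min` and its
#' Benjamini-Hochberg adjusted p-value (across genes, within group) is below
#' `alpha`.
#'
#' @param expr Gene-by-sample matrix on the log2 scale.
#' @param labels Group label per column.
#' @param log2fc_min Minimum log2 fold-change (default 1).
#' @param alpha Adjusted p-value threshold (default 0.05).
#' @return Named list (one element per group) of marker gene-id vectors; a
#'   `signature_set`.
#' @export
wilcoxon_markers <- function(expr, labels, log2fc_min = 1, alpha = 0.05) {
  labels <- as.character(labels)
  assert_that(length(labels) == ncol(expr),
              "labels must have one entry per expression column")
  groups <- sort(unique(labels))
  for (g in groups) {
    assert_that(sum(labels == g) >= 2, "group '", g, "' has fewer than 2 members")
  }
  assert_that(length(labels) - min(table(labels)) >= 2,
              "the rest group must have at least 2 members")
  out <- stats::setNames(vector("list", length(groups)), groups)
  for (g in groups) {
    in_g <- labels == g
    lfc <- rowMeans(expr[, in_g, drop = FALSE]) -
      rowMeans(expr[, !in_g, drop = FALSE])
    if (!is.finite(log2fc_min)) {
      out[[g]] <- character(0)
      next
    }
    pv <- apply(expr, 1L, function(x) {
      stats::wilcox.test(x[in_g], x[!in_g], exact = FALSE)$p.value
    })
    qv <- stats::p.adjust(pv, method = "BH")
    out[[g]] <- rownames(expr)[lfc > log2fc_min & qv < alpha]
  }
  structure(out, class = "signature_set")
}

#' Standardize expression using training-set statistics
#'
#' Per-gene mean and sample standard deviation are computed on the training
#' patients only and applied to every column, so that validation and test
#' patients never leak into the scaling. A gene with zero training variance
#' is standardized to zeros with a warning.
#'
#' @param expr Gene-by-patient matrix on the log2 scale (attribute
#'   `scale = "log2"` if present must not be `"standardized"`).
#' @param train_ids Patient ids defining the statistics.
#' @return Standardized matrix with attributes `scale = "standardized"`,
#'   `center` and `scale_sd` (the training statistics).
#' @export
standardize_train <- function(expr, train_ids) {
  assert_that(length(train_ids) >= 1, "train_ids must be non-empty")
  assert_that(all(train_ids %in% colnames(expr)),
              "train_ids must be expression columns")
  sc <- attr(expr, "scale", exact = TRUE)
  assert_that(is.null(sc) || sc != "standardized",
              "expression is already standardized")
  tr <- expr[, train_ids, drop = FALSE]
  mu <- rowMeans(tr)
  sd_ <- apply(tr, 1L, stats::sd)
  zero_var <- !is.finite(sd_) | sd_ == 0
  if (any(zero_var)) {
    warning(sum(zero_var), " gene(s) with zero training variance standardized to zeros")
  }
  sd_adj <- ifelse(zero_var, 1, sd_)
  z <- (expr - mu) / sd_adj
  z[zero_var, ] <- 0
  attr(z, "scale") <- "standardized"
  attr(z, "center") <- mu
  attr(z, "scale_sd") <- sd_
  z
}

#' Binary gene-by-signature mask
#'
#' Restricts each signature to the measured gene universe and encodes
#' membership as a binary matrix; every signature must keep at least 3 genes
#' after restriction.
#'
#' @param signatures Named list of gene-id vectors (a `signature_set`).
#' @param genes Measured gene universe (rownames of the expression matrix).
#' @return Binary `genes x signatures` matrix.
#' @export
signature_mask <- function(signatures, genes) {
  assert_that(is.list(signatures) && !is.null(names(signatures)),
              "signatures must be a named list")
  M <- matrix(0, nrow = length(genes), ncol = length(signatures),
              dimnames = list(genes, names(signatures)))
  for (s in names(signatures)) {
    kept <- intersect(signatures[[s]], genes)
    assert_that(length(kept) >= 3,
                "signature '", s, "' has fewer than 3 measured genes")
    M[kept, s] <- 1
  }
  M
}

#' Read a GMT gene-set file
#'
#' @param path GMT path (set name, description, member genes per line).
#' @return Named list of gene-id vectors (`signature_set`).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    assert_that(length(parts) >= 3, "malformed GMT line: ", substr(ln, 1, 40))
    out[[parts[1]]] <- parts[-(1:2)]
  }
  structure(out, class = "signature_set")
}

#' Write a GMT gene-set file
#'
#' @param signatures Named list of gene-id vectors.
#' @param path Output path.
#' @export
write_gmt <- function(signatures, path) {
  lines <- vapply(names(signatures), function(s) {
    paste(c(s, s, signatures[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
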