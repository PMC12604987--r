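## Gene-level hazard attribution. For each gene, a "hazard contour" probes
## the trained network over a grid of (own standardized expression,
## graph-neighbourhood standardized expression): a probe cohort is built in
## which every patient carries the gene at value a, the probe patient's
## neighbours carry it at value b, and all other genes sit at their cohort
## means; the probe patient's predicted risk is recorded per grid cell. The
## fitted least-squares slope of risk along the (1,1)/sqrt(2) diagonal — the
## hazard vector — classifies the gene as risk-enhancing (RMHZ: high
## expression, high hazard), risk-mitigating (MHZ: low expression, high
## hazard) or neutral.
##
## Attention is restricted to graph neighbourhoods, so the probe patient's
## output after L transformer layers depends only on patients within graph
## distance L; contours are therefore evaluated exactly on that induced
## subgraph.

## Patient whose graph degree equals the cohort median (deterministic
## tie-break by ascending id).
median_degree_patient <- function(graph) {
  nb <- graph_neighbors(graph)
  deg <- lengths(nb)
  med <- stats::median(deg)
  cand <- names(deg)[abs(deg - med) == min(abs(deg - med))]
  sort(cand)[1L]
}

## Ball of radius L around a node, plus the induced patient_graph.
neighborhood_ball <- function(graph, center, radius) {
  nb <- graph_neighbors(graph)
  seen <- center
  frontier <- center
  for (r in seq_len(radius)) {
    nxt <- setdiff(unique(unlist(nb[frontier], use.names = FALSE)), seen)
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  ids <- sort(seen)
  e <- graph$edges
  keep <- e$from %in% ids & e$to %in% ids
  sub <- structure(list(ids = ids, edges = e[keep, , drop = FALSE]),
                   class = "patient_graph")
  sub
}

contour_context <- function(model, expr, graph) {
  if (is.function(model)) {
    Z <- expr
    sc <- attr(expr, "scale", exact = TRUE)
    assert_that(!is.null(sc) && sc == "standardized",
                "function models require standardized expression")
    list(fun = model, Z = Z, graph = graph, probe = median_degree_patient(graph))
  } else {
    assert_that(inherits(model, "ctg_model"), "model must be a ctg_model or function")
    Z <- apply_model_scaling(model, expr)
    probe <- median_degree_patient(graph)
    ball <- neighborhood_ball(graph, probe, model$config$n_layers)
    list(model = model, Z = Z[, graph$ids, drop = FALSE], graph = graph,
         probe = probe, ball = ball, B_sub = attention_bias(ball))
  }
}

contour_eval <- function(ctx, gene, grid) {
  pts <- expand.grid(z_self = grid, z_neigh = grid, KEEP.OUT.ATTRS = FALSE)
  if (!is.null(ctx$fun)) {
    ids <- ctx$graph$ids
    base <- rowMeans(ctx$Z[, ids, drop = FALSE])
    nbrs <- graph_neighbors(ctx$graph)[[ctx$probe]]
    Xb <- matrix(base, nrow = length(ids), ncol = length(base), byrow = TRUE,
                 dimnames = list(ids, rownames(ctx$Z)))
    p_idx <- match(ctx$probe, ids)
    hz <- vapply(seq_len(nrow(pts)), function(r) {
      X <- Xb
      X[, gene] <- pts$z_self[r]
      X[nbrs, gene] <- pts$z_neigh[r]
      ctx$fun(X, ctx$graph)[p_idx]
    }, numeric(1))
  } else {
    ids <- ctx$ball$ids
    base <- rowMeans(ctx$Z)
    Xb <- matrix(base, nrow = length(ids), ncol = length(base), byrow = TRUE,
                 dimnames = list(ids, names(base)))
    nbrs <- intersect(graph_neighbors(ctx$graph)[[ctx$probe]], ids)
    p_idx <- match(ctx$probe, ids)
    gcol <- match(gene, colnames(Xb))
    n_idx <- match(nbrs, ids)
    cfg <- ctx$model$config
    hz <- vapply(seq_len(nrow(pts)), function(r) {
      X <- Xb
      X[, gcol] <- pts$z_self[r]
      X[n_idx, gcol] <- pts$z_neigh[r]
      network_forward(ctx$model$params, X, ctx$model$mask, ctx$B_sub, cfg,
                      training = FALSE)$risk[p_idx]
    }, numeric(1))
  }
  pts$hazard <- hz
  pts
}

ls_slope <- function(pts) {
  s <- (pts$z_self + pts$z_neigh) / sqrt(2)
  sc <- s - mean(s)
  sum(sc * (pts$hazard - mean(pts$hazard))) / sum(sc^2)
}

#' Hazard contour of a gene over (own, neighbourhood) expression
#'
#' @param model A trained `ctg_model`, or a function `f(X, graph)` mapping a
#'   patient-by-gene standardized matrix to per-patient risk (useful for
#'   analytic surrogates).
#' @param expr Gene-by-patient expression covering the model genes.
#' @param graph A connected `patient_graph`.
#' @param gene Gene id to probe.
#' @param grid Standardized-expression grid for each axis; default 41 steps
#'   over `[-2, 2]`.
#' @param neutral_band Slope magnitude below which the gene is `neutral`;
#'   default 0.05.
#' @return A `hazard_contour`: `gene`, `surface` (data frame `z_self`,
#'   `z_neigh`, `hazard`), `slope` (least-squares slope along the hazard
#'   diagonal), `class`, `probe` (probe patient id).
#' @export
hazard_contour <- function(model, expr, graph, gene,
                           grid = seq(-2, 2, length.out = 41),
                           neutral_band = 0.05) {
  gene_universe <- if (is.function(model)) rownames(expr) else model$genes
  assert_that(gene %in% gene_universe, "unknown gene: ", gene)
  ctx <- contour_context(model, expr, graph)
  pts <- contour_eval(ctx, gene, grid)
  slope <- ls_slope(pts)
  out <- structure(list(gene = gene, surface = pts, slope = slope,
                        probe = ctx$probe),
                   class = "hazard_contour")
  out$class <- classify_direction(out, neutral_band)
  out
}

#' Classify a hazard contour as risk-enhancing or risk-mitigating
#'
#' Slope above `neutral_band` means high expression drives high hazard
#' (`"RMHZ"`); slope below `-neutral_band` means low expression drives high
#' hazard (`"MHZ"`); otherwise `"neutral"`.
#'
#' @param contour A `hazard_contour` (or anything with a `slope` element).
#' @param neutral_band Positive slope threshold; default 0.05.
#' @return `"RMHZ"`, `"MHZ"` or `"neutral"`.
#' @export
classify_direction <- function(contour, neutral_band = 0.05) {
  assert_that(is_scalar_num(neutral_band) && neutral_band >= 0,
              "neutral_band must be a non-negative real")
  slope <- contour$slope
  if (slope > neutral_band) "RMHZ"
  else if (slope < -neutral_band) "MHZ"
  else "neutral"
}

#' Rank genes by hazard-contour attribution
#'
#' Computes every gene's contour slope, partitions genes into risk-enhancing
#' and risk-mitigating classes, and reports the top-`top_k` of each by
#' attribution magnitude `|slope|` (ties broken by gene id).
#'
#' @inheritParams hazard_contour
#' @param genes Genes to attribute; default the model's whole universe.
#' @param top_k List length per class; default 20.
#' @return An `attribution_ranking`: `table` (gene, slope, magnitude, class,
#'   sorted by descending magnitude), `top_enhancers`, `top_mitigators`.
#' @export
rank_genes <- function(model, expr, graph, genes = NULL, top_k = 20L,
                       grid = seq(-2, 2, length.out = 41),
                       neutral_band = 0.05) {
  universe <- if (is.function(model)) rownames(expr) else model$genes
  if (is.null(genes)) genes <- universe
  assert_that(all(genes %in% universe), "genes outside the model universe")
  assert_that(is_count(top_k), "top_k must be a positive integer")
  ctx <- contour_context(model, expr, graph)
  slopes <- vapply(genes, function(g) ls_slope(contour_eval(ctx, g, grid)),
                   numeric(1))
  cls <- vapply(slopes, function(s) {
    classify_direction(list(slope = s), neutral_band)
  }, character(1))
  tab <- data.frame(gene = genes, slope = slopes, magnitude = abs(slopes),
                    class = cls, stringsAsFactors = FALSE)
  tab <- tab[order(-tab$magnitude, tab$gene), ]
  rownames(tab) <- NULL
  top_of <- function(cl) {
    sub <- tab[tab$class == cl, , drop = FALSE]
    utils::head(sub, top_k)
  }
  structure(list(table = tab, top_enhancers = top_of("RMHZ"),
                 top_mitigators = top_of("MHZ"), probe = ctx$probe),
            class = "attribution_ranking")
}

#' @export
print.attribution_ranking <- function(x, ...) {
  cat(sprintf("attribution_ranking: %d genes (%d RMHZ, %d MHZ, %d neutral)\n",
              nrow(x$table), sum(x$table$class == "RMHZ"),
              sum(x$table$class == "MHZ"), sum(x$table$class == "neutral")))
  invisible(x)
}
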