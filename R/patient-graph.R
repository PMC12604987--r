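## Clinical patient-similarity graph: mixed-feature preprocessing, Gower
## distance, self-tuning (local-scaling) Gaussian kernels, multi-view fusion,
## mutual-kNN sparsification, and a minimum-spanning-tree backbone that
## guarantees a single connected component.

#' Preprocess a clinical table for similarity computation
#'
#' Applies a declared per-feature transform: `"minmax"` maps a numeric
#' feature to `[0, 1]` (a constant feature maps to all zeros with a warning),
#' `"rank"` maps to `(rank - 1) / (n - 1)` using average ranks for ties, and
#' `"onehot"` expands a categorical feature to indicator columns. Missing
#' numeric values are median-imputed; missing categorical values become an
#' explicit `"missing"` level.
#'
#' @param clinical Data frame with a unique `patient_id` column; `time` /
#'   `event` columns are carried through untouched and excluded from features.
#' @param scaling Named character vector mapping feature name to
#'   `"minmax"`, `"rank"` or `"onehot"`. Unnamed features default to
#'   `"minmax"` for numerics and `"onehot"` for categoricals.
#' @return A `clinical_features` object with elements `ids`, `matrix`
#'   (numeric, one-hot expanded, rows ordered by sorted id), `gower` (data
#'   frame of scaled numerics and factor categoricals for Gower distance) and
#'   `kinds` (per-column `"numeric"` / `"categorical"` for `gower`).
#' @export
preprocess_clinical <- function(clinical, scaling = NULL) {
  assert_that(is.data.frame(clinical) && "patient_id" %in% names(clinical),
              "clinical must be a data frame with a patient_id column")
  assert_that(!anyDuplicated(clinical$patient_id), "patient ids must be unique")
  ord <- order(clinical$patient_id)
  clinical <- clinical[ord, , drop = FALSE]
  ids <- as.character(clinical$patient_id)
  feat_names <- setdiff(names(clinical), c("patient_id", "time", "event"))
  assert_that(length(feat_names) > 0, "no clinical features to preprocess")
  n <- nrow(clinical)

  num_cols <- list()
  gower_cols <- list()
  kinds <- character()
  for (f in feat_names) {
    v <- clinical[[f]]
    is_num <- is.numeric(v)
    method <- if (!is.null(scaling) && f %in% names(scaling)) scaling[[f]]
              else if (is_num) "minmax" else "onehot"
    assert_that(method %in% c("minmax", "rank", "onehot"),
                "unknown scaling method '", method, "' for feature ", f)
    if (method %in% c("minmax", "rank")) {
      assert_that(is_num, "feature ", f, " must be numeric for ", method)
      assert_that(!all(is.na(v)), "feature ", f, " is entirely missing")
      if (anyNA(v)) v[is.na(v)] <- stats::median(v, na.rm = TRUE)
      if (method == "minmax") {
        rng <- range(v)
        if (rng[1] == rng[2]) {
          warning("constant numeric feature '", f, "' mapped to all zeros")
          sv <- rep(0, n)
        } else {
          sv <- (v - rng[1]) / (rng[2] - rng[1])
        }
      } else {
        sv <- if (n == 1L) 0 else (rank(v, ties.method = "average") - 1) / (n - 1)
      }
      num_cols[[f]] <- sv
      gower_cols[[f]] <- sv
      kinds[f] <- "numeric"
    } else {
      v <- as.character(v)
      assert_that(!all(is.na(v)), "feature ", f, " is entirely missing")
      v[is.na(v)] <- "missing"
      lv <- sort(unique(v))
      for (l in lv) num_cols[[paste0(f, "=", l)]] <- as.numeric(v == l)
      gower_cols[[f]] <- factor(v, levels = lv)
      kinds[f] <- "categorical"
    }
  }
  X <- do.call(cbind, num_cols)
  rownames(X) <- ids
  gdf <- as.data.frame(gower_cols, optional = TRUE)
  rownames(gdf) <- ids
  structure(list(ids = ids, matrix = X, gower = gdf, kinds = kinds),
            class = "clinical_features")
}

#' Gower distance over mixed preprocessed features
#'
#' `D[i, j]` is the mean over features of the per-feature dissimilarity:
#' numeric columns contribute `|x_i - x_j| / range` with the range fixed at 1
#' for pre-scaled columns, categorical columns contribute 0/1 mismatch.
#' Features missing in either patient are skipped; a pair with no comparable
#' feature raises an error naming the pair.
#'
#' @param features A `clinical_features` object, or a data frame of scaled
#'   numeric and factor columns.
#' @param kinds Per-column `"numeric"` / `"categorical"`; taken from
#'   `features` when it is a `clinical_features` object.
#' @return A `distance_view`: list with `ids`, symmetric matrix `D` (zero
#'   diagonal, entries in `[0, 1]`) and `metric_name = "gower"`.
#' @export
gower_distance <- function(features, kinds = NULL) {
  if (inherits(features, "clinical_features")) {
    kinds <- features$kinds
    df <- features$gower
  } else {
    df <- features
    if (is.null(kinds)) {
      kinds <- ifelse(vapply(df, is.numeric, logical(1)),
                      "numeric", "categorical")
      names(kinds) <- names(df)
    }
  }
  n <- nrow(df)
  assert_that(n >= 2, "need at least 2 patients")
  ids <- rownames(df)
  if (is.null(ids)) ids <- as.character(seq_len(n))

  total <- matrix(0, n, n)
  count <- matrix(0L, n, n)
  for (j in seq_along(df)) {
    v <- df[[j]]
    obs <- !is.na(v)
    comp <- outer(obs, obs, `&`)
    if (kinds[[j]] == "numeric") {
      d <- abs(outer(as.numeric(v), as.numeric(v), `-`))
    } else {
      code <- as.integer(factor(as.character(v)))
      d <- (outer(code, code, `!=`)) * 1
    }
    d[!comp] <- 0
    total <- total + d
    count <- count + comp
  }
  diag(count) <- pmax(diag(count), 1L)  # self-pairs trivially comparable
  bad <- which(count == 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_ctg("no comparable features for patient pair (",
             ids[bad[1, 1]], ", ", ids[bad[1, 2]], ")",
             class = "ctgsurv_gower_error")
  }
  D <- total / count
  diag(D) <- 0
  dimnames(D) <- list(ids, ids)
  structure(list(ids = ids, D = D, metric_name = "gower"),
            class = "distance_view")
}

local_scales <- function(D, k_local) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) sort(D[i, -i])[k_local], numeric(1))
}

#' Self-tuning local-scaling similarity kernel
#'
#' `S[i, j] = exp(-D[i, j]^2 / (sigma_i * sigma_j))` where `sigma_i` is the
#' distance from patient `i` to its `k_local`-th nearest neighbour. Scales are
#' floored at the smallest positive off-diagonal distance times 1e-3 so that
#' duplicated patients yield similarity 1 rather than 0/0.
#'
#' @param dist A `distance_view`.
#' @param k_local Neighbour index used for the per-patient scale (`< n`).
#' @return A `similarity_view`: `ids`, matrix `S` in `[0, 1]` with unit
#'   diagonal, `view_name`, and the `sigma` vector as an attribute.
#' @export
local_scaling_kernel <- function(dist, k_local = 5L) {
  assert_that(inherits(dist, "distance_view"), "dist must be a distance_view")
  D <- dist$D
  n <- nrow(D)
  assert_that(is_count(k_local) && k_local < n,
              "k_local must be a positive integer below the number of patients")
  sigma <- local_scales(D, k_local)
  off <- D[upper.tri(D)]
  pos <- off[off > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1
  sigma <- pmax(sigma, eps)
  S <- exp(-D^2 / outer(sigma, sigma))
  diag(S) <- 1
  dimnames(S) <- dimnames(D)
  structure(list(ids = dist$ids, S = S,
                 view_name = paste0("local_scaling_k", k_local),
                 sigma = sigma),
            class = "similarity_view")
}

#' Fuse similarity views by a normalized weighted mean
#'
#' Element-wise convex combination of similarity matrices sharing the same
#' patient ids, with weights normalized to sum to one.
#'
#' @param views List of `similarity_view` objects over identical ids.
#' @param weights Non-negative weights, not all zero (default equal).
#' @return A fused `similarity_view`.
#' @export
fuse_views <- function(views, weights = NULL) {
  assert_that(is.list(views) && length(views) >= 1, "views must be a list")
  ids <- views[[1]]$ids
  for (v in views) {
    assert_that(inherits(v, "similarity_view"), "each view must be a similarity_view")
    assert_that(identical(v$ids, ids), "views must share identical patient ids")
  }
  if (is.null(weights)) weights <- rep(1, length(views))
  assert_that(length(weights) == length(views) && all(weights >= 0) &&
                sum(weights) > 0,
              "weights must be non-negative and not all zero")
  w <- weights / sum(weights)
  S <- Reduce(`+`, Map(function(v, wi) wi * v$S, views, w))
  diag(S) <- 1
  structure(list(ids = ids, S = S, view_name = "fused"),
            class = "similarity_view")
}

## k most similar patients to i, ties at rank k broken by ascending id.
knn_lists <- function(S, k) {
  ids <- rownames(S)
  n <- nrow(S)
  lapply(seq_len(n), function(i) {
    others <- setdiff(seq_len(n), i)
    ord <- others[order(-S[i, others], ids[others])]
    ord[seq_len(min(k, length(ord)))]
  })
}

#' Mutual k-nearest-neighbour edge set
#'
#' Retains edge `(i, j)` iff `j` is among the `k` most similar patients to
#' `i` and vice versa; edge weight is `S[i, j]`. Ties at rank `k` are broken
#' by ascending patient id for determinism.
#'
#' @param sim A `similarity_view`.
#' @param k Neighbourhood size (`< n`); default 5.
#' @return Data frame with columns `from`, `to` (id strings, `from < to`),
#'   `weight`, `provenance = "mutual_knn"`.
#' @export
build_mutual_knn <- function(sim, k = 5L) {
  assert_that(inherits(sim, "similarity_view"), "sim must be a similarity_view")
  S <- sim$S
  n <- nrow(S)
  assert_that(is_count(k) && k < n, "k must be a positive integer below n")
  ids <- sim$ids
  nbr <- knn_lists(S, k)
  from <- integer(); to <- integer()
  for (i in seq_len(n)) {
    for (j in nbr[[i]]) {
      if (j > i && i %in% nbr[[j]]) {
        from <- c(from, i); to <- c(to, j)
      }
    }
  }
  data.frame(from = ids[from], to = ids[to],
             weight = if (length(from)) S[cbind(from, to)] else numeric(0),
             provenance = rep("mutual_knn", length(from)),
             stringsAsFactors = FALSE)
}

## Deterministic Kruskal MST: edges sorted by (distance, id-pair) lexicographic.
kruskal_mst <- function(D) {
  ids <- rownames(D)
  n <- nrow(D)
  if (n < 2) return(data.frame(from = character(0), to = character(0),
                               d = numeric(0), stringsAsFactors = FALSE))
  ut <- which(upper.tri(D), arr.ind = TRUE)
  ed <- data.frame(i = ut[, 1], j = ut[, 2], d = D[ut],
                   stringsAsFactors = FALSE)
  ed <- ed[order(ed$d, ids[ed$i], ids[ed$j]), ]
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  keep <- logical(nrow(ed))
  taken <- 0L
  for (e in seq_len(nrow(ed))) {
    ri <- find(ed$i[e]); rj <- find(ed$j[e])
    if (ri != rj) {
      parent[ri] <- rj
      keep[e] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  ed <- ed[keep, , drop = FALSE]
  data.frame(from = ids[ed$i], to = ids[ed$j], d = ed$d,
             stringsAsFactors = FALSE)
}

#' Add a minimum-spanning-tree backbone to a mutual-kNN edge set
#'
#' Unions the mutual-kNN edges with the edges of a deterministic Kruskal MST
#' on the distance matrix, guaranteeing a single connected component. MST-only
#' edges are flagged `mst_backbone` and weighted `exp(-d^2 / sigma_bar^2)`
#' with `sigma_bar` the median local scale, keeping all weights on the
#' similarity scale `(0, 1]`.
#'
#' @param edges Mutual-kNN edge data frame from [build_mutual_knn()].
#' @param dist The `distance_view` covering all patients.
#' @param sigma Optional per-patient local scales (from
#'   [local_scaling_kernel()]); recomputed from `dist` with `k_local` when
#'   absent.
#' @param k_local Fallback neighbour index for recomputing scales.
#' @return A connected `patient_graph`: `ids`, `edges` data frame
#'   (`from`, `to`, `weight`, `provenance`), adjacency index.
#' @export
add_mst_backbone <- function(edges, dist, sigma = NULL, k_local = 5L) {
  assert_that(inherits(dist, "distance_view"), "dist must be a distance_view")
  ids <- dist$ids
  n <- length(ids)
  if (n <= 1L) {
    return(new_patient_graph(ids, edges[0, , drop = FALSE]))
  }
  if (is.null(sigma)) sigma <- local_scales(dist$D, min(k_local, n - 1L))
  off <- dist$D[upper.tri(dist$D)]
  pos <- off[off > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1
  sigma_bar <- max(stats::median(sigma), eps)
  mst <- kruskal_mst(dist$D)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- key(edges$from, edges$to)
  extra <- mst[!(key(mst$from, mst$to) %in% have), , drop = FALSE]
  if (nrow(extra)) {
    w <- exp(-extra$d^2 / sigma_bar^2)
    extra_df <- data.frame(from = pmin(extra$from, extra$to),
                           to = pmax(extra$from, extra$to),
                           weight = w, provenance = "mst_backbone",
                           stringsAsFactors = FALSE)
    edges <- rbind(edges, extra_df)
  }
  new_patient_graph(ids, edges)
}

new_patient_graph <- function(ids, edges) {
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  assert_that(all(edges$from %in% ids) && all(edges$to %in% ids),
              "edge endpoints must be known patient ids")
  assert_that(all(edges$from != edges$to), "self-loops are not allowed")
  assert_that(all(edges$weight > 0), "edge weights must be positive")
  g <- structure(list(ids = ids, edges = edges), class = "patient_graph")
  assert_that(is_connected(g), "patient graph must be connected",
              class = "ctgsurv_connectivity_error")
  g
}

#' Test connectivity of a patient graph
#'
#' @param graph A `patient_graph`.
#' @return TRUE iff the graph has a single connected component (a single
#'   isolated node counts as connected).
#' @export
is_connected <- function(graph) {
  n <- length(graph$ids)
  if (n <= 1L) return(TRUE)
  if (!nrow(graph$edges)) return(FALSE)
  ig <- igraph::graph_from_data_frame(graph$edges[, c("from", "to")],
                                      directed = FALSE,
                                      vertices = data.frame(name = graph$ids))
  igraph::is_connected(ig)
}

#' Adjacency (neighbour) lists of a patient graph
#'
#' @param graph A `patient_graph`.
#' @return Named list mapping each patient id to the character vector of its
#'   neighbours' ids.
#' @export
graph_neighbors <- function(graph) {
  nb <- stats::setNames(vector("list", length(graph$ids)), graph$ids)
  for (i in seq_along(nb)) nb[[i]] <- character(0)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    nb[[e$from[r]]] <- c(nb[[e$from[r]]], e$to[r])
    nb[[e$to[r]]] <- c(nb[[e$to[r]]], e$from[r])
  }
  nb
}

#' @export
print.patient_graph <- function(x, ...) {
  cat(sprintf("patient_graph: %d patients, %d edges (%d mutual-kNN, %d MST backbone)\n",
              length(x$ids), nrow(x$edges),
              sum(x$edges$provenance == "mutual_knn"),
              sum(x$edges$provenance == "mst_backbone")))
  invisible(x)
}

#' Build a clinical patient-similarity graph end to end
#'
#' Convenience wrapper chaining [preprocess_clinical()], [gower_distance()],
#' [local_scaling_kernel()], [build_mutual_knn()] and [add_mst_backbone()].
#'
#' @inheritParams preprocess_clinical
#' @param k Mutual-kNN neighbourhood size (default 5, the number of nearest
#'   neighbours retained per patient).
#' @param k_local Neighbour index for the local-scaling kernel.
#' @return A connected `patient_graph`.
#' @export
build_patient_graph <- function(clinical, scaling = NULL, k = 5L,
                                k_local = 5L) {
  feats <- preprocess_clinical(clinical, scaling)
  n <- length(feats$ids)
  k <- min(k, n - 1L)
  k_local <- min(k_local, n - 1L)
  dv <- gower_distance(feats)
  sv <- local_scaling_kernel(dv, k_local)
  edges <- build_mutual_knn(sv, k)
  add_mst_backbone(edges, dv, sigma = sv$sigma, k_local = k_local)
}

#' Mean expression of a gene over graph neighbours
#'
#' For each patient, the unweighted mean of the gene's value over that
#' patient's graph neighbours (self excluded). Connectivity of the graph
#' guarantees every patient has at least one neighbour whenever `n >= 2`.
#'
#' @param graph A `patient_graph`.
#' @param expr Gene-by-patient matrix covering the graph's ids.
#' @param gene Gene id present in `expr`.
#' @return Named numeric vector over the graph's patients.
#' @export
neighborhood_mean <- function(graph, expr, gene) {
  assert_that(gene %in% rownames(expr), "unknown gene: ", gene)
  assert_that(all(graph$ids %in% colnames(expr)),
              "expression matrix must cover all graph patients")
  v <- expr[gene, graph$ids]
  nb <- graph_neighbors(graph)
  out <- vapply(graph$ids, function(id) {
    if (!length(nb[[id]])) return(NA_real_)
    mean(v[nb[[id]]])
  }, numeric(1))
  stats::setNames(out, graph$ids)
}
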