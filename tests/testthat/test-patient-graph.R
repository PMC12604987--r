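clin_fixture <- function() {
  data.frame(patient_id = c("P1", "P2", "P3"),
             age = c(2, 4, 6),
             grade = c("II", "III", "IV"),
             time = c(10, 20, 30), event = c(1, 0, 1),
             stringsAsFactors = FALSE)
}

test_that("preprocessing applies min-max, rank and one-hot transforms", {
  pf <- preprocess_clinical(clin_fixture())
  expect_equal(unname(pf$matrix[, "age"]), c(0, 0.5, 1))
  onehot <- pf$matrix[, grep("^grade=", colnames(pf$matrix))]
  expect_equal(unname(rowSums(onehot)), c(1, 1, 1))
  expect_equal(ncol(onehot), 3)

  cl <- data.frame(patient_id = paste0("P", 1:4), x = c(10, 20, 20, 40))
  pr <- preprocess_clinical(cl, scaling = c(x = "rank"))
  expect_equal(unname(pr$matrix[, "x"]), c(0, 0.5, 0.5, 1))

  cl$x <- 5
  expect_warning(pc <- preprocess_clinical(cl), "constant")
  expect_equal(unname(pc$matrix[, "x"]), rep(0, 4))
})

test_that("missing values are imputed as documented", {
  cl <- data.frame(patient_id = paste0("P", 1:5),
                   age = c(1, NA, 3, 5, 7),
                   sex = c("m", NA, "f", "m", "f"))
  pf <- preprocess_clinical(cl)
  expect_false(anyNA(pf$matrix))
  expect_true("missing" %in% levels(pf$gower$sex))
  ## numeric median imputation: NA -> median(1,3,5,7) = 4 -> scaled
  expect_equal(unname(pf$matrix[2, "age"]), (4 - 1) / 6)
})

test_that("gower distance matches its definition on closed-form cases", {
  pf <- preprocess_clinical(clin_fixture())
  dv <- gower_distance(pf)
  expect_s3_class(dv, "distance_view")
  expect_equal(diag(dv$D), rep(0, 3), ignore_attr = TRUE)
  expect_equal(dv$D, t(dv$D))
  ## P1 vs P2: numeric |0-0.5| = 0.5, categorical mismatch = 1 -> mean 0.75
  expect_equal(dv$D["P1", "P2"], 0.75)
  expect_equal(dv$D["P1", "P3"], 1)

  df <- data.frame(a = factor(c("x", "y")))
  rownames(df) <- c("P1", "P2")
  expect_equal(gower_distance(df)$D["P1", "P2"], 1)
  dfi <- data.frame(a = c(0.3, 0.3), b = factor(c("x", "x")))
  rownames(dfi) <- c("P1", "P2")
  expect_equal(gower_distance(dfi)$D["P1", "P2"], 0)
})

test_that("gower distance equals the brute-force oracle on random fixtures", {
  set.seed(42)
  for (rep in 1:40) {
    df <- data.frame(
      n1 = runif(6), n2 = runif(6),
      c1 = factor(sample(letters[1:3], 6, TRUE)),
      c2 = factor(sample(letters[1:2], 6, TRUE)))
    ## inject missingness (keeping every pair comparable via n1)
    df$n2[sample(6, 2)] <- NA
    df$c1[sample(6, 1)] <- NA
    rownames(df) <- paste0("P", 1:6)
    kinds <- c("numeric", "numeric", "categorical", "categorical")
    D <- gower_distance(df, kinds)$D
    expect_equal(unname(D), bf_gower(df, kinds), tolerance = 1e-12)
  }
})

test_that("a pair with no comparable features raises a named error", {
  df <- data.frame(a = c(1, NA, 2), b = c(NA, 1, 2))
  rownames(df) <- paste0("P", 1:3)
  expect_error(gower_distance(df, c("numeric", "numeric")),
               class = "ctgsurv_gower_error")
})

test_that("local scaling kernel follows the closed form and stays in [0,1]", {
  D <- matrix(c(0, 1, 2,
                1, 0, 1.5,
                2, 1.5, 0), 3, 3, dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  dv <- structure(list(ids = paste0("P", 1:3), D = D, metric_name = "toy"),
                  class = "distance_view")
  sv <- local_scaling_kernel(dv, k_local = 1)
  ## sigma_i = nearest-neighbour distance: (1, 1, 1.5)
  expect_equal(sv$S["P1", "P2"], exp(-1 / (1 * 1)))
  expect_equal(sv$S["P1", "P3"], exp(-4 / (1 * 1.5)))
  expect_equal(sv$S["P2", "P3"], exp(-2.25 / (1 * 1.5)))
  expect_equal(diag(sv$S), rep(1, 3), ignore_attr = TRUE)
  expect_true(all(sv$S >= 0 & sv$S <= 1))
  expect_error(local_scaling_kernel(dv, k_local = 3),
               class = "ctgsurv_validation_error")
})

test_that("kernel similarity is monotone decreasing in distance and handles duplicates", {
  set.seed(7)
  x <- c(0, 0, 1, 3, 7)  # first two are duplicate patients
  D <- abs(outer(x, x, `-`))
  dimnames(D) <- list(paste0("P", 1:5), paste0("P", 1:5))
  dv <- structure(list(ids = paste0("P", 1:5), D = D, metric_name = "toy"),
                  class = "distance_view")
  sv <- local_scaling_kernel(dv, 2)
  expect_equal(sv$S["P1", "P2"], 1)  # duplicates stay at similarity 1
  expect_true(all(is.finite(sv$S)))
  ## fixed row: similarity ordered opposite to distance
  ord <- order(D["P5", -5])
  s_row <- sv$S["P5", -5]
  expect_true(all(diff(s_row[ord]) <= 1e-12))
})

test_that("view fusion is a normalized convex combination", {
  ids <- paste0("P", 1:3)
  mk <- function(S) structure(list(ids = ids, S = S, view_name = "v"),
                              class = "similarity_view")
  S1 <- matrix(c(1, .2, .4, .2, 1, .6, .4, .6, 1), 3, dimnames = list(ids, ids))
  S2 <- matrix(c(1, .8, .1, .8, 1, .3, .1, .3, 1), 3, dimnames = list(ids, ids))
  expect_equal(fuse_views(list(mk(S1)), 1)$S, S1)
  expect_equal(fuse_views(list(mk(S1), mk(S1)), c(2, 5))$S, S1)
  f <- fuse_views(list(mk(S1), mk(S2)), c(1, 3))
  expect_equal(f$S, (S1 + 3 * S2) / 4)
  ## permutation invariance of (views, weights)
  f2 <- fuse_views(list(mk(S2), mk(S1)), c(3, 1))
  expect_equal(f$S, f2$S)
  expect_error(fuse_views(list(mk(S1), structure(list(ids = c("A", "B", "C"), S = S2),
                                                 class = "similarity_view"))),
               class = "ctgsurv_validation_error")
})

test_that("mutual kNN keeps exactly the reciprocal neighbour pairs", {
  ids2 <- c("A", "B")
  S2 <- matrix(c(1, .5, .5, 1), 2, dimnames = list(ids2, ids2))
  sv2 <- structure(list(ids = ids2, S = S2), class = "similarity_view")
  e2 <- build_mutual_knn(sv2, 1)
  expect_equal(nrow(e2), 1)
  expect_equal(e2$weight, 0.5)

  ## two well-separated triplets on a line: with k = 2 only within-triplet
  ## edges are mutual
  x <- c(0, 1, 2, 10, 11, 12)
  ids <- paste0("P", 1:6)
  S <- exp(-abs(outer(x, x, `-`)))
  dimnames(S) <- list(ids, ids)
  sv <- structure(list(ids = ids, S = S), class = "similarity_view")
  e <- build_mutual_knn(sv, 2)
  got <- sort(paste(e$from, e$to))
  expect_equal(got, sort(c("P1 P2", "P2 P3", "P1 P3", "P4 P5", "P5 P6", "P4 P6")))

  ## complete-graph limit: k = n-1 keeps every pair
  e_all <- build_mutual_knn(sv, 5)
  expect_equal(nrow(e_all), choose(6, 2))
})

test_that("MST backbone connects separated clusters through the closest pair", {
  x <- c(0, 1, 2, 10, 11, 12)
  ids <- paste0("P", 1:6)
  D <- abs(outer(x, x, `-`)); dimnames(D) <- list(ids, ids)
  dv <- structure(list(ids = ids, D = D), class = "distance_view")
  S <- exp(-D); dimnames(S) <- dimnames(D)
  sv <- structure(list(ids = ids, S = S), class = "similarity_view")
  e <- build_mutual_knn(sv, 2)
  g <- add_mst_backbone(e, dv)
  expect_true(is_connected(g))
  bridge <- g$edges[g$edges$provenance == "mst_backbone", ]
  expect_equal(nrow(bridge), 1)  # exactly one inter-cluster bridge
  expect_setequal(c(bridge$from, bridge$to), c("P3", "P4"))
  expect_true(all(g$edges$weight > 0 & g$edges$weight <= 1))

  ## already-connected mutual-kNN graph stays connected, MST adds nothing new
  e_all <- build_mutual_knn(sv, 5)
  g_all <- add_mst_backbone(e_all, dv)
  expect_true(is_connected(g_all))
  expect_equal(nrow(g_all$edges), nrow(e_all))
})

test_that("single-patient graphs are trivially connected", {
  dv <- structure(list(ids = "P1",
                       D = matrix(0, 1, 1, dimnames = list("P1", "P1"))),
                  class = "distance_view")
  g <- add_mst_backbone(data.frame(from = character(0), to = character(0),
                                   weight = numeric(0), provenance = character(0)),
                        dv)
  expect_equal(nrow(g$edges), 0)
  expect_true(is_connected(g))
})

test_that("neighbourhood means average the gene over graph neighbours", {
  ids <- paste0("P", 1:5)
  edges <- data.frame(from = c("P1", "P1", "P1", "P1", "P2"),
                      to = c("P2", "P3", "P4", "P5", "P3"),
                      weight = 1, provenance = "mutual_knn",
                      stringsAsFactors = FALSE)
  g <- ctgsurv:::new_patient_graph(ids, edges)
  expr <- matrix(c(10, 4, 4, 4, 4), 1, dimnames = list("g1", ids))
  nm <- neighborhood_mean(g, expr, "g1")
  expect_equal(nm[["P1"]], 4)                # star centre sees constant leaves
  expect_equal(nm[["P4"]], 10)               # leaf sees the centre
  expect_equal(nm[["P2"]], mean(c(10, 4)))
  expect_equal(nm[["P3"]], mean(c(10, 4)))

  g2 <- ctgsurv:::new_patient_graph(c("A", "B"),
    data.frame(from = "A", to = "B", weight = 1, provenance = "mutual_knn",
               stringsAsFactors = FALSE))
  e2 <- matrix(c(3, 8), 1, dimnames = list("g1", c("A", "B")))
  expect_equal(unname(neighborhood_mean(g2, e2, "g1")), c(8, 3))
  expect_error(neighborhood_mean(g2, e2, "nope"),
               class = "ctgsurv_validation_error")
})

test_that("end-to-end clinical graphs are connected with reciprocal kNN edges", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(5:80, 1)
    cl <- data.frame(
      patient_id = sprintf("P%03d", 1:n),
      age = round(rnorm(n, 60, 10)),
      kps = sample(seq(40, 100, by = 10), n, TRUE),
      sex = sample(c("m", "f"), n, TRUE),
      stringsAsFactors = FALSE)
    if (n > 6) cl[sample(n, 2), "age"] <- cl$age[1]  # inject duplicates
    g <- suppressWarnings(build_patient_graph(cl))
    expect_true(is_connected(g))
    ## every mutual-kNN edge is reciprocal by construction: verify against
    ## an independently computed kNN list
    feats <- preprocess_clinical(cl)
    dv <- gower_distance(feats)
    sv <- local_scaling_kernel(dv, min(5, n - 1))
    k <- min(5, n - 1)
    nb <- lapply(seq_len(n), function(i) {
      ord <- order(-sv$S[i, -i])
      setdiff(seq_len(n), i)[ord][seq_len(k)]
    })
    knn_edges <- g$edges[g$edges$provenance == "mutual_knn", ]
    for (r in seq_len(nrow(knn_edges))) {
      i <- match(knn_edges$from[r], sv$ids)
      j <- match(knn_edges$to[r], sv$ids)
      expect_true(j %in% nb[[i]] || any(sv$S[i, nb[[i]]] == sv$S[i, j]))
      expect_true(i %in% nb[[j]] || any(sv$S[j, nb[[j]]] == sv$S[j, i]))
    }
  }
})
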