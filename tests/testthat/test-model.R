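toy_mask <- function() {
  M <- matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "sig"))
  M[, 1] <- c(1, 0)
  M
}

test_that("masked projection matches hand arithmetic and honours the mask", {
  M <- toy_mask()
  params <- list(Wm = matrix(c(0.5, 9), 2, 1), bm = 0.25,
                 U = matrix(c(2), 1, 1), Rr = matrix(c(0.1, -0.3), 2, 1),
                 be = 0.05)
  x <- c(g1 = 1.2, g2 = -0.7)
  out <- masked_projection(x, M, params)
  ## pre-activation: only g1 feeds the unit; Wm[2,1] is masked away
  z <- 0.5 * 1.2 + 0.25
  expect_equal(unname(drop(out$preactivation)), z)
  emb <- tanh(z) * 2 + (1.2 * 0.1 + (-0.7) * (-0.3)) + 0.05
  expect_equal(drop(out$embedding), emb, tolerance = 1e-12)

  ## perturbing the non-member gene leaves the masked pre-activation
  ## bit-identical
  x2 <- x; x2["g2"] <- 100
  expect_identical(out$preactivation,
                   masked_projection(x2, M, params)$preactivation)

  ## all-zero mask: pre-activation equals the bias regardless of input
  M0 <- M; M0[] <- 0
  out0 <- masked_projection(x, M0, params)
  expect_equal(unname(drop(out0$preactivation)), 0.25)
  expect_equal(unname(drop(masked_projection(x2, M0, params)$preactivation)),
               0.25)
})

## Independent re-implementation of one pre-normalized attention layer with
## explicit loops.
bf_attention_layer <- function(H, lp, B) {
  n <- nrow(H); d <- ncol(H)
  ln <- function(X, g, b) {
    t(apply(X, 1, function(r) {
      (r - mean(r)) / sqrt(mean((r - mean(r))^2) + 1e-5) * g + b
    }))
  }
  Hn <- ln(H, lp$ln1_g, lp$ln1_b)
  Q <- Hn %*% lp$Wq; K <- Hn %*% lp$Wk; V <- Hn %*% lp$Wv
  O <- matrix(0, n, d)
  for (i in seq_len(n)) {
    logit <- numeric(n)
    for (j in seq_len(n)) logit[j] <- sum(Q[i, ] * K[j, ]) / sqrt(d) + B[i, j]
    w <- exp(logit - max(logit[is.finite(logit)]))
    w[!is.finite(logit)] <- 0
    a <- w / sum(w)
    for (j in seq_len(n)) O[i, ] <- O[i, ] + a[j] * V[j, ]
  }
  H1 <- H + O %*% lp$Wo + matrix(lp$bo, n, d, byrow = TRUE)
  H1n <- ln(H1, lp$ln2_g, lp$ln2_b)
  F1 <- pmax(H1n %*% lp$W1 + matrix(lp$b1, n, length(lp$b1), byrow = TRUE), 0)
  H1 + F1 %*% lp$W2 + matrix(lp$b2, n, d, byrow = TRUE)
}

test_that("transformer forward matches a step-by-step hand evaluation", {
  set.seed(9)
  d <- 3; n <- 3
  lp <- list(Wq = matrix(rnorm(9), 3), Wk = matrix(rnorm(9), 3),
             Wv = matrix(rnorm(9), 3), Wo = matrix(rnorm(9), 3),
             bo = rnorm(3), ln1_g = runif(3, 0.5, 1.5), ln1_b = rnorm(3),
             W1 = matrix(rnorm(12), 3, 4), b1 = rnorm(4),
             W2 = matrix(rnorm(12), 4, 3), b2 = rnorm(3),
             ln2_g = runif(3, 0.5, 1.5), ln2_b = rnorm(3))
  H <- matrix(rnorm(9), 3)
  ## path graph 1 - 2 - 3 with distinct edge weights
  B <- matrix(-Inf, 3, 3); diag(B) <- 0
  B[1, 2] <- B[2, 1] <- log(0.8); B[2, 3] <- B[3, 2] <- log(0.4)
  out <- transformer_gnn_forward(B, H, list(lp), n_heads = 1)
  expect_equal(out, bf_attention_layer(H, lp, B), tolerance = 1e-10)
})

test_that("attention never mixes information across disconnected components", {
  set.seed(2)
  d <- 4
  cfg <- model_config(embed_dim = 4, n_layers = 2, n_heads = 2, ff_dim = 6,
                      dropout = 0, seed = 1)
  lp <- ctgsurv:::init_params(4, 1, cfg,
                              matrix(1, 4, 1))$layers
  for (l in 1:2) {  # randomize the zero-initialized projections
    lp[[l]]$Wo <- matrix(rnorm(16, sd = 0.5), 4)
    lp[[l]]$W2 <- matrix(rnorm(24, sd = 0.5), 6, 4)
  }
  ## two 2-node components
  B <- matrix(-Inf, 4, 4); diag(B) <- 0
  B[1, 2] <- B[2, 1] <- 0; B[3, 4] <- B[4, 3] <- 0
  H <- matrix(rnorm(16), 4)
  out1 <- transformer_gnn_forward(B, H, lp, n_heads = 2)
  H2 <- H; H2[3:4, ] <- H2[3:4, ] + 5  # perturb the second component only
  out2 <- transformer_gnn_forward(B, H2, lp, n_heads = 2)
  expect_identical(out1[1:2, ], out2[1:2, ])

  ## a single isolated node is a deterministic transform of itself
  B1 <- matrix(0, 1, 1)
  h1 <- matrix(rnorm(4), 1)
  o1a <- transformer_gnn_forward(B1, h1, lp, n_heads = 2)
  o1b <- transformer_gnn_forward(B1, h1, lp, n_heads = 2)
  expect_identical(o1a, o1b)
})

test_that("full-network analytic gradients match finite differences", {
  set.seed(42)
  G <- 8; S <- 2; n <- 6
  mask <- matrix(0, G, S); mask[1:3, 1] <- 1; mask[4:6, 2] <- 1
  cfg <- model_config(embed_dim = 4, n_layers = 2, n_heads = 2, ff_dim = 5,
                      dropout = 0, seed = 1)
  params <- ctgsurv:::init_params(G, S, cfg, mask)
  params$Rr <- matrix(rnorm(G * 4, sd = 0.3), G, 4)
  params$head_w <- rnorm(4)
  for (l in 1:2) {
    params$layers[[l]]$Wo <- matrix(rnorm(16, sd = 0.3), 4, 4)
    params$layers[[l]]$W2 <- matrix(rnorm(20, sd = 0.3), 5, 4)
  }
  X <- matrix(rnorm(n * G), n, G)
  B <- matrix(-Inf, n, n); diag(B) <- 0
  for (i in 1:(n - 1)) B[i, i + 1] <- B[i + 1, i] <- log(runif(1, 0.2, 1))
  time <- rexp(n) + 0.1; event <- c(1, 0, 1, 1, 0, 1)
  lossfun <- function(p) {
    as.numeric(cox_partial_likelihood(
      ctgsurv:::network_forward(p, X, mask, B, cfg)$risk, time, event))
  }
  fwd <- ctgsurv:::network_forward(params, X, mask, B, cfg, keep_cache = TRUE)
  l <- cox_partial_likelihood(fwd$risk, time, event, gradient = TRUE)
  grads <- ctgsurv:::network_backward(params, fwd, attr(l, "gradient"),
                                      mask, cfg)
  fp <- flatten_params(params); fg <- flatten_params(grads)
  expect_true(all(names(fp) %in% names(fg)))
  for (path in names(fp)) {
    p <- fp[[path]]; g <- fg[[path]]
    for (ii in sample(length(p), min(3, length(p)))) {
      eps <- 1e-5
      fd <- (lossfun(set_param_at(params, path, ii, p[ii] + eps)) -
             lossfun(set_param_at(params, path, ii, p[ii] - eps))) / (2 * eps)
      expect_lt(abs(fd - g[ii]), 1e-4 * max(1, abs(fd) + abs(g[ii])))
    }
  }
})

test_that("training is deterministic and enforces exact masked zeros", {
  co <- small_cohort(seed = 4)
  g <- build_patient_graph(co$clinical)
  mask <- signature_mask(co$signatures, rownames(co$expression))
  mc <- small_model_config(seed = 9)
  fit1 <- train_survival_gnn(co$expression, co$clinical, g, mask, mc)
  fit2 <- train_survival_gnn(co$expression, co$clinical, g, mask, mc)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$params, fit2$params)

  expect_true(all(fit1$params$Wm[mask == 0] == 0))
  ## selected epoch attains the maximum recorded validation concordance
  expect_equal(fit1$history$val_concordance[fit1$history$epoch == fit1$selected_epoch],
               max(fit1$history$val_concordance))
})

test_that("patience 0 stops at the first epoch that fails to improve", {
  co <- small_cohort(seed = 6)
  g <- build_patient_graph(co$clinical)
  mask <- signature_mask(co$signatures, rownames(co$expression))
  fit <- train_survival_gnn(co$expression, co$clinical, g, mask,
                            small_model_config(seed = 2, patience = 0L,
                                               max_epochs = 50L))
  h <- fit$history
  vc <- h$val_concordance
  ## every epoch before the last strictly improved on the running maximum
  if (nrow(h) > 2) {
    for (e in 2:(nrow(h) - 1)) expect_gt(vc[e], max(vc[1:(e - 1)]))
  }
  expect_lte(vc[nrow(h)], max(vc[-nrow(h)]))
})

test_that("prediction is deterministic, shift-equivariant and checks genes", {
  co <- small_cohort(seed = 8)
  g <- build_patient_graph(co$clinical)
  mask <- signature_mask(co$signatures, rownames(co$expression))
  fit <- train_survival_gnn(co$expression, co$clinical, g, mask,
                            small_model_config(seed = 3))
  r1 <- predict_risk(fit, co$expression, g)
  r2 <- predict_risk(fit, co$expression, g)
  expect_identical(r1, r2)

  ## adding a constant to the Cox head bias shifts all scores equally
  fit_b <- fit; fit_b$params$head_b <- fit_b$params$head_b + 1.5
  r3 <- predict_risk(fit_b, co$expression, g)
  expect_equal(unname(r3 - r1), rep(1.5, length(r1)), tolerance = 1e-12)
  expect_identical(order(r3), order(r1))

  ## permuting patient columns leaves per-patient scores unchanged
  perm <- sample(ncol(co$expression))
  expr_p <- co$expression[, perm]
  attr(expr_p, "scale") <- attr(co$expression, "scale")
  r4 <- predict_risk(fit, expr_p, g)
  expect_equal(r4, r1, tolerance = 1e-12)

  expect_error(predict_risk(fit, co$expression[-1, , drop = FALSE], g),
               class = "ctgsurv_missing_genes_error")
})

test_that("training rejects an event-free validation split", {
  co <- small_cohort(seed = 10)
  co$clinical$event <- rep(0L, nrow(co$clinical))
  co$clinical$event[1] <- 1L  # the single event lands in the training split
  g <- build_patient_graph(co$clinical)
  mask <- signature_mask(co$signatures, rownames(co$expression))
  expect_error(
    train_survival_gnn(co$expression, co$clinical, g, mask,
                       small_model_config(seed = 1)),
    class = "ctgsurv_split_error")
})
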