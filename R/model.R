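## The cell-type-aware graph transformer survival network.
##
## Architecture: standardized gene vectors are projected onto cell-state
## signature units through a multiplicatively masked linear map (a gene can
## only feed the signatures it belongs to), activated, lifted to the embedding
## dimension, and summed with a dense residual bypass from the gene vector.
## Node embeddings are then refined by transformer layers whose multi-head
## scaled dot-product attention is restricted to each patient's graph
## neighbourhood (self included) with edge log-weights as an additive bias on
## the attention logits; each layer is attention + position-wise feed-forward,
## both with residual connections and layer normalization. A linear Cox head
## maps the final representation to a relative log hazard.
##
## Forward, analytic backpropagation and the Adam optimizer are implemented
## directly on base-R matrices; the mask is applied multiplicatively at every
## forward pass, so projector weights at mask zeros stay exactly zero under
## any optimizer trajectory.

LN_EPS <- 1e-5

add_row <- function(M, b) M + rep(b, each = nrow(M))

softmax_rows <- function(L) {
  m <- apply(L, 1L, max)
  E <- exp(L - m)
  E / rowSums(E)
}

relu <- function(x) pmax(x, 0)

#' Model configuration for the graph transformer survival network
#'
#' @param embed_dim Embedding width (divisible by `n_heads`); default 64.
#' @param n_layers Number of transformer layers; default 2.
#' @param n_heads Attention heads; default 4.
#' @param ff_dim Position-wise feed-forward width; default 128.
#' @param dropout Dropout rate in `[0, 1)`; default 0.1.
#' @param learning_rate Adam step size; default 1e-3.
#' @param steps_per_epoch Full-batch Adam steps per epoch; default 4.
#' @param max_epochs Maximum epochs; default 300.
#' @param patience Early-stopping patience in epochs without validation
#'   concordance improvement; default 20.
#' @param ties Cox tie handling, `"breslow"` (default) or `"efron"`.
#' @param split Named fractions `train` / `validation` / `test`, positive and
#'   summing to 1; default 60/20/20.
#' @param seed Master seed for split, initialization and dropout streams.
#' @return A validated `model_config` object.
#' @export
model_config <- function(embed_dim = 64L, n_layers = 2L, n_heads = 4L,
                         ff_dim = 128L, dropout = 0.1, learning_rate = 1e-3,
                         steps_per_epoch = 4L, max_epochs = 300L, patience = 20L,
                         ties = c("breslow", "efron"),
                         split = c(train = 0.6, validation = 0.2, test = 0.2),
                         seed = 1L) {
  ties <- match.arg(ties)
  assert_that(is_count(embed_dim) && is_count(n_layers) && is_count(n_heads) &&
                is_count(ff_dim), "dimensions must be positive integers")
  assert_that(embed_dim %% n_heads == 0, "embed_dim must be divisible by n_heads")
  assert_that(is_scalar_num(dropout) && dropout >= 0 && dropout < 1,
              "dropout must lie in [0, 1)")
  assert_that(all(c("train", "validation", "test") %in% names(split)),
              "split must name train, validation and test fractions")
  assert_that(all(split > 0) && abs(sum(split) - 1) < 1e-8,
              "split fractions must be positive and sum to 1")
  assert_that(is_count(steps_per_epoch), "steps_per_epoch must be a positive integer")
  structure(list(embed_dim = as.integer(embed_dim),
                 n_layers = as.integer(n_layers),
                 n_heads = as.integer(n_heads),
                 ff_dim = as.integer(ff_dim),
                 dropout = dropout, learning_rate = learning_rate,
                 steps_per_epoch = as.integer(steps_per_epoch),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 ties = ties, split = split, seed = as.integer(seed)),
            class = "model_config")
}

## Seeded parameter initialization. Wm is dense storage but only mask-one
## entries are ever non-zero.
init_params <- function(G, S, config, mask) {
  d <- config$embed_dim; f <- config$ff_dim; L <- config$n_layers
  rn <- function(nr, nc, sd) matrix(stats::rnorm(nr * nc, sd = sd), nr, nc)
  ## Masked path starts as a (noisy) signature-mean readout: weight 1/n_s for
  ## every gene of signature s, so each signature unit begins as the mean
  ## standardized expression of its marker genes — the field's usual
  ## signature score — and training refines gene-level weights from there.
  col_n <- pmax(colSums(mask), 1)
  Wm <- (1 + 0.1 * rn(G, S, 1)) * rep(1 / col_n, each = G) * mask
  layers <- vector("list", L)
  for (l in seq_len(L)) {
    ## Residual-branch output projections (Wo, W2) start at zero, so every
    ## layer begins as identity-plus-normalization and the attention and
    ## feed-forward sub-blocks only contribute once their gradients ask for
    ## it; keeps the early network an interpretable signature readout.
    layers[[l]] <- list(
      Wq = rn(d, d, 1 / sqrt(d)), Wk = rn(d, d, 1 / sqrt(d)),
      Wv = rn(d, d, 1 / sqrt(d)), Wo = matrix(0, d, d),
      bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      W1 = rn(d, f, 1 / sqrt(d)), b1 = numeric(f),
      W2 = matrix(0, f, d), b2 = numeric(d),
      ln2_g = rep(1, d), ln2_b = numeric(d))
  }
  ## The residual gene bypass and the Cox head start at zero: the forward
  ## pass begins from the signature-structured masked path alone, and the
  ## dense bypass only grows where gradients demand it.
  list(Wm = Wm, bm = numeric(S),
       U = rn(S, d, 1 / sqrt(S)), Rr = matrix(0, G, d), be = numeric(d),
       layers = layers,
       head_w = numeric(d), head_b = 0)
}

## Attention-logit bias from a patient graph: log edge weight for neighbours,
## 0 on the diagonal (self), -Inf elsewhere.
attention_bias <- function(graph) {
  ids <- graph$ids
  n <- length(ids)
  B <- matrix(-Inf, n, n, dimnames = list(ids, ids))
  diag(B) <- 0
  e <- graph$edges
  if (nrow(e)) {
    i <- match(e$from, ids); j <- match(e$to, ids)
    B[cbind(i, j)] <- log(e$weight)
    B[cbind(j, i)] <- log(e$weight)
  }
  B
}

layernorm_fwd <- function(X, g, b) {
  mu <- rowMeans(X)
  Xc <- X - mu
  va <- rowMeans(Xc^2)
  sd_ <- sqrt(va + LN_EPS)
  Xhat <- Xc / sd_
  list(Y = add_row(Xhat * rep(g, each = nrow(X)), b), Xhat = Xhat, sd = sd_)
}

layernorm_bwd <- function(dY, cache, g) {
  n <- nrow(dY)
  Xhat <- cache$Xhat
  dXhat <- dY * rep(g, each = n)
  dg <- colSums(dY * Xhat)
  db <- colSums(dY)
  dX <- (dXhat - rowMeans(dXhat) - Xhat * rowMeans(dXhat * Xhat)) / cache$sd
  list(dX = dX, dg = dg, db = db)
}

dropout_mask <- function(n, d, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(n * d, 1L, 1 - rate), n, d) / (1 - rate)
}

#' Masked signature projection of gene vectors
#'
#' Computes the masked path's signature pre-activations
#' `Z[, s] = sum_g M[g, s] * W[g, s] * x[g] + b[s]` — genes outside signature
#' `s` contribute exactly zero — and the patient embedding
#' `tanh(Z) %*% U + X %*% R + b_e` (activated signature representation lifted
#' to the embedding dimension plus the dense residual bypass).
#'
#' @param X Patient-by-gene matrix (rows are patients), columns matching the
#'   mask's gene universe.
#' @param mask Binary gene-by-signature matrix.
#' @param params List with `Wm` (gene x signature), `bm`, `U`
#'   (signature x embed), `Rr` (gene x embed), `be`.
#' @return List: `embedding` (patients x embed), `preactivation`
#'   (patients x signatures), `signature_activation`.
#' @export
masked_projection <- function(X, mask, params) {
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, names(X)))
  assert_that(ncol(X) == nrow(mask), "gene dimension mismatch with the mask")
  assert_that(identical(dim(params$Wm), dim(mask)),
              "projector weight dimensions must match the mask")
  Z <- add_row(X %*% (params$Wm * mask), params$bm)
  ## tanh keeps the sign of below-average signature scores (standardized
  ## inputs are centred), which a linear hazard readout needs
  Hsig <- tanh(Z)
  H <- add_row(Hsig %*% params$U + X %*% params$Rr, params$be)
  list(embedding = H, preactivation = Z, signature_activation = Hsig)
}

## One transformer layer forward (pre-normalization convention: each
## sub-block reads a layer-normalized copy of the stream and adds its output
## back residually, so the embedding travels to the Cox head through an
## unnormalized linear path). B is the attention-logit bias matrix.
layer_forward <- function(H, lp, B, n_heads, drop_rate = 0, training = FALSE) {
  n <- nrow(H); d <- ncol(H); dh <- d %/% n_heads
  ln1 <- layernorm_fwd(H, lp$ln1_g, lp$ln1_b)
  Hn <- ln1$Y
  Q <- Hn %*% lp$Wq; K <- Hn %*% lp$Wk; V <- Hn %*% lp$Wv
  heads <- vector("list", n_heads)
  O <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    logits <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) /
      sqrt(dh) + B
    A <- softmax_rows(logits)
    O[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[h]] <- list(A = A, cols = cols)
  }
  Ao <- add_row(O %*% lp$Wo, lp$bo)
  m1 <- if (training) dropout_mask(n, d, drop_rate) else NULL
  if (!is.null(m1)) Ao <- Ao * m1
  H1 <- H + Ao
  ln2 <- layernorm_fwd(H1, lp$ln2_g, lp$ln2_b)
  H1n <- ln2$Y
  F1p <- add_row(H1n %*% lp$W1, lp$b1)
  F1 <- relu(F1p)
  F2 <- add_row(F1 %*% lp$W2, lp$b2)
  m2 <- if (training) dropout_mask(n, d, drop_rate) else NULL
  if (!is.null(m2)) F2 <- F2 * m2
  list(out = H1 + F2,
       cache = list(H = H, Hn = Hn, Q = Q, K = K, V = V, heads = heads,
                    O = O, m1 = m1, ln1 = ln1, H1 = H1, H1n = H1n, ln2 = ln2,
                    F1p = F1p, F1 = F1, m2 = m2))
}

layer_backward <- function(dOut, lp, cache, n_heads) {
  n <- nrow(dOut); d <- ncol(dOut); dh <- d %/% n_heads
  g <- list()
  ## feed-forward sub-block: out = H1 + drop(FFN(LN2(H1)))
  dH1 <- dOut
  dF2 <- dOut
  if (!is.null(cache$m2)) dF2 <- dF2 * cache$m2
  g$W2 <- crossprod(cache$F1, dF2); g$b2 <- colSums(dF2)
  dF1 <- tcrossprod(dF2, lp$W2) * (cache$F1p > 0)
  g$W1 <- crossprod(cache$H1n, dF1); g$b1 <- colSums(dF1)
  dH1n <- tcrossprod(dF1, lp$W1)
  lb2 <- layernorm_bwd(dH1n, cache$ln2, lp$ln2_g)
  g$ln2_g <- lb2$dg; g$ln2_b <- lb2$db
  dH1 <- dH1 + lb2$dX

  ## attention sub-block: H1 = H + drop(Attn(LN1(H)))
  dH <- dH1
  dAo <- dH1
  if (!is.null(cache$m1)) dAo <- dAo * cache$m1
  g$Wo <- crossprod(cache$O, dAo); g$bo <- colSums(dAo)
  dO <- tcrossprod(dAo, lp$Wo)
  dQ <- matrix(0, n, d); dK <- matrix(0, n, d); dV <- matrix(0, n, d)
  for (h in seq_len(n_heads)) {
    cols <- cache$heads[[h]]$cols
    A <- cache$heads[[h]]$A
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- tcrossprod(dOh, Vh)
    dV[, cols] <- crossprod(A, dOh)
    dlog <- A * (dA - rowSums(dA * A))
    dQ[, cols] <- dlog %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- crossprod(dlog, cache$Q[, cols, drop = FALSE]) / sqrt(dh)
  }
  g$Wq <- crossprod(cache$Hn, dQ); g$Wk <- crossprod(cache$Hn, dK)
  g$Wv <- crossprod(cache$Hn, dV)
  dHn <- tcrossprod(dQ, lp$Wq) + tcrossprod(dK, lp$Wk) +
    tcrossprod(dV, lp$Wv)
  lb1 <- layernorm_bwd(dHn, cache$ln1, lp$ln1_g)
  g$ln1_g <- lb1$dg; g$ln1_b <- lb1$db
  dH <- dH + lb1$dX
  list(dH = dH, grads = g)
}

#' Neighbour-restricted transformer forward pass
#'
#' Runs `length(layers)` transformer layers over per-patient embeddings, with
#' each patient attending only to itself and its graph neighbours; attention
#' weights over that allowed set are non-negative and sum to one per head.
#' Edge weights enter as additive log-weight biases on the attention logits.
#'
#' @param graph A `patient_graph` (or a precomputed attention-bias matrix).
#' @param embeddings Patient-by-dim matrix, rows ordered like the graph ids.
#' @param layers List of per-layer parameter lists (`Wq`, `Wk`, `Wv`, `Wo`,
#'   `bo`, layer-norm gains/biases, feed-forward weights; exposed for direct
#'   evaluation with hand-set parameters).
#' @param n_heads Number of attention heads.
#' @return Patient-by-dim matrix of refined representations.
#' @export
transformer_gnn_forward <- function(graph, embeddings, layers, n_heads = 1L) {
  B <- if (is.matrix(graph)) graph else attention_bias(graph)
  assert_that(nrow(embeddings) == nrow(B),
              "embeddings must cover every graph node")
  H <- embeddings
  for (lp in layers) {
    H <- layer_forward(H, lp, B, n_heads)$out
  }
  H
}

## Full network forward. Returns risk vector and (optionally) caches.
network_forward <- function(params, X, mask, B, config, training = FALSE,
                            keep_cache = FALSE) {
  n <- nrow(X)
  mx <- if (training) dropout_mask(n, ncol(X), config$dropout) else NULL
  if (!is.null(mx)) X <- X * mx
  mp <- masked_projection(X, mask, params)
  H <- mp$embedding
  m0 <- if (training) dropout_mask(n, config$embed_dim, config$dropout) else NULL
  if (!is.null(m0)) H <- H * m0
  caches <- vector("list", config$n_layers)
  for (l in seq_len(config$n_layers)) {
    lf <- layer_forward(H, params$layers[[l]], B, config$n_heads,
                        config$dropout, training)
    H <- lf$out
    if (keep_cache) caches[[l]] <- lf$cache
  }
  risk <- drop(H %*% params$head_w) + params$head_b
  if (!keep_cache) return(list(risk = risk))
  list(risk = risk, mp = mp, m0 = m0, caches = caches, H_final = H, X = X)
}

network_backward <- function(params, fwd, drisk, mask, config) {
  n <- length(drisk)
  g <- list()
  g$head_w <- drop(crossprod(fwd$H_final, drisk))
  g$head_b <- sum(drisk)
  dH <- tcrossprod(drisk, params$head_w)
  g$layers <- vector("list", config$n_layers)
  for (l in rev(seq_len(config$n_layers))) {
    lb <- layer_backward(dH, params$layers[[l]], fwd$caches[[l]],
                         config$n_heads)
    g$layers[[l]] <- lb$grads
    dH <- lb$dH
  }
  if (!is.null(fwd$m0)) dH <- dH * fwd$m0
  g$U <- crossprod(fwd$mp$signature_activation, dH)
  g$be <- colSums(dH)
  g$Rr <- crossprod(fwd$X, dH)
  dHsig <- tcrossprod(dH, params$U)
  dZ <- dHsig * (1 - fwd$mp$signature_activation^2)
  g$Wm <- crossprod(fwd$X, dZ) * mask
  g$bm <- colSums(dZ)
  g
}

## ---- Adam over the nested parameter list ----

adam_init <- function(params) {
  zeros_like <- function(p) {
    if (is.list(p)) lapply(p, zeros_like) else p * 0
  }
  list(m = zeros_like(params), v = zeros_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  tt <- state$t
  ## param and gradient lists may order their elements differently, so
  ## recurse by name where names exist (layers are unnamed: by position)
  upd2 <- function(p, gr, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      keys <- if (is.null(names(p))) seq_along(p) else names(p)
      for (k in keys) {
        r <- upd2(p[[k]], gr[[k]], m[[k]], v[[k]])
        out_p[[k]] <- r$p; out_m[[k]] <- r$m; out_v[[k]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * gr
    v <- beta2 * v + (1 - beta2) * gr^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd2(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}
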