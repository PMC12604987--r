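## End-to-end training of the graph transformer survival network: event-
## stratified splitting, leakage-free standardization, full-batch Adam on the
## Cox partial likelihood, per-epoch validation concordance, early stopping,
## and selection of the best validation epoch.

## Event-stratified train/validation/test split, seeded.
stratified_split <- function(ids, event, fractions, seed) {
  set.seed(seed)
  out <- list(train = character(0), validation = character(0),
              test = character(0))
  for (ev in unique(event)) {
    grp <- sample(ids[event == ev])
    n <- length(grp)
    n_tr <- round(fractions[["train"]] * n)
    n_va <- round(fractions[["validation"]] * n)
    n_tr <- min(n_tr, n); n_va <- min(n_va, n - n_tr)
    out$train <- c(out$train, grp[seq_len(n_tr)])
    out$validation <- c(out$validation,
                        grp[n_tr + seq_len(n_va)])
    out$test <- c(out$test, grp[setdiff(seq_len(n), seq_len(n_tr + n_va))])
  }
  lapply(out, sort)
}

#' Train the cell-type-aware graph transformer survival model
#'
#' Splits patients (stratified on event status) into train/validation/test,
#' standardizes expression using training-set statistics only, and fits the
#' masked-projector + graph-transformer + Cox-head network by full-batch Adam
#' on the training patients' negative log partial likelihood. Validation
#' concordance is recorded every epoch; training stops when it fails to
#' improve for `patience` epochs (or at `max_epochs`), and the returned state
#' is the epoch of maximum validation concordance (earliest epoch on ties).
#' Fully reproducible under `config$seed`.
#'
#' @param expr Gene-by-patient expression matrix on the log2 scale (or
#'   already standardized, in which case it is used as-is).
#' @param clinical Data frame with `patient_id`, `time`, `event` covering the
#'   graph's patients.
#' @param graph A connected `patient_graph` over the same patients.
#' @param mask Binary gene-by-signature matrix from [signature_mask()].
#' @param config A [model_config()].
#' @return A `ctg_model`: best `params`, `config`, `mask`, `genes`,
#'   standardization statistics, `split` (id vectors), `history` (per-epoch
#'   data frame of training loss and validation concordance),
#'   `selected_epoch`.
#' @export
train_survival_gnn <- function(expr, clinical, graph, mask,
                               config = model_config()) {
  assert_that(inherits(config, "model_config"), "config must be a model_config")
  assert_that(inherits(graph, "patient_graph"), "graph must be a patient_graph")
  assert_that(is_connected(graph), "graph must be connected")
  ids <- graph$ids
  assert_that(all(ids %in% colnames(expr)),
              "expression must cover all graph patients")
  assert_that(all(ids %in% clinical$patient_id),
              "clinical table must cover all graph patients")
  genes <- rownames(mask)
  missing <- setdiff(genes, rownames(expr))
  assert_that(length(missing) == 0,
              "expression is missing mask genes: ",
              paste(utils::head(missing, 5), collapse = ", "))
  cl <- clinical[match(ids, clinical$patient_id), ]
  time <- cl$time; event <- cl$event

  seeds <- child_seeds(config$seed, 3L)
  split <- stratified_split(ids, event, config$split, seeds[1L])
  val_idx <- match(split$validation, ids)
  if (sum(event[val_idx]) == 0) {
    stop_ctg("validation split contains no events",
             class = "ctgsurv_split_error")
  }

  sc <- attr(expr, "scale", exact = TRUE)
  if (is.null(sc) || sc != "standardized") {
    expr <- suppressWarnings(standardize_train(expr[genes, ids, drop = FALSE],
                                               split$train))
  } else {
    expr <- expr[genes, ids, drop = FALSE]
  }
  X <- t(expr)  # patients x genes
  B <- attention_bias(graph)
  tr_idx <- match(split$train, ids)

  set.seed(seeds[2L])
  params <- init_params(length(genes), ncol(mask), config, mask)

  ## Warm-start the Cox head: with zero-initialized residual branches the
  ## initial network is an (almost) linear signature readout, so a ridge Cox
  ## fit on the initial training representations gives the head the best
  ## linear readout before end-to-end fine-tuning. Recorded as epoch 0 so
  ## early stopping can keep it when fine-tuning does not improve on it.
  fwd0 <- network_forward(params, X, mask, B, config, training = FALSE,
                          keep_cache = TRUE)
  params$head_w <- tryCatch({
    wf <- survival::coxph(
      survival::Surv(time[tr_idx], event[tr_idx]) ~
        survival::ridge(fwd0$H_final[tr_idx, ], theta = 10))
    w <- unname(stats::coef(wf))
    if (all(is.finite(w))) w else params$head_w
  }, error = function(e) params$head_w)
  opt <- adam_init(params)

  ev0 <- network_forward(params, X, mask, B, config, training = FALSE)
  val_c0 <- concordance_index(ev0$risk[val_idx], time[val_idx],
                              event[val_idx])
  loss0 <- cox_partial_likelihood(ev0$risk[tr_idx], time[tr_idx],
                                  event[tr_idx], ties = config$ties)
  history <- data.frame(epoch = 0L, train_loss = as.numeric(loss0),
                        val_concordance = val_c0)
  best_c <- val_c0; best_epoch <- 0L; best_params <- params
  wait <- 0L

  set.seed(seeds[3L])  # dropout stream
  for (epoch in seq_len(config$max_epochs)) {
    for (step in seq_len(config$steps_per_epoch)) {
      fwd <- network_forward(params, X, mask, B, config, training = TRUE,
                             keep_cache = TRUE)
      loss <- cox_partial_likelihood(fwd$risk[tr_idx], time[tr_idx],
                                     event[tr_idx], ties = config$ties,
                                     gradient = TRUE)
      drisk <- numeric(length(ids))
      drisk[tr_idx] <- attr(loss, "gradient")
      grads <- network_backward(params, fwd, drisk, mask, config)
      st <- adam_step(params, grads, opt, config$learning_rate)
      params <- st$params
      params$Wm <- params$Wm * mask  # exact masked-zero enforcement
      opt <- st$state
    }

    ev <- network_forward(params, X, mask, B, config, training = FALSE)
    val_c <- concordance_index(ev$risk[val_idx], time[val_idx], event[val_idx])
    history <- rbind(history,
                     data.frame(epoch = epoch, train_loss = as.numeric(loss),
                                val_concordance = val_c))
    if (val_c > best_c) {
      best_c <- val_c; best_epoch <- epoch; best_params <- params
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait > config$patience) break
    }
  }

  structure(
    list(params = best_params, config = config, mask = mask, genes = genes,
         center = attr(expr, "center", exact = TRUE),
         scale_sd = attr(expr, "scale_sd", exact = TRUE),
         split = split, history = history, selected_epoch = best_epoch,
         val_concordance = best_c),
    class = "ctg_model")
}

#' @export
print.ctg_model <- function(x, ...) {
  cat(sprintf("ctg_model: %d genes, %d signatures, %d layers x %d heads (d=%d)\n",
              length(x$genes), ncol(x$mask), x$config$n_layers,
              x$config$n_heads, x$config$embed_dim))
  cat(sprintf("  selected epoch %d of %d; validation concordance %.3f\n",
              x$selected_epoch, max(x$history$epoch), x$val_concordance))
  invisible(x)
}

## Standardize a raw/log2 matrix with the model's stored training statistics.
apply_model_scaling <- function(model, expr) {
  missing <- setdiff(model$genes, rownames(expr))
  if (length(missing)) {
    stop_ctg("expression is missing model genes: ",
             paste(utils::head(missing, 10), collapse = ", "),
             class = "ctgsurv_missing_genes_error")
  }
  expr <- expr[model$genes, , drop = FALSE]
  sc <- attr(expr, "scale", exact = TRUE)
  if (!is.null(sc) && sc == "standardized") return(expr)
  if (is.null(model$center)) return(expr)
  sd_ <- model$scale_sd
  zero <- !is.finite(sd_) | sd_ == 0
  sd_adj <- ifelse(zero, 1, sd_)
  z <- (expr - model$center) / sd_adj
  z[zero, ] <- 0
  z
}

#' Predict relative log hazards
#'
#' Deterministic forward pass (dropout disabled) of a trained model on a
#' cohort; expression is standardized with the model's stored training
#' statistics when not already standardized.
#'
#' @param model A `ctg_model` from [train_survival_gnn()].
#' @param expr Gene-by-patient expression covering the model's gene universe.
#' @param graph A connected `patient_graph` over the cohort.
#' @return Named numeric vector of per-patient relative log hazards.
#' @export
predict_risk <- function(model, expr, graph) {
  assert_that(inherits(model, "ctg_model"), "model must be a ctg_model")
  ids <- graph$ids
  assert_that(all(ids %in% colnames(expr)),
              "expression must cover all graph patients")
  Z <- apply_model_scaling(model, expr)[, ids, drop = FALSE]
  B <- attention_bias(graph)
  fwd <- network_forward(model$params, t(Z), model$mask, B, model$config,
                         training = FALSE)
  stats::setNames(fwd$risk, ids)
}
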