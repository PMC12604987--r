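## Independent brute-force oracles used across the suite. These deliberately
## re-derive each quantity from its definition (loops and enumerations), and
## never call the package functions they check.

## Harrell's C by exhaustive pair enumeration: i is the earlier event when
## t_i < t_j & e_i = 1, or t_i == t_j with e_i = 1, e_j = 0.
bf_concordance <- function(risk, time, event) {
  n <- length(risk)
  num <- 0; den <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      comparable <- (time[i] < time[j] && event[i] == 1) ||
        (time[i] == time[j] && event[i] == 1 && event[j] == 0)
      if (!comparable) next
      den <- den + 1
      if (risk[i] > risk[j]) num <- num + 1
      else if (risk[i] == risk[j]) num <- num + 0.5
    }
  }
  num / den
}

## Gower distance by explicit per-feature averaging over a data frame of
## scaled numerics (range 1) and factors, skipping NAs.
bf_gower <- function(df, kinds) {
  n <- nrow(df)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      s <- 0; m <- 0
      for (f in seq_along(df)) {
        vi <- df[[f]][i]; vj <- df[[f]][j]
        if (is.na(vi) || is.na(vj)) next
        m <- m + 1
        s <- s + if (kinds[[f]] == "numeric") abs(as.numeric(vi) - as.numeric(vj))
                 else as.numeric(as.character(vi) != as.character(vj))
      }
      D[i, j] <- s / m
    }
  }
  D
}

## Two-sided Fisher p by exhaustive enumeration over the hypergeometric
## support, summing point probabilities <= observed (with a numerical
## tolerance for ties in probability).
bf_fisher <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  pr <- vapply(support, function(x) {
    exp(lchoose(r1, x) + lchoose(r2, c1 - x) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- pr[match(a, support)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

## Negative log Cox partial likelihood (Breslow) from the closed form,
## written as a direct double loop over events and risk sets.
bf_cox_breslow <- function(risk, time, event) {
  loss <- 0
  for (i in which(event == 1)) {
    loss <- loss - risk[i] + log(sum(exp(risk[time >= time[i]])))
  }
  loss
}

## Two-group log-rank chi-square from hand-tabulated risk sets.
bf_logrank <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- unique(group)[1]
  tt <- sort(unique(time[event == 1]))
  o_minus_e <- 0; v <- 0
  for (t in tt) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & group == g1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

## Small helper cohort for model-level tests: quick to simulate and train.
small_cohort <- function(seed = 1, n_patients = 60, n_genes = 48) {
  gps <- max(3L, floor(n_genes / 8))
  cfg <- cohort_config(
    n_patients = n_patients, n_genes = n_genes,
    signatures = default_signatures(n_genes, genes_per_signature = gps),
    seed = seed)
  simulate_cohort(cfg)
}

small_model_config <- function(seed = 1, max_epochs = 12L, patience = 4L, ...) {
  model_config(embed_dim = 16L, n_heads = 4L, ff_dim = 24L,
               max_epochs = max_epochs, patience = patience, seed = seed, ...)
}

## Flatten a nested parameter list to named leaves (used by gradient checks).
flatten_params <- function(p, path = "") {
  if (is.list(p)) {
    keys <- if (is.null(names(p))) as.character(seq_along(p)) else names(p)
    out <- list()
    for (k in keys) out <- c(out, flatten_params(p[[k]], paste0(path, "/", k)))
    out
  } else stats::setNames(list(p), path)
}

set_param_at <- function(params, path, ii, val) {
  keys <- strsplit(sub("^/", "", path), "/")[[1]]
  expr <- "params"
  for (k in keys) {
    expr <- if (grepl("^[0-9]+$", k)) paste0(expr, "[[", k, "]]")
            else paste0(expr, "[[\"", k, "\"]]")
  }
  eval(parse(text = paste0(expr, "[", ii, "] <- val")))
  params
}
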