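## Synthetic cohort generator: bulk-like cohorts with Dirichlet cell-state
## fractions, signature-structured expression, and Weibull proportional-hazards
## survival driven by a designated cell state. Every downstream stage of the
## pipeline (graph construction, model training, attribution) is testable
## against the generator's ground truth.

#' Default cell-state signature blocks
#'
#' Partitions the first genes of a universe of `n_genes` into six equally
#' sized cell-state signatures named after glioblastoma malignant and lineage
#' states, with the remainder left as unassigned noise genes. The designated
#' high-risk state is `"MES2-like"` by convention.
#'
#' @param n_genes Total number of genes in the universe.
#' @param n_signatures Number of signature blocks (default 6).
#' @param genes_per_signature Genes per block; default splits 80% of the
#'   universe evenly across blocks (at least 3 genes each).
#' @return Named list of gene-id character vectors.
#' @export
default_signatures <- function(n_genes, n_signatures = 6L,
                               genes_per_signature = NULL) {
  assert_that(is_count(n_genes) && is_count(n_signatures),
              "n_genes and n_signatures must be positive integers")
  state_names <- c("MES2-like", "MES1-like", "AC-like", "OPC-like",
                   "NPC-like", "Cycling")
  if (n_signatures > length(state_names)) {
    state_names <- c(state_names,
                     paste0("State", seq_len(n_signatures - length(state_names))))
  }
  state_names <- state_names[seq_len(n_signatures)]
  if (is.null(genes_per_signature)) {
    genes_per_signature <- max(3L, floor(0.8 * n_genes / n_signatures))
  }
  assert_that(genes_per_signature * n_signatures <= n_genes,
              "signature blocks exceed the gene universe")
  genes <- gene_universe(n_genes)
  sigs <- vector("list", n_signatures)
  names(sigs) <- state_names
  for (s in seq_len(n_signatures)) {
    idx <- ((s - 1L) * genes_per_signature + 1L):(s * genes_per_signature)
    sigs[[s]] <- genes[idx]
  }
  sigs
}

gene_universe <- function(n_genes) {
  sprintf("gene_%04d", seq_len(n_genes))
}

patient_ids <- function(n) sprintf("P%04d", seq_len(n))

#' Cohort generator configuration
#'
#' Assembles and validates the full parameterisation of a synthetic cohort:
#' cohort size, gene universe, cell-state signature blocks, Dirichlet
#' concentration of the state fractions, expression loading and noise,
#' log-hazard coefficients per state, Weibull baseline hazard, target
#' censoring proportion, and a clinical covariate specification.
#'
#' Defaults emulate a TCGA-like glioblastoma cohort: 240 patients, 300 genes
#' in six cell-state blocks, survival loading only on the `"MES2-like"`
#' fraction with log-hazard coefficient 2, 30% right-censoring, and
#' survival-independent clinical covariates (age, sex, Karnofsky score, MGMT
#' methylation, IDH status) used solely for graph construction.
#'
#' @param n_patients,n_genes Cohort dimensions.
#' @param signatures Named list of disjoint gene-id vectors (>= 3 genes each).
#' @param fraction_concentration Positive Dirichlet concentration per
#'   signature (recycled if scalar).
#' @param signature_loading Expression units added per unit of state fraction.
#' @param noise_sd Gaussian noise s.d. on the log2 expression scale.
#' @param beta Named numeric of log-hazard coefficients per unit fraction;
#'   states not named get 0.
#' @param baseline_shape,baseline_scale Weibull baseline hazard parameters
#'   (time in days).
#' @param censor_rate Target expected censoring proportion in `[0, 1)`.
#' @param clinical_spec List of per-feature generator specs, each a list with
#'   `name`, `type` (`"numeric"` or `"categorical"`), and either `mean`/`sd`
#'   or `levels`/`probs`; an optional `link` adds `link * linear_predictor`
#'   to a numeric feature (default 0: clinical features independent of
#'   outcome).
#' @param seed Master seed; all randomness flows from it.
#' @return A validated `cohort_config` object.
#' @export
cohort_config <- function(n_patients = 240L,
                          n_genes = 300L,
                          signatures = default_signatures(n_genes),
                          fraction_concentration = NULL,
                          signature_loading = 3,
                          noise_sd = 0.5,
                          beta = c("MES2-like" = 2),
                          baseline_shape = 1.2,
                          baseline_scale = 500,
                          censor_rate = 0.3,
                          clinical_spec = default_clinical_spec(),
                          seed = 1L) {
  assert_that(is_count(n_patients), "n_patients must be a positive integer")
  assert_that(is_count(n_genes), "n_genes must be a positive integer")
  assert_that(is.list(signatures) && length(signatures) >= 1 &&
                !is.null(names(signatures)),
              "signatures must be a named list")
  universe <- gene_universe(n_genes)
  all_sig_genes <- unlist(signatures, use.names = FALSE)
  if (anyDuplicated(all_sig_genes)) {
    stop_ctg("signature gene lists must be disjoint",
             class = "ctgsurv_signature_overlap_error")
  }
  assert_that(all(all_sig_genes %in% universe),
              "signature genes must lie inside the gene universe")
  assert_that(all(lengths(signatures) >= 3L),
              "each signature needs at least 3 genes")
  k <- length(signatures)
  if (is.null(fraction_concentration)) {
    ## Sparse Dirichlet: real malignant-state compositions are dominated by
    ## one or two states per tumour, with the designated high-risk state
    ## spanning near-absence to dominance. This calibration makes the
    ## designated state a strong prognostic factor (true-linear-predictor
    ## concordance ~0.70 at beta = 2, median-split hazard ratio ~2.7, inside
    ## the association range reported for mesenchymal-state abundance).
    fraction_concentration <- rep(0.06, k)
    designated <- if ("MES2-like" %in% names(signatures)) "MES2-like"
                  else names(signatures)[1L]
    fraction_concentration[match(designated, names(signatures))] <- 0.15
  }
  if (length(fraction_concentration) == 1L) {
    fraction_concentration <- rep(fraction_concentration, k)
  }
  assert_that(length(fraction_concentration) == k &&
                all(fraction_concentration > 0),
              "Dirichlet concentrations must be positive, one per signature")
  names(fraction_concentration) <- names(signatures)
  beta_full <- stats::setNames(numeric(k), names(signatures))
  if (length(beta)) {
    assert_that(!is.null(names(beta)) && all(names(beta) %in% names(signatures)),
                "beta names must match signature names")
    beta_full[names(beta)] <- beta
  }
  assert_that(is_scalar_num(signature_loading) && signature_loading > 0,
              "signature_loading must be a positive real")
  assert_that(is_scalar_num(noise_sd) && noise_sd >= 0,
              "noise_sd must be non-negative")
  assert_that(is_scalar_num(baseline_shape) && baseline_shape > 0 &&
                is_scalar_num(baseline_scale) && baseline_scale > 0,
              "Weibull baseline parameters must be positive")
  assert_that(is_scalar_num(censor_rate) && censor_rate >= 0 && censor_rate < 1,
              "censor_rate must lie in [0, 1)")
  structure(
    list(n_patients = as.integer(n_patients),
         n_genes = as.integer(n_genes),
         signatures = signatures,
         fraction_concentration = fraction_concentration,
         signature_loading = signature_loading,
         noise_sd = noise_sd,
         beta = beta_full,
         baseline_shape = baseline_shape,
         baseline_scale = baseline_scale,
         censor_rate = censor_rate,
         clinical_spec = clinical_spec,
         seed = as.integer(seed)),
    class = "cohort_config")
}

#' Default clinical covariate specification
#'
#' Age (years), sex, Karnofsky performance score, MGMT promoter methylation
#' and IDH mutation status, generated independently of survival.
#'
#' @return List of feature specs consumable by [simulate_cohort()].
#' @export
default_clinical_spec <- function() {
  list(
    list(name = "age", type = "numeric", mean = 60, sd = 10, link = 0),
    list(name = "sex", type = "categorical",
         levels = c("male", "female"), probs = c(0.6, 0.4)),
    list(name = "kps", type = "numeric", mean = 80, sd = 10, link = 0),
    list(name = "mgmt", type = "categorical",
         levels = c("methylated", "unmethylated"), probs = c(0.45, 0.55)),
    list(name = "idh", type = "categorical",
         levels = c("wildtype", "mutant"), probs = c(0.9, 0.1))
  )
}

dirichlet_sample <- function(n, alpha) {
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

## Solve the uniform-censoring upper bound c so that the expected censoring
## proportion E[min(T, c)] / c matches the target, given the drawn event times.
solve_censor_bound <- function(event_times, censor_rate) {
  f <- function(cc) mean(pmin(event_times, cc)) / cc - censor_rate
  upper <- max(event_times) * 2
  while (f(upper) > 0) upper <- upper * 2
  lower <- min(event_times) * 1e-6
  stats::uniroot(f, c(lower, upper), tol = 1e-10)$root
}

#' Simulate a synthetic survival cohort
#'
#' Draws per-patient cell-state fractions from a Dirichlet distribution,
#' builds a log2-scale expression matrix in which each signature gene reads
#' out its state's fraction (`signature_loading * fraction + noise`, around a
#' gene-specific base level) while non-signature genes carry noise only,
#' generates event times from a Weibull proportional-hazards model whose
#' linear predictor is `fractions %*% beta`, and applies independent uniform
#' right-censoring calibrated to the target censoring proportion. Identical
#' config (including seed) yields a bit-identical cohort.
#'
#' @param config A [cohort_config()].
#' @return A `synthetic_cohort` object: `clinical` (data.frame with
#'   `patient_id`, covariates, `time`, `event`), `expression` (gene-by-patient
#'   matrix, attribute `scale = "log2"`), `signatures`, `true_fractions`
#'   (patient-by-signature, rows sum to 1), `true_linear_predictor`, `config`.
#' @export
simulate_cohort <- function(config) {
  assert_that(inherits(config, "cohort_config"),
              "config must come from cohort_config()")
  n <- config$n_patients
  genes <- gene_universe(config$n_genes)
  sigs <- config$signatures
  seeds <- child_seeds(config$seed, 5L)

  set.seed(seeds[1L])
  fr <- dirichlet_sample(n, config$fraction_concentration)
  dimnames(fr) <- list(patient_ids(n), names(sigs))

  set.seed(seeds[2L])
  base_level <- stats::runif(length(genes), 4, 8)
  names(base_level) <- genes
  expr <- matrix(stats::rnorm(length(genes) * n, sd = config$noise_sd),
                 nrow = length(genes), ncol = n,
                 dimnames = list(genes, patient_ids(n)))
  expr <- expr + base_level
  for (s in names(sigs)) {
    expr[sigs[[s]], ] <- expr[sigs[[s]], ] +
      config$signature_loading * rep(fr[, s], each = length(sigs[[s]]))
  }
  attr(expr, "scale") <- "log2"

  eta <- drop(fr %*% config$beta)
  set.seed(seeds[3L])
  u <- stats::runif(n)
  ## Weibull PH: S(t | eta) = exp(-(t/scale)^shape * exp(eta))
  t_event <- config$baseline_scale *
    (-log(u) * exp(-eta))^(1 / config$baseline_shape)

  if (config$censor_rate > 0) {
    cc <- solve_censor_bound(t_event, config$censor_rate)
    set.seed(seeds[4L])
    t_cens <- stats::runif(n, 0, cc)
    time <- pmin(t_event, t_cens)
    event <- as.integer(t_event <= t_cens)
  } else {
    time <- t_event
    event <- rep(1L, n)
  }

  set.seed(seeds[5L])
  clinical <- data.frame(patient_id = patient_ids(n),
                         stringsAsFactors = FALSE)
  for (fs in config$clinical_spec) {
    if (fs$type == "numeric") {
      link <- if (is.null(fs$link)) 0 else fs$link
      clinical[[fs$name]] <- stats::rnorm(n, fs$mean, fs$sd) + link * eta
    } else if (fs$type == "categorical") {
      clinical[[fs$name]] <- sample(fs$levels, n, replace = TRUE,
                                    prob = fs$probs)
    } else {
      stop_ctg("unknown clinical feature type: ", fs$type,
               class = "ctgsurv_validation_error")
    }
  }
  clinical$time <- time
  clinical$event <- event

  structure(
    list(clinical = clinical,
         expression = expr,
         signatures = sigs,
         true_fractions = fr,
         true_linear_predictor = stats::setNames(eta, patient_ids(n)),
         config = config),
    class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic_cohort: %d patients, %d genes, %d signatures\n",
              ncol(x$expression), nrow(x$expression), length(x$signatures)))
  cat(sprintf("  events: %d/%d (censoring %.1f%%)\n",
              sum(x$clinical$event), nrow(x$clinical),
              100 * mean(1 - x$clinical$event)))
  invisible(x)
}

#' Simulate a labelled two-group expression matrix
#'
#' Fixture generator for marker selection and rank-reversal testing: genes are
#' i.i.d. Gaussian around gene-specific base levels in controls, and a chosen
#' set of genes is shifted by `shift_log2` log2 units in cases.
#'
#' @param n_case,n_control Group sizes (each >= 2).
#' @param n_genes Number of genes.
#' @param de_genes Gene ids (within the universe) shifted in cases.
#' @param shift_log2 Shift applied to `de_genes` in the case group.
#' @param seed Seed; identical seeds yield identical matrices.
#' @param base_sd Within-group noise s.d. (default 1).
#' @return Gene-by-sample matrix with a `labels` attribute (`"case"` /
#'   `"control"` per column).
#' @export
simulate_two_group_expression <- function(n_case, n_control, n_genes,
                                          de_genes = character(),
                                          shift_log2 = 0, seed = 1L,
                                          base_sd = 1) {
  assert_that(is_count(n_case) && n_case >= 2 &&
                is_count(n_control) && n_control >= 2,
              "n_case and n_control must be integers >= 2")
  genes <- gene_universe(n_genes)
  assert_that(all(de_genes %in% genes),
              "de_genes must lie inside the gene universe")
  set.seed(as.integer(seed))
  n <- n_case + n_control
  base_level <- stats::runif(n_genes, 4, 8)
  x <- matrix(stats::rnorm(n_genes * n, sd = base_sd), nrow = n_genes,
              dimnames = list(genes,
                              c(sprintf("case_%03d", seq_len(n_case)),
                                sprintf("control_%03d", seq_len(n_control)))))
  x <- x + base_level
  if (length(de_genes)) {
    x[de_genes, seq_len(n_case)] <- x[de_genes, seq_len(n_case)] + shift_log2
  }
  attr(x, "labels") <- c(rep("case", n_case), rep("control", n_control))
  attr(x, "scale") <- "log2"
  x
}
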