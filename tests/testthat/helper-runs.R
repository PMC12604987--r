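## Multi-seed training runs shared by the risk-recovery and attribution
## acceptance tests. Results are memoised so the cohorts are simulated and
## the models trained exactly once per test session.

.run_cache <- new.env(parent = emptyenv())

## One end-to-end run of the study conditions: default TCGA-like cohort
## (240 patients, 300 genes, 6 signatures, beta_MES2 = 2, 30% censoring),
## clinical graph, trained model, held-out evaluation.
recovery_run <- function(seed) {
  key <- paste0("run_", seed)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  cohort <- simulate_cohort(cohort_config(seed = seed))
  graph <- build_patient_graph(cohort$clinical)
  mask <- signature_mask(cohort$signatures, rownames(cohort$expression))
  fit <- train_survival_gnn(cohort$expression, cohort$clinical, graph, mask,
                            model_config(seed = seed + 1000L))
  risk <- predict_risk(fit, cohort$expression, graph)
  te <- fit$split$test
  cl <- cohort$clinical[match(te, cohort$clinical$patient_id), ]
  test_c <- concordance_index(risk[te], cl$time, cl$event)
  true_c <- concordance_index(cohort$true_linear_predictor[te],
                              cl$time, cl$event)
  lr <- suppressWarnings(median_split_logrank(risk[te], cl$time, cl$event))
  out <- list(cohort = cohort, graph = graph, mask = mask, fit = fit,
              risk = risk, test_c = test_c, true_c = true_c,
              logrank_p = lr$p_value)
  .run_cache[[key]] <- out
  out
}

RECOVERY_SEEDS <- 1:20
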