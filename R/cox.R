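## Survival-side primitives of the model: the negative log Cox partial
## likelihood (Breslow / Efron ties) with its analytic gradient — the training
## loss of the graph transformer head — plus Harrell's concordance index and
## median-risk stratification with a log-rank test.

#' Negative log Cox partial likelihood
#'
#' Computes the (unnormalized) negative log partial likelihood of a vector of
#' relative log hazards under right censoring, with Breslow (default) or
#' Efron handling of tied event times. Returns 0 with a warning when there
#' are no events. The analytic gradient with respect to the risk vector is
#' attached as attribute `"gradient"` when `gradient = TRUE`.
#'
#' @param risk Per-patient relative log hazard.
#' @param time Positive follow-up times.
#' @param event 0/1 event indicators.
#' @param ties `"breslow"` or `"efron"`.
#' @param gradient Attach the analytic gradient?
#' @return Non-negative scalar loss (attribute `"gradient"` optional).
#' @export
cox_partial_likelihood <- function(risk, time, event, ties = c("breslow", "efron"),
                                   gradient = FALSE) {
  ties <- match.arg(ties)
  n <- length(risk)
  assert_that(length(time) == n && length(event) == n,
              "risk, time and event must have equal length")
  assert_that(all(time > 0), "all times must be positive")
  assert_that(all(event %in% c(0, 1)), "event must be 0/1")
  if (sum(event) == 0) {
    warning("no events: Cox partial likelihood is identically zero")
    out <- 0
    if (gradient) attr(out, "gradient") <- numeric(n)
    return(out)
  }
  m <- max(risk)
  e_eta <- exp(risk - m)

  ## risk-set sums per distinct event time (time >= t)
  ev_times <- sort(unique(time[event == 1]))
  S <- vapply(ev_times, function(t) sum(e_eta[time >= t]), numeric(1))
  d <- vapply(ev_times, function(t) sum(event == 1 & time == t), numeric(1))

  if (ties == "breslow") {
    loss <- -sum(risk[event == 1] - m) + sum(d * log(S))
    if (gradient) {
      ratio <- d / S
      cum_ratio <- cumsum(ratio)  # over event times ascending
      ## A_j = sum over event times <= t_j of d/S
      idx <- findInterval(time, ev_times)
      A <- ifelse(idx >= 1, cum_ratio[pmax(idx, 1L)], 0)
      A[idx < 1] <- 0
      grad <- -event + e_eta * A
      attr(loss, "gradient") <- grad
    }
  } else {
    loss <- -sum(risk[event == 1] - m)
    grad <- if (gradient) -as.numeric(event) else NULL
    for (k in seq_along(ev_times)) {
      t_k <- ev_times[k]
      tied <- which(event == 1 & time == t_k)
      dk <- length(tied)
      Ek <- sum(e_eta[tied])
      l <- seq_len(dk) - 1
      denom <- S[k] - (l / dk) * Ek
      loss <- loss + sum(log(denom))
      if (gradient) {
        in_risk <- which(time >= t_k)
        coef_all <- sum(1 / denom)
        coef_tied <- sum((1 - l / dk) / denom)
        grad[in_risk] <- grad[in_risk] + e_eta[in_risk] * coef_all
        grad[tied] <- grad[tied] + e_eta[tied] * (coef_tied - coef_all)
      }
    }
    if (gradient) attr(loss, "gradient") <- grad
  }
  loss
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs whose risk ordering agrees with their
#' survival ordering. A pair is comparable when the patient with the shorter
#' time had an event (strictly earlier), or when times are tied and exactly
#' one of the two had the event (the event patient counts as earlier).
#' Tied risks on comparable pairs count 0.5. Pairs rendered unorderable by
#' censoring are excluded.
#'
#' @inheritParams cox_partial_likelihood
#' @return C in `[0, 1]`; errors when no pair is comparable.
#' @export
concordance_index <- function(risk, time, event) {
  n <- length(risk)
  assert_that(length(time) == n && length(event) == n,
              "risk, time and event must have equal length")
  ## comparable[i, j]: i is the (strictly) earlier event relative to j
  earlier <- outer(time, time, `<`) & (event == 1)
  tied_t <- outer(time, time, `==`) & outer(event == 1, event == 0, `&`)
  comp <- earlier | tied_t
  diag(comp) <- FALSE
  n_comp <- sum(comp)
  if (n_comp == 0) {
    stop_ctg("no comparable pairs under censoring",
             class = "ctgsurv_concordance_error")
  }
  higher <- outer(risk, risk, `>`)
  tied_r <- outer(risk, risk, `==`)
  (sum(higher & comp) + 0.5 * sum(tied_r & comp)) / n_comp
}

#' Median-risk stratification with a log-rank test
#'
#' Splits patients at the median predicted risk (a patient exactly at the
#' median goes to the low-risk group), runs the two-group log-rank test, and
#' exports Kaplan-Meier step functions per group.
#'
#' @param risk Named per-patient risk (names = patient ids) or plain vector.
#' @param time,event Survival outcome, aligned with `risk`.
#' @return List: `groups` (factor `"high"`/`"low"`), `statistic` (log-rank
#'   chi-square), `p_value`, `km` (per-group data frames of `time`, `surv`,
#'   `n_risk`, `n_event`), `warning` (NULL or text when a group has no
#'   events).
#' @export
median_split_logrank <- function(risk, time, event) {
  n <- length(risk)
  assert_that(n >= 4, "need at least 4 patients")
  med <- stats::median(risk)
  grp <- factor(ifelse(risk > med, "high", "low"), levels = c("high", "low"))
  if (length(unique(grp)) < 2) {
    stop_ctg("all risks on one side of the median: cannot stratify",
             class = "ctgsurv_stratification_error")
  }
  warn <- NULL
  ev_by_grp <- tapply(event, grp, sum)
  if (any(ev_by_grp == 0)) {
    warn <- paste("group(s) with zero events:",
                  paste(names(ev_by_grp)[ev_by_grp == 0], collapse = ", "))
    warning(warn)
  }
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ grp)
  stat <- sd_$chisq
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  fit <- survival::survfit(survival::Surv(time, event) ~ grp)
  km <- list()
  strata_names <- rep(names(fit$strata), fit$strata)
  for (g in levels(grp)) {
    sel <- strata_names == paste0("grp=", g)
    km[[g]] <- data.frame(time = fit$time[sel], surv = fit$surv[sel],
                          n_risk = fit$n.risk[sel], n_event = fit$n.event[sel])
  }
  list(groups = stats::setNames(grp, names(risk)), statistic = stat,
       p_value = p, km = km, warning = warn)
}
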