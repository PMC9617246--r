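#' @importFrom stats pchisq
NULL

#' Dichotomize survival at a horizon for ROC analysis
#'
#' Death within the horizon is the positive class; patients censored before
#' the horizon carry no definitive outcome and are excluded; everyone
#' followed to the horizon without an event (event after the horizon or
#' censoring at/after it) is negative.
#'
#' @param time Follow-up time (days).
#' @param event Logical; `TRUE` = death, `FALSE` = censored.
#' @param horizon Prediction horizon in the same units as `time`.
#' @return Logical vector (`TRUE` = positive) with `NA` for excluded
#'   patients.
#' @export
dichotomize_at_horizon <- function(time, event, horizon) {
  stopifnot(length(time) == length(event), all(time > 0))
  out <- rep(NA, length(time))
  out[event & time <= horizon] <- TRUE
  out[time > horizon] <- FALSE
  out[!event & time == horizon] <- FALSE
  out
}

#' Empirical ROC curve and AUC for a survival biomarker
#'
#' Dichotomizes the outcome at `horizon` (see [dichotomize_at_horizon()]),
#' then sweeps all distinct marker values as thresholds, calling
#' `marker >= threshold` positive (higher marker predicts death). The AUC
#' equals the normalized Mann-Whitney U statistic, with tied marker pairs
#' contributing 1/2.
#'
#' @param time,event,marker Per-patient follow-up time, event flag, and
#'   baseline biomarker value.
#' @param horizon Dichotomization horizon (days).
#' @return A list of class `roc_curve`: `points` (threshold, sensitivity,
#'   specificity), `auc`, `n_pos`, `n_neg`, `horizon`.
#' @export
roc_auc <- function(time, event, marker, horizon) {
  stopifnot(all(is.finite(marker)))
  y <- dichotomize_at_horizon(time, event, horizon)
  keep <- !is.na(y)
  y <- y[keep]
  marker <- marker[keep]
  n_pos <- sum(y)
  n_neg <- sum(!y)
  if (n_pos == 0 || n_neg == 0) {
    stop("a class is empty after horizon dichotomization", call. = FALSE)
  }
  # AUC via rank-sum (average ranks handle ties as 1/2)
  rk <- rank(marker, ties.method = "average")
  u <- sum(rk[y]) - n_pos * (n_pos + 1) / 2
  auc <- u / (n_pos * n_neg)
  thresholds <- c(sort(unique(marker)), Inf)
  points <- data.frame(
    threshold = thresholds,
    sensitivity = vapply(thresholds,
                         function(t) mean(marker[y] >= t), numeric(1)),
    specificity = vapply(thresholds,
                         function(t) mean(marker[!y] < t), numeric(1))
  )
  structure(list(points = points, auc = auc, n_pos = n_pos, n_neg = n_neg,
                 horizon = horizon),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f (%d positives, %d negatives, horizon %g)\n",
              x$auc, x$n_pos, x$n_neg, x$horizon))
  invisible(x)
}

#' Optimal cutoff by the Youden index
#'
#' Maximizes `J = sensitivity + specificity - 1` over the ROC thresholds;
#' ties are broken toward the higher threshold (the more conservative
#' cutoff, calling fewer positives).
#'
#' @param curve A `roc_curve` from [roc_auc()].
#' @return List of class `cutoff_result`: `threshold`, `j`, `sensitivity`,
#'   `specificity`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  p <- curve$points
  p <- p[is.finite(p$threshold), , drop = FALSE]
  j <- p$sensitivity + p$specificity - 1
  best <- max(j)
  idx <- max(which(j >= best - 1e-12))  # highest threshold among ties
  structure(list(threshold = p$threshold[idx], j = j[idx],
                 sensitivity = p$sensitivity[idx],
                 specificity = p$specificity[idx]),
            class = "cutoff_result")
}

#' Kaplan-Meier product-limit estimator
#'
#' At each distinct event time `t_i` with `d_i` deaths among `n_i` at risk,
#' `S(t)` is multiplied by `1 - d_i/n_i`; censored subjects leave the risk
#' set after their censoring time.
#'
#' @param time,event Follow-up times and event flags.
#' @return A list of class `km_fit` with a `steps` data.frame (`time`,
#'   `n_risk`, `n_event`, `n_censor`, `survival`) over all distinct
#'   observation times, and `n` subjects. `S(0) = 1` implicitly.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, all(time > 0),
            length(time) == length(event))
  times <- sort(unique(time))
  surv <- 1
  rows <- lapply(times, function(t) {
    n_risk <- sum(time >= t)
    d <- sum(time == t & event)
    cns <- sum(time == t & !event)
    if (d > 0) surv <<- surv * (1 - d / n_risk)
    data.frame(time = t, n_risk = n_risk, n_event = d, n_censor = cns,
               survival = surv)
  })
  structure(list(steps = do.call(rbind, rows), n = length(time)),
            class = "km_fit")
}

#' Survival probability at given times from a Kaplan-Meier fit
#'
#' @param fit A `km_fit`.
#' @param t Times at which to evaluate the step function.
#' @return `S(t)` (right-continuous; 1 before the first event).
#' @export
km_survival_at <- function(fit, t) {
  stopifnot(inherits(fit, "km_fit"))
  vapply(t, function(tt) {
    prior <- fit$steps$survival[fit$steps$time <= tt]
    if (length(prior) == 0) 1 else prior[length(prior)]
  }, numeric(1))
}

#' @export
print.km_fit <- function(x, ...) {
  cat(sprintf("Kaplan-Meier fit: %d subjects, %d events\n",
              x$n, sum(x$steps$n_event)))
  invisible(x)
}

#' Two-sample log-rank test
#'
#' At each distinct event time, compares the observed deaths in group A with
#' the hypergeometric expectation given the pooled risk set; the statistic
#' `(sum(O - E))^2 / sum(V)` is referred to a chi-square distribution with
#' one degree of freedom. Symmetric in the group labels.
#'
#' @param time_a,event_a,time_b,event_b Per-group follow-up times and event
#'   flags.
#' @return List of class `logrank_result`: `statistic`, `df`, `p_value`,
#'   `observed` and `expected` deaths per group.
#' @export
logrank_test <- function(time_a, event_a, time_b, event_b) {
  stopifnot(length(time_a) >= 1, length(time_b) >= 1)
  if (!any(event_a) && !any(event_b)) {
    stop("log-rank test undefined: no events in either group", call. = FALSE)
  }
  event_times <- sort(unique(c(time_a[event_a], time_b[event_b])))
  o_minus_e <- 0
  v <- 0
  obs_a <- 0
  exp_a <- 0
  for (t in event_times) {
    n1 <- sum(time_a >= t)
    n2 <- sum(time_b >= t)
    n <- n1 + n2
    d1 <- sum(time_a == t & event_a)
    d2 <- sum(time_b == t & event_b)
    d <- d1 + d2
    if (n == 0 || d == 0) next
    e1 <- d * n1 / n
    o_minus_e <- o_minus_e + (d1 - e1)
    obs_a <- obs_a + d1
    exp_a <- exp_a + e1
    if (n > 1) v <- v + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  if (v == 0) stop("log-rank variance is zero (degenerate risk sets)",
                   call. = FALSE)
  stat <- o_minus_e^2 / v
  structure(list(statistic = stat, df = 1L,
                 p_value = pchisq(stat, df = 1, lower.tail = FALSE),
                 observed = c(a = obs_a, b = sum(event_a) + sum(event_b) -
                                obs_a),
                 expected = c(a = exp_a, b = sum(c(event_a, event_b)) -
                                exp_a)),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: chi-square = %.4f (df = 1), p = %.4g\n",
              x$statistic, x$p_value))
  invisible(x)
}
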