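# Survival evaluation: Harrell's concordance index, the Kaplan-Meier
# product-limit estimator, the two-group log-rank (Mantel) test,
# median-risk dichotomisation, and the paired t-test used to compare
# cross-validated runs.

#' Harrell's concordance index
#'
#' Over all usable sample pairs — a pair is usable iff the member with
#' the strictly earlier time carries an event — a pair is concordant
#' when the shorter-lived sample has the higher predicted risk; risk
#' ties count 1/2.  `C = (concordant + 0.5 * tied) / usable`.
#'
#' @param risk numeric risk scores (higher = worse prognosis).
#' @param time follow-up times or a [survival_data].
#' @param event 0/1 event indicators (ignored when `time` is a
#'   [survival_data]).
#' @return scalar in `[0, 1]`; errors when no pair is usable.
#' @export
concordance_index <- function(risk, time, event = NULL) {
  se <- as_time_event(time, event)
  n <- length(risk)
  stopifnot(length(se$time) == n)
  conc <- 0; tied <- 0; usable <- 0
  for (i in which(se$event == 1)) {
    # pairs (i, j) with Y_i < Y_j: i is the usable earlier event
    later <- se$time > se$time[i]
    usable <- usable + sum(later)
    conc <- conc + sum(risk[i] > risk[later])
    tied <- tied + sum(risk[i] == risk[later])
  }
  if (usable == 0) stop("no usable pairs for the concordance index")
  (conc + 0.5 * tied) / usable
}

#' Kaplan-Meier product-limit estimator
#'
#' `S(t) = prod over event times t_k <= t of (1 - d_k / n_k)`.
#' Censored-only times shrink the risk set but leave `S` unchanged.
#'
#' @param time follow-up times or a [survival_data].
#' @param event 0/1 event indicators.
#' @return data frame of class `km_curve`: one row per distinct observed
#'   time with columns `time`, `n_risk`, `n_event`, `n_censor`,
#'   `survival`.
#' @export
kaplan_meier <- function(time, event = NULL) {
  se <- as_time_event(time, event)
  if (!length(se$time)) stop("need at least one sample")
  ut <- sort(unique(se$time))
  n_risk <- vapply(ut, function(t) sum(se$time >= t), numeric(1))
  n_event <- vapply(ut, function(t) sum(se$time == t & se$event == 1),
                    numeric(1))
  n_censor <- vapply(ut, function(t) sum(se$time == t & se$event == 0),
                     numeric(1))
  surv <- cumprod(1 - n_event / n_risk)
  structure(data.frame(time = ut, n_risk = n_risk, n_event = n_event,
                       n_censor = n_censor, survival = surv),
            class = c("km_curve", "data.frame"))
}

#' Evaluate a Kaplan-Meier curve at arbitrary times
#' @param km a `km_curve`.
#' @param t numeric times.
#' @return survival probabilities (1 before the first observed time).
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(x) {
    rows <- km$time <= x
    if (!any(rows)) 1 else km$survival[max(which(rows))]
  }, numeric(1))
}

#' Two-group log-rank (Mantel) test
#'
#' At each distinct event time the observed events in group A are
#' compared with their hypergeometric expectation given the pooled risk
#' set; `chisq = (O - E)^2 / V` with a two-sided p-value from the 1-df
#' chi-square tail.
#'
#' @param surv_a,surv_b [survival_data] for the two groups, or numeric
#'   time vectors with `event_a`/`event_b` supplied.
#' @param event_a,event_b 0/1 vectors when times are passed directly.
#' @return list with `chisq`, `p_value`, `observed` (group A), and
#'   `expected` (group A).
#' @export
logrank_test <- function(surv_a, surv_b, event_a = NULL, event_b = NULL) {
  a <- as_time_event(surv_a, event_a)
  b <- as_time_event(surv_b, event_b)
  if (!length(a$time) || !length(b$time)) stop("both groups must be non-empty")
  time <- c(a$time, b$time)
  event <- c(a$event, b$event)
  grp <- rep(c(0L, 1L), c(length(a$time), length(b$time)))
  if (!any(event == 1)) stop("need at least one event overall")
  ev_times <- sort(unique(time[event == 1]))
  O <- 0; E <- 0; V <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n_a <- sum(at_risk & grp == 0L)
    d <- sum(time == t & event == 1)
    d_a <- sum(time == t & event == 1 & grp == 0L)
    O <- O + d_a
    E <- E + d * n_a / n
    if (n > 1)
      V <- V + d * (n_a / n) * (1 - n_a / n) * (n - d) / (n - 1)
  }
  if (V <= 0) {
    warning("zero log-rank variance; p-value set to 1")
    return(list(chisq = 0, p_value = 1, observed = O, expected = E))
  }
  chisq <- (O - E)^2 / V
  list(chisq = chisq, p_value = stats::pchisq(chisq, df = 1,
                                              lower.tail = FALSE),
       observed = O, expected = E)
}

#' Split samples at the median risk
#'
#' Label 1 (high risk) iff `risk > median(risk)`; samples exactly at the
#' median go to the low-risk group, so group sizes differ by at most the
#' number of exact-median ties.
#'
#' @param risk numeric vector.
#' @return integer 0/1 labels.
#' @export
dichotomize_by_median <- function(risk) {
  as.integer(risk > stats::median(risk))
}

#' Paired two-sided t-test
#'
#' Classical paired t on the differences `a - b` with `n - 1` degrees of
#' freedom.  All-zero differences (or zero variance) return `t = 0`,
#' `p = 1` rather than NaN.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return list with `t`, `p_value`, `df`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  s <- stats::sd(d)
  if (s == 0) return(list(t = 0, p_value = 1, df = n - 1))
  t_stat <- mean(d) / (s / sqrt(n))
  list(t = t_stat,
       p_value = 2 * stats::pt(-abs(t_stat), df = n - 1),
       df = n - 1)
}

#' Median-split survival comparison of a risk vector
#'
#' Convenience wrapper: dichotomise risks at the median and run the
#' log-rank test between the two groups.
#'
#' @param risk numeric risks.
#' @param surv matching [survival_data].
#' @return list with `labels` and the [logrank_test] result `logrank`.
#' @export
median_split_logrank <- function(risk, surv) {
  labels <- dichotomize_by_median(risk)
  if (all(labels == labels[1])) stop("median split produced a single group")
  lr <- logrank_test(survival_data(surv$time[labels == 0],
                                   surv$event[labels == 0]),
                     survival_data(surv$time[labels == 1],
                                   surv$event[labels == 1]))
  list(labels = labels, logrank = lr)
}

#' Export a Kaplan-Meier curve as CSV
#' @param km a `km_curve`.
#' @param path output path.
#' @export
write_km <- function(km, path) {
  utils::write.csv(as.data.frame(km), path, row.names = FALSE)
  invisible(path)
}
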