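#' Exclude short-follow-up patients
#'
#' Drops records whose survival time is below `min_days` (strictly less
#' than; a time exactly at the threshold is retained). Short-follow-up
#' deaths often reflect perioperative events rather than tumor biology, so
#' survival analyses here exclude them by default.
#'
#' @param data data frame with columns `time` (days) and `event` (0/1).
#' @param min_days threshold in days (default 30).
#' @return the filtered data frame.
#' @export
filter_min_followup <- function(data, min_days = 30) {
  .check_surv(data)
  keep <- data$time >= min_days
  if (!any(keep)) stop("all records have follow-up below ", min_days, " days")
  data[keep, , drop = FALSE]
}

.check_surv <- function(data) {
  if (!all(c("time", "event") %in% names(data)))
    stop("survival data needs `time` and `event` columns")
  if (any(data$time <= 0)) stop("survival times must be positive")
  if (!all(data$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(data)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over event times, with the
#' Greenwood standard error. Censored observations at an event time remain
#' at risk for that time (standard convention).
#'
#' @param data data frame with `time` and `event`.
#' @return data frame with one row per event time: `time`, `n_at_risk`,
#'   `n_events`, `survival`, `std_err` (Greenwood SE of S).
#' @export
km_estimate <- function(data) {
  .check_surv(data)
  if (sum(data$event) == 0) {
    warning("no events: survival curve is constant 1")
    return(data.frame(time = numeric(0), n_at_risk = integer(0),
                      n_events = integer(0), survival = numeric(0),
                      std_err = numeric(0)))
  }
  fit <- survival::survfit(survival::Surv(time, event) ~ 1, data = data)
  s <- summary(fit, censored = FALSE)
  keep <- s$n.event > 0
  data.frame(time = s$time[keep], n_at_risk = s$n.risk[keep],
             n_events = s$n.event[keep], survival = s$surv[keep],
             std_err = s$std.err[keep])
}

#' Multi-group log-rank test
#'
#' Observed-minus-expected chi-square over event times with hypergeometric
#' variance; `df = groups - 1`.
#'
#' @param data data frame with `time` and `event`.
#' @param labels group labels, one per row of `data`.
#' @return list with `chi_square`, `df`, `p`.
#' @export
logrank_test <- function(data, labels) {
  .check_surv(data)
  labels <- droplevels(as.factor(labels))
  if (nlevels(labels) < 2) stop("need >= 2 non-empty groups")
  if (sum(data$event) == 0) stop("no events in the data")
  sd <- survival::survdiff(
    survival::Surv(time, event) ~ g,
    data = data.frame(time = data$time, event = data$event, g = labels))
  df <- nlevels(labels) - 1
  list(chi_square = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df, lower.tail = FALSE))
}

# Standardized two-group log-rank statistic Z = (O1 - E1) / sqrt(V) for the
# split `in_high` (logical). Used by the maximally selected cutpoint scan;
# Z^2 equals the two-group log-rank chi-square.
.logrank_z <- function(time, event, in_high) {
  et <- sort(unique(time[event == 1]))
  O <- E <- V <- 0
  for (t in et) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & in_high)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & in_high)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  if (V <= 0) return(0)
  (O - E) / sqrt(V)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Scans candidate cutpoints (midpoints between consecutive distinct score
#' values whose induced groups both contain at least `minprop * n` samples)
#' and returns the one maximizing the absolute standardized two-group
#' log-rank statistic. This is the "optimal cutoff" used to split a
#' continuous marker into high/low prognostic groups; the selection process
#' inflates downstream log-rank p-values, which are reported uncorrected.
#'
#' @param scores numeric vector, one per sample.
#' @param data data frame with `time` and `event`, same order as `scores`.
#' @param minprop minimum proportion of samples on each side (default 0.1).
#' @return list of class `cutpoint_result`: `cutpoint`,
#'   `max_standardized_statistic`, `n_candidates`, `candidates` (data frame
#'   of cutpoint and statistic).
#' @export
maxstat_cutpoint <- function(scores, data, minprop = 0.1) {
  .check_surv(data)
  n <- length(scores)
  if (n != nrow(data)) stop("scores and survival data must align")
  if (n < 20) stop("need at least 20 samples for cutpoint selection")
  u <- sort(unique(scores))
  if (length(u) < 2) stop("all scores are identical")
  mids <- (u[-1] + u[-length(u)]) / 2
  n_low <- vapply(mids, function(c) sum(scores <= c), numeric(1))
  ok <- n_low >= minprop * n & (n - n_low) >= minprop * n
  if (!any(ok)) stop("no candidate cutpoint satisfies minprop = ", minprop)
  mids <- mids[ok]
  z <- vapply(mids, function(c)
    .logrank_z(data$time, data$event, scores > c), numeric(1))
  best <- which.max(abs(z))
  structure(list(cutpoint = mids[best],
                 max_standardized_statistic = abs(z[best]),
                 n_candidates = length(mids),
                 candidates = data.frame(cutpoint = mids, statistic = z)),
            class = "cutpoint_result")
}
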