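#' Kaplan-Meier survival curve for one group
#'
#' Product-limit estimate of the survival function over the distinct event
#' times, with Greenwood standard errors, computed through
#' [survival::survfit()]. With no censoring the estimate equals one minus
#' the empirical CDF of the death times.
#'
#' @param records data.frame with columns `time` (days, > 0) and `event`
#'   (1 death, 0 censored) for a single group.
#' @return list of class `km_curve`: `times` (distinct event times),
#'   `n_at_risk`, `n_events`, `survival`, `greenwood_se`, `n` (subjects).
#'   Censored-only input yields a flat curve at 1 (no event times).
#' @export
km_estimate <- function(records) {
  check_survival_records(records)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = records,
                          conf.type = "none")
  keep <- sf$n.event > 0
  structure(list(times = sf$time[keep],
                 n_at_risk = sf$n.risk[keep],
                 n_events = sf$n.event[keep],
                 survival = sf$surv[keep],
                 greenwood_se = sf$std.err[keep] * sf$surv[keep],
                 n = nrow(records)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  if (length(x$times) == 0) {
    cat("Kaplan-Meier: no events (S = 1 throughout), n =", x$n, "\n")
    return(invisible(x))
  }
  print(data.frame(time = x$times, n_at_risk = x$n_at_risk,
                   n_events = x$n_events, survival = x$survival,
                   se = x$greenwood_se))
  invisible(x)
}

#' Mantel-Cox log-rank test across groups
#'
#' Observed-minus-expected chi-squared over the pooled event times with
#' hypergeometric variance, via [survival::survdiff()] (`rho = 0`). All
#' events at a tied time share the same risk set.
#'
#' @param records data.frame with columns `group`, `time`, `event` covering
#'   two or more groups.
#' @return list of class `logrank_result`: `chi2`, `df` (groups - 1), `p`,
#'   `observed`, `expected` (per group).
#' @export
logrank_test <- function(records) {
  check_survival_records(records)
  groups <- unique(records$group)
  if (length(groups) < 2) stop("need >= 2 groups for a log-rank test")
  if (sum(records$event) == 0) stop("no events in any group")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                           data = records, rho = 0)
  df <- length(groups) - 1
  structure(list(chi2 = unname(sd$chisq), df = df,
                 p = stats::pchisq(unname(sd$chisq), df, lower.tail = FALSE),
                 observed = sd$obs, expected = sd$exp),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("Log-rank (Mantel-Cox): chi2 = %.4f, df = %d, p = %.4g\n",
              x$chi2, x$df, x$p))
  invisible(x)
}

#' Unpaired two-sample t-test
#'
#' Pooled-variance Student t by default (df = nA + nB - 2, matching how
#' mean lethal times of donor and receiver groups are compared); Welch
#' optional.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @param pooled use the pooled-variance Student test (default TRUE);
#'   `FALSE` gives Welch.
#' @return list: `t`, `df`, `p` (two-sided), `mean_a`, `mean_b`, `pooled`.
#' @export
t_test_unpaired <- function(a, b, pooled = TRUE) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  tt <- stats::t.test(a, b, var.equal = pooled)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(a), mean_b = mean(b), pooled = pooled)
}

check_survival_records <- function(records) {
  req <- c("time", "event")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("survival records missing column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(records) < 1) stop("need >= 1 survival record")
  if (any(records$time <= 0)) stop("times must be > 0")
  if (!all(records$event %in% c(0, 1))) stop("event must be 0 or 1")
  invisible(TRUE)
}
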