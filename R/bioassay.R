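#' Conidial germination percentage and viability gate
#'
#' Mean percentage germination over coverslips (100 conidia scored per
#' coverslip in the standard protocol), with the standard error across
#' coverslips. Strains with mean germination at or below the gate (default
#' 80%) are excluded from bioassays.
#'
#' @param counts data.frame with columns `n_germinated` and `n_scored`
#'   (one row per coverslip), optionally `plate_id`, `coverslip_index`.
#' @param gate viability gate in percent; a strain passes when the mean
#'   strictly exceeds it (default 80).
#' @return list: `mean_pct`, `se_pct` (0 for a single coverslip),
#'   `n_coverslips`, `passes_gate`.
#' @export
percent_germination <- function(counts, gate = 80) {
  if (is.null(counts) || nrow(counts) < 1)
    stop("need at least one coverslip count")
  if (!all(c("n_germinated", "n_scored") %in% names(counts)))
    stop("counts must have columns 'n_germinated' and 'n_scored'")
  if (any(counts$n_germinated < 0 | counts$n_germinated > counts$n_scored))
    stop("n_germinated must lie in [0, n_scored]")
  pct <- 100 * counts$n_germinated / counts$n_scored
  k <- length(pct)
  se <- if (k > 1) stats::sd(pct) / sqrt(k) else 0
  m <- mean(pct)
  list(mean_pct = m, se_pct = se, n_coverslips = k, passes_gate = m > gate)
}

#' Cumulative mortality percentage at a given day
#'
#' Per-replicate cumulative percent mortality at `day`, then the mean and
#' standard error across replicates, per treatment.
#'
#' @param records mortality data.frame with columns `treatment_id`,
#'   `replicate`, `day`, `n_initial`, `n_dead_cum`.
#' @param day observation day (default: last day present).
#' @return data.frame: `treatment_id`, `day`, `mean_pct`, `se_pct`,
#'   `n_replicates`.
#' @export
cumulative_mortality_pct <- function(records, day = max(records$day)) {
  check_mortality_records(records)
  sub <- records[records$day == day, , drop = FALSE]
  if (nrow(sub) == 0) stop("no records at day ", day)
  out <- lapply(split(sub, sub$treatment_id), function(d) {
    reps <- unique(records$replicate[records$treatment_id == d$treatment_id[1]])
    if (!setequal(d$replicate, reps))
      stop("treatment ", d$treatment_id[1], ": day ", day,
           " missing for replicate(s) ",
           paste(setdiff(reps, d$replicate), collapse = ", "))
    pct <- 100 * d$n_dead_cum / d$n_initial
    data.frame(treatment_id = d$treatment_id[1], day = day,
               mean_pct = mean(pct),
               se_pct = if (length(pct) > 1) stats::sd(pct) / sqrt(length(pct)) else 0,
               n_replicates = length(pct), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Abbott's control-mortality correction
#'
#' Adjusts treated-group percent mortality for background mortality in the
#' untreated control: `corrected = 100 * (treated - control) / (100 -
#' control)`, floored at 0 so a treated group dying less than the control
#' reports zero fungus-attributable mortality.
#'
#' @param treated_pct treated-group cumulative mortality, percent in [0, 100].
#' @param control_pct control-group cumulative mortality, percent in [0, 100).
#' @return list: `treated_pct`, `control_pct`, `corrected_pct`.
#' @export
abbott_correct <- function(treated_pct, control_pct) {
  if (any(control_pct >= 100))
    stop("control_pct must be < 100 (correction undefined at 100)")
  if (any(control_pct < 0) || any(treated_pct < 0) || any(treated_pct > 100))
    stop("percentages out of range: treated in [0,100], control in [0,100)")
  corrected <- pmax(0, 100 * (treated_pct - control_pct) / (100 - control_pct))
  list(treated_pct = treated_pct, control_pct = control_pct,
       corrected_pct = corrected)
}

#' Median lethal time (LT50) from time-mortality data
#'
#' Fits a binomial GLM of cumulative proportion dead on day (logit link by
#' default, probit or logit-on-log(day) optional) and inverts it at 50%
#' mortality: `LT50 = -b0 / b1`. The standard error comes from the delta
#' method on the coefficient covariance,
#' \deqn{Var(LT50) = \frac{1}{b_1^2}\left[Var(b_0) + LT50^2 Var(b_1) +
#'       2\, LT50\, Cov(b_0, b_1)\right].}
#'
#' Cumulative counts on successive days are repeated observations of the
#' same flies, so the ordinary binomial covariance understates the sampling
#' variance of the fitted curve. Because deaths are absorbing, per-fly death
#' days can be reconstructed exactly from the cumulative counts; the default
#' covariance is therefore cluster-robust at the fly level
#' ([sandwich::vcovCL()] on the per-fly Bernoulli expansion), which restores
#' nominal coverage. The model-based covariance (what `dose.p` reports) is
#' kept as `se_naive`, and is used as `se` when the robust expansion is
#' unavailable (non-integer Abbott-corrected counts).
#'
#' Replicates are pooled into the binomial denominators by default (one LT50
#' per treatment, matching how a single LT50 +/- SE per strain is reported);
#' set `per_replicate = TRUE` for one fit per replicate.
#'
#' @param records mortality data.frame (columns `treatment_id`, `replicate`,
#'   `day`, `n_initial`, `n_dead_cum`) for a single treatment, or several
#'   when `per_replicate = FALSE` and `treatment_id` is unique.
#' @param link `"logit"` (default) or `"probit"`.
#' @param log_time regress on `log(day)` instead of day (default FALSE); the
#'   returned LT50 is back-transformed to days.
#' @param control optional control-treatment records; when supplied, each
#'   day's treated percentages are Abbott-corrected against the control's
#'   pooled percentage at that day before fitting.
#' @param per_replicate fit one LT50 per replicate instead of pooling.
#' @return object of class `lt50_estimate` (or a list of them when
#'   `per_replicate = TRUE`): `lt50`, `se` (cluster-robust when available),
#'   `se_naive` (model-based), `slope`, `slope_se`, `intercept`, `link`,
#'   `n_obs`, `converged`, `note`.
#' @export
fit_time_mortality <- function(records, link = c("logit", "probit"),
                               log_time = FALSE, control = NULL,
                               per_replicate = FALSE) {
  link <- match.arg(link)
  check_mortality_records(records)
  if (per_replicate) {
    out <- lapply(split(records, records$replicate), fit_time_mortality,
                  link = link, log_time = log_time, control = control,
                  per_replicate = FALSE)
    return(out)
  }
  # pool replicates: total deaths / total flies per day
  agg_d <- tapply(records$n_dead_cum, records$day, sum)
  agg_n <- tapply(records$n_initial, records$day, sum)
  day <- as.numeric(names(agg_d))
  dead <- as.numeric(agg_d)
  n <- as.numeric(agg_n)
  if (!is.null(control)) {
    check_mortality_records(control)
    cd <- tapply(control$n_dead_cum, control$day, sum)
    cn <- tapply(control$n_initial, control$day, sum)
    ctrl_pct <- 100 * as.numeric(cd) / as.numeric(cn)
    names(ctrl_pct) <- names(cd)
    cp <- ctrl_pct[as.character(day)]
    if (any(is.na(cp)))
      stop("control series missing day(s): ",
           paste(day[is.na(cp)], collapse = ", "))
    corr <- abbott_correct(100 * dead / n, cp)$corrected_pct
    dead <- corr / 100 * n  # corrected effective deaths, may be non-integer
  }
  informative <- dead > 0 & dead < n
  note <- NULL
  if (sum(informative) == 0 || length(unique(day)) < 2) {
    note <- "degenerate time-mortality data (no partial-mortality days)"
  }
  x <- if (log_time) log(day) else day
  fit <- suppressWarnings(stats::glm(cbind(dead, n - dead) ~ x,
                                     family = stats::binomial(link = link)))
  co <- stats::coef(fit)
  V_naive <- stats::vcov(fit)
  V <- V_naive
  robust <- FALSE
  if (is.null(control)) {
    Vr <- try(fly_cluster_vcov(records, link = link, log_time = log_time),
              silent = TRUE)
    if (!inherits(Vr, "try-error") && all(is.finite(Vr))) {
      V <- Vr
      robust <- TRUE
    }
  }
  delta_se <- function(V, b0, b1, lt50_x) {
    v <- (1 / b1^2) * (V[1, 1] + lt50_x^2 * V[2, 2] + 2 * lt50_x * V[1, 2])
    sqrt(max(v, 0))
  }
  b0 <- unname(co[1]); b1 <- unname(co[2])
  lt50_x <- -b0 / b1
  lt50 <- if (log_time) exp(lt50_x) else lt50_x
  back <- if (log_time) exp(lt50_x) else 1
  se <- back * delta_se(V, b0, b1, lt50_x)
  se_naive <- back * delta_se(V_naive, b0, b1, lt50_x)
  converged <- isTRUE(fit$converged) && is.finite(lt50) && is.null(note)
  if (b1 <= 0) {
    note <- c(note, "non-positive slope: mortality does not increase with time")
    converged <- FALSE
  }
  structure(list(lt50 = lt50, se = se, se_naive = se_naive, slope = b1,
                 slope_se = sqrt(V[2, 2]), intercept = b0, link = link,
                 log_time = log_time, n_obs = length(day),
                 converged = converged, robust_se = robust,
                 note = if (is.null(note)) NA_character_ else
                   paste(note, collapse = "; "),
                 glm_fit = fit),
            class = "lt50_estimate")
}

#' @export
print.lt50_estimate <- function(x, ...) {
  cat(sprintf("LT50 = %.3f +/- %.3f days (slope %.4f +/- %.4f, %s link)%s\n",
              x$lt50, x$se, x$slope, x$slope_se, x$link,
              if (!x$converged) "  [NOT converged]" else ""))
  if (!is.na(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Classify a strain's SIT compatibility from its LT50
#'
#' A fungal strain is SIT-compatible when its median lethal time leaves
#' released sterile males alive and competitive long enough to mate but
#' still kills: strains killing faster than the lower bound are `too_fast`,
#' slower than the upper bound `too_slow`. Boundary values are compatible.
#'
#' @param lt50 median lethal time in days (finite, > 0); vectorised.
#' @param window length-2 numeric, compatibility window in days
#'   (default `c(10, 20)`).
#' @param strain optional strain label(s).
#' @return data.frame: `strain`, `lt50`, `class` (factor with levels
#'   `too_fast`, `compatible`, `too_slow`).
#' @export
classify_sit_compatible <- function(lt50, window = c(10, 20), strain = NULL) {
  stopifnot(length(window) == 2, window[1] < window[2])
  if (any(!is.finite(lt50)) || any(lt50 <= 0))
    stop("lt50 must be finite and > 0")
  cls <- ifelse(lt50 < window[1], "too_fast",
                ifelse(lt50 > window[2], "too_slow", "compatible"))
  data.frame(strain = if (is.null(strain)) NA_character_ else strain,
             lt50 = lt50,
             class = factor(cls, levels = c("too_fast", "compatible",
                                            "too_slow")),
             stringsAsFactors = FALSE)
}

# Cluster-robust coefficient covariance at the fly level. Deaths are
# absorbing, so each replicate's cumulative counts determine its flies'
# death days exactly (flies within a replicate are exchangeable); the GLM is
# refitted on the per-fly Bernoulli expansion and sandwich::vcovCL clusters
# on the fly.
fly_cluster_vcov <- function(records, link, log_time) {
  rows <- do.call(rbind, lapply(
    split(records, interaction(records$treatment_id, records$replicate,
                               drop = TRUE)),
    function(d) {
      d <- d[order(d$day), ]
      if (any(abs(d$n_dead_cum - round(d$n_dead_cum)) > 1e-9))
        stop("non-integer counts: cannot expand to flies")
      n <- d$n_initial[1]
      deaths_new <- diff(c(0, d$n_dead_cum))
      death_day <- rep(Inf, n)
      idx <- 1
      for (i in seq_along(d$day)) {
        k <- deaths_new[i]
        if (k > 0) {
          death_day[idx:(idx + k - 1)] <- d$day[i]
          idx <- idx + k
        }
      }
      g <- expand.grid(fly = seq_len(n), day = d$day)
      data.frame(y = as.integer(death_day[g$fly] <= g$day), day = g$day,
                 fly_id = paste(d$treatment_id[1], d$replicate[1], g$fly))
    }))
  rows$x <- if (log_time) log(rows$day) else rows$day
  f <- suppressWarnings(stats::glm(y ~ x, family = stats::binomial(link),
                                   data = rows))
  sandwich::vcovCL(f, cluster = rows$fly_id)
}

check_mortality_records <- function(records) {
  req <- c("treatment_id", "replicate", "day", "n_initial", "n_dead_cum")
  missing <- setdiff(req, names(records))
  if (length(missing))
    stop("mortality records missing column(s): ",
         paste(missing, collapse = ", "))
  if (any(records$n_dead_cum < 0 | records$n_dead_cum > records$n_initial))
    stop("n_dead_cum must lie in [0, n_initial]")
  for (key in split(records, interaction(records$treatment_id,
                                         records$replicate, drop = TRUE))) {
    d <- key[order(key$day), ]
    if (is.unsorted(d$n_dead_cum))
      stop("cumulative deaths decrease over time for treatment '",
           d$treatment_id[1], "', replicate '", d$replicate[1], "'")
  }
  invisible(TRUE)
}
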