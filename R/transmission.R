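#' Conidia concentration from hemocytometer counts
#'
#' Standard improved-Neubauer conversion: the mean count per large square
#' (1 mm^2 x 0.1 mm depth = 1e-4 mL) times 1e4 gives conidia/mL of the
#' counted suspension, multiplied by the dilution factor.
#'
#' @param square_counts nonnegative counts, one per large square (>= 1).
#' @param dilution dilution factor (>= 1, default 1).
#' @param volume_factor per-mL multiplier of the mean square count
#'   (default 1e4, the improved-Neubauer large-square constant).
#' @return conidia per mL.
#' @export
conidia_concentration <- function(square_counts, dilution = 1,
                                  volume_factor = 1e4) {
  if (length(square_counts) < 1) stop("need >= 1 square count")
  if (any(square_counts < 0)) stop("square counts must be >= 0")
  if (dilution < 1) stop("dilution factor must be >= 1")
  mean(square_counts) * volume_factor * dilution
}

#' Summarise conidia acquisition and retention
#'
#' Group means and standard errors of conidia load per (role, sex, day), and
#' a log-linear decay slope per (role, sex): OLS of `ln(load)` on day, so
#' that loads decaying as `L0 * r^day` give slope `ln(r)`. Zero loads are
#' excluded from the decay fit (log undefined) with the excluded count
#' reported; no pseudo-count is added.
#'
#' @param loads data.frame with columns `role`, `sex`, `day_post_exposure`,
#'   `conidia_per_ml` (see [gen_transmission()]).
#' @return list: `by_day` data.frame (role, sex, day_post_exposure, n,
#'   mean_load, se_load), `decay` data.frame (role, sex, slope,
#'   daily_retention = exp(slope), n_used, n_zero_excluded; slope `NA` with
#'   fewer than 2 distinct days of positive loads).
#' @export
retention_summary <- function(loads) {
  req <- c("role", "sex", "day_post_exposure", "conidia_per_ml")
  missing <- setdiff(req, names(loads))
  if (length(missing))
    stop("loads missing column(s): ", paste(missing, collapse = ", "))
  if (nrow(loads) == 0)
    return(list(by_day = data.frame(role = character(), sex = character(),
                                    day_post_exposure = numeric(),
                                    n = integer(), mean_load = numeric(),
                                    se_load = numeric()),
                decay = data.frame(role = character(), sex = character(),
                                   slope = numeric(),
                                   daily_retention = numeric(),
                                   n_used = integer(),
                                   n_zero_excluded = integer())))
  if (any(loads$conidia_per_ml < 0)) stop("conidia_per_ml must be >= 0")
  key3 <- interaction(loads$role, loads$sex, loads$day_post_exposure,
                      drop = TRUE)
  by_day <- do.call(rbind, lapply(split(loads, key3), function(d) {
    x <- d$conidia_per_ml
    data.frame(role = d$role[1], sex = d$sex[1],
               day_post_exposure = d$day_post_exposure[1],
               n = length(x), mean_load = mean(x),
               se_load = if (length(x) > 1) stats::sd(x) / sqrt(length(x)) else 0,
               stringsAsFactors = FALSE)
  }))
  key2 <- interaction(loads$role, loads$sex, drop = TRUE)
  decay <- do.call(rbind, lapply(split(loads, key2), function(d) {
    pos <- d[d$conidia_per_ml > 0, , drop = FALSE]
    n_zero <- nrow(d) - nrow(pos)
    slope <- NA_real_
    if (nrow(pos) >= 2 && length(unique(pos$day_post_exposure)) >= 2) {
      fit <- stats::lm(log(conidia_per_ml) ~ day_post_exposure, data = pos)
      slope <- unname(stats::coef(fit)["day_post_exposure"])
    }
    data.frame(role = d$role[1], sex = d$sex[1], slope = slope,
               daily_retention = exp(slope), n_used = nrow(pos),
               n_zero_excluded = n_zero, stringsAsFactors = FALSE)
  }))
  rownames(by_day) <- rownames(decay) <- NULL
  list(by_day = by_day[order(by_day$role, by_day$sex,
                             by_day$day_post_exposure), , drop = FALSE],
       decay = decay)
}
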