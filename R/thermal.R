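#' Absolute radial growth rate per plate
#'
#' Reduces daily colony-radius series to an absolute radial growth rate:
#' for each (strain, temperature, plate) the four quadrant radii are averaged
#' per day and the mean radius is regressed on day by ordinary least squares.
#' The slope (mm/day) is the absolute growth rate used by [fit_tpc()].
#'
#' @param series data.frame with columns `plate_id`, `strain`, `temperature`,
#'   `day` and quadrant radii `q1`..`q4` (mm), one row per plate x day.
#' @return data.frame with one row per (strain, temperature, plate_id) and
#'   columns `beta` (slope, mm/day), `intercept` (mm) and `fit_r2`
#'   (coefficient of determination; `NA` for a constant series).
#' @export
absolute_growth_rate <- function(series) {
  req <- c("plate_id", "strain", "temperature", "day", "q1", "q2", "q3", "q4")
  missing <- setdiff(req, names(series))
  if (length(missing))
    stop("series is missing column(s): ", paste(missing, collapse = ", "))
  series$mean_radius <- rowMeans(series[, c("q1", "q2", "q3", "q4")])
  key <- interaction(series$strain, series$temperature, series$plate_id,
                     drop = TRUE)
  out <- lapply(split(series, key), function(d) {
    if (length(unique(d$day)) < 2)
      stop("plate ", d$plate_id[1], " (", d$strain[1], ", ",
           d$temperature[1], " degC): need >= 2 distinct days")
    fit <- stats::lm(mean_radius ~ day, data = d)
    co <- stats::coef(fit)
    tss <- sum((d$mean_radius - mean(d$mean_radius))^2)
    rss <- sum(stats::residuals(fit)^2)
    data.frame(strain = d$strain[1], temperature = d$temperature[1],
               plate_id = d$plate_id[1],
               beta = unname(co["day"]), intercept = unname(co["(Intercept)"]),
               fit_r2 = if (tss > 0) 1 - rss / tss else NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$strain, res$temperature, res$plate_id), , drop = FALSE]
}

#' Fit a thermal performance curve to growth rates
#'
#' Minimises the (optionally weighted) residual sum of squares of
#' [eval_tpc()] against observed per-plate growth rates for a single strain.
#' The linear model is fitted in closed form by [stats::lm()]. Nonlinear
#' models use Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm()]) started from a fixed deterministic grid:
#' `Tmin` in `{min(T)-15, min(T)-5, min(T)}`, `Tmax` in
#' `{max(T), max(T)+5, max(T)+15}`, `Topt` over the observed temperatures,
#' and the rate scale from the maximum observed rate. Starts are ranked by
#' their initial RSS and local optimisation is run from the best
#' `n_local` starts; the best converged solution wins, so the fit is
#' deterministic given the data. Cardinal ordering (`Tmin < Topt < Tmax`) is
#' enforced by a smooth penalty on violating parameter vectors.
#'
#' @param rates data.frame with columns `temperature` and `beta` (mm/day),
#'   e.g. from [absolute_growth_rate()], for one strain.
#' @param model model name, see [tpc_models()].
#' @param weights optional numeric vector of per-observation weights
#'   (default all 1), or `"inverse_variance"` for per-temperature
#'   inverse-variance weights.
#' @param n_local number of grid starts to refine locally (default 6).
#' @return object of class `tpc_fit`: list with `model`, `params` (named
#'   list), `rss`, `n`, `k`, `aic`, `pseudo_r2`, `adj_r2`, `converged`,
#'   `temperature`, `observed`, `fitted`, `weights`.
#' @export
fit_tpc <- function(rates, model, weights = NULL, n_local = 6L) {
  model <- match.arg(model, tpc_models())
  if (!all(c("temperature", "beta") %in% names(rates)))
    stop("rates must have columns 'temperature' and 'beta'")
  tt <- as.numeric(rates$temperature)
  yy <- as.numeric(rates$beta)
  ok <- is.finite(tt) & is.finite(yy)
  tt <- tt[ok]; yy <- yy[ok]
  n <- length(yy)
  k <- tpc_n_params(model)
  if (length(unique(tt)) < k + 1)
    stop("need at least k + 1 = ", k + 1, " distinct temperatures for '",
         model, "' (got ", length(unique(tt)), ")")
  w <- resolve_weights(weights, tt, yy)

  if (model == "linear") {
    fit <- stats::lm(yy ~ tt, weights = w)
    params <- list(a = unname(stats::coef(fit)[1]),
                   b = unname(stats::coef(fit)[2]))
    fitted <- eval_tpc("linear", params, tt)
    converged <- TRUE
  } else {
    starts <- tpc_start_grid(model, tt, yy)
    rss_fun <- function(par) sum(w * tpc_penalised_resid(par, model, tt, yy)^2)
    init_rss <- vapply(starts, rss_fun, numeric(1))
    ord <- order(init_rss)
    keep <- starts[ord[seq_len(min(n_local, length(starts)))]]
    best <- NULL
    for (st in keep) {
      res <- try(minpack.lm::nls.lm(
        par = st,
        fn = function(par) sqrt(w) * tpc_penalised_resid(par, model, tt, yy),
        control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
      if (inherits(res, "try-error")) next
      cand_rss <- sum(w * tpc_penalised_resid(res$par, model, tt, yy)^2)
      if (is.null(best) || cand_rss < best$rss - 1e-12)
        best <- list(par = res$par, rss = cand_rss,
                     info = res$info)
    }
    if (is.null(best)) {
      params <- as.list(starts[[ord[1]]])
      fitted <- eval_tpc(model, params, tt)
      converged <- FALSE
    } else {
      params <- as.list(best$par)
      params <- params[tpc_param_names(model)]
      converged <- tpc_params_admissible(model, params)
      fitted <- if (converged) eval_tpc(model, params, tt) else
        pmax(rep(0, n), 0)
    }
  }
  rss <- sum(w * (yy - fitted)^2)
  r2 <- r2_measures(rss, yy, k, weights = w)
  structure(list(model = model, params = params, rss = rss, n = n, k = k,
                 aic = aic_gaussian(rss, n, k),
                 pseudo_r2 = r2[["pseudo_r2"]], adj_r2 = r2[["adj_r2"]],
                 converged = converged,
                 temperature = tt, observed = yy, fitted = fitted,
                 weights = w),
            class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat("TPC fit:", x$model,
      if (!x$converged) "(NOT converged)" else "", "\n")
  cat("  params:", paste(names(x$params),
                         signif(unlist(x$params), 5), sep = " = ",
                         collapse = ", "), "\n")
  cat(sprintf("  n = %d, RSS = %.5g, AIC = %.4f, pseudo-R2 = %.4f, adj-R2 = %.4f\n",
              x$n, x$rss, x$aic, x$pseudo_r2, x$adj_r2))
  invisible(x)
}

resolve_weights <- function(weights, tt, yy) {
  n <- length(yy)
  if (is.null(weights)) return(rep(1, n))
  if (identical(weights, "inverse_variance")) {
    v <- tapply(yy, tt, stats::var)
    v[!is.finite(v) | v <= 0] <- min(v[is.finite(v) & v > 0], 1)
    return(as.numeric(1 / v[as.character(tt)]))
  }
  if (!is.numeric(weights) || length(weights) != n || any(weights < 0))
    stop("weights must be NULL, 'inverse_variance', or a nonnegative ",
         "numeric vector matching the observations")
  weights
}

tpc_params_admissible <- function(model, p) {
  switch(model,
    ctmi = isTRUE(p$Tmin < p$Topt && p$Topt < p$Tmax && p$mu_opt > 0),
    lactin1 = isTRUE(p$Tmin < p$Tmax && p$a > 0),
    TRUE)
}

# residuals with a smooth ordering penalty so the optimiser is repelled from
# inadmissible parameter regions but the objective stays continuous
tpc_penalised_resid <- function(par, model, tt, yy) {
  p <- as.list(par)
  pen <- 0
  if (model == "ctmi") {
    gap1 <- p$Topt - p$Tmin; gap2 <- p$Tmax - p$Topt
    if (gap1 < 1 || gap2 < 1 || p$mu_opt <= 0)
      pen <- pen + max(0, 1 - gap1)^2 + max(0, 1 - gap2)^2 +
        max(0, -p$mu_opt)^2
    if (gap1 <= 0.01 || gap2 <= 0.01)
      return(rep(100 + 10 * pen, length(yy)))
  }
  if (model == "lactin1" && p$Tmin >= p$Tmax - 0.01)
    return(rep(100 + 10 * (p$Tmin - p$Tmax)^2, length(yy)))
  mu <- tryCatch(eval_tpc(model, p, tt),
                 error = function(e) NULL)  # degenerate denominator etc.
  if (is.null(mu) || any(!is.finite(mu)))
    return(rep(100, length(yy)))
  (yy - mu) + pen / length(yy)
}

tpc_start_grid <- function(model, tt, yy) {
  tmin_c <- min(tt) + c(-15, -5, 0)
  tmax_c <- max(tt) + c(0, 5, 15)
  mu_max <- max(yy, 0.1)
  temps <- sort(unique(tt))
  starts <- list()
  if (model == "ctmi") {
    for (tn in tmin_c) for (tx in tmax_c) for (to in temps)
      if (tn < to && to < tx)
        starts[[length(starts) + 1]] <-
          c(mu_opt = mu_max, Tmin = tn, Topt = to, Tmax = tx)
  } else if (model == "lactin1") {
    for (tn in tmin_c) for (tx in tmax_c) {
      tstar <- (2 * tx + tn) / 3  # analytic peak of a(T-Tmin)^2(Tmax-T)
      a0 <- mu_max / ((tstar - tn)^2 * (tx - tstar))
      starts[[length(starts) + 1]] <- c(a = a0, Tmin = tn, Tmax = tx)
    }
  } else if (model == "lactin1_classic") {
    for (tx in tmax_c) for (rho in c(0.01, 0.05, 0.1))
      starts[[length(starts) + 1]] <- c(rho = rho, Tmax = tx, delta = 5)
  }
  starts
}

#' Gaussian residual-sum-of-squares AIC
#'
#' AIC under a Gaussian likelihood with the error variance counted as a
#' parameter: \eqn{AIC = n \ln(RSS/n) + 2 (k + 1)}.
#'
#' @param rss residual sum of squares, or a `tpc_fit` object.
#' @param n number of observations (ignored when `rss` is a fit).
#' @param k number of fitted model parameters (ignored when `rss` is a fit).
#' @return numeric AIC (`-Inf` for an exactly zero RSS).
#' @export
aic_gaussian <- function(rss, n, k) {
  if (inherits(rss, "tpc_fit")) {
    n <- rss$n; k <- rss$k; rss <- rss$rss
  }
  stopifnot(n > k + 1, rss >= 0)
  n * log(rss / n) + 2 * (k + 1)
}

#' Pseudo and adjusted R-squared of a fit
#'
#' `pseudo_r2 = 1 - RSS/TSS` with the total sum of squares about the
#' (weighted) mean; `adj_r2 = 1 - (1 - pseudo_r2) (n - 1) / (n - k - 1)`.
#'
#' @param rss residual sum of squares, or a `tpc_fit` object (then `observed`
#'   and `k` are taken from the fit).
#' @param observed numeric vector of observed responses.
#' @param k number of fitted parameters.
#' @param weights optional observation weights (default 1).
#' @return named numeric vector `c(pseudo_r2 = , adj_r2 = )`.
#' @export
r2_measures <- function(rss, observed, k, weights = NULL) {
  if (inherits(rss, "tpc_fit")) {
    observed <- rss$observed; k <- rss$k; weights <- rss$weights
    rss <- rss$rss
  }
  n <- length(observed)
  if (n < 2) stop("need >= 2 observations")
  if (is.null(weights)) weights <- rep(1, n)
  mbar <- sum(weights * observed) / sum(weights)
  tss <- sum(weights * (observed - mbar)^2)
  if (tss <= 0) stop("observed responses have zero variance")
  pseudo <- 1 - rss / tss
  adj <- 1 - (1 - pseudo) * (n - 1) / (n - k - 1)
  c(pseudo_r2 = pseudo, adj_r2 = adj)
}

#' Vuong non-nested model comparison
#'
#' Compares two thermal-model fits on the same observations through the
#' per-observation Gaussian log-likelihood differences
#' \eqn{m_i = \ell_i^A - \ell_i^B} (each model's error variance is its
#' \eqn{RSS/n}). The statistic is \eqn{z = \sum m_i / (\sqrt{n}\, sd(m_i))},
#' with a two-sided normal p-value; positive z favours model A.
#'
#' @param fitA,fitB `tpc_fit` objects on identical observations.
#' @param alpha significance level for the verdict (default 0.05).
#' @return list of class `vuong_result`: `z`, `p`, `n`, `verdict` (one of
#'   `"A_preferred"`, `"B_preferred"`, `"indistinguishable"`).
#' @export
vuong_test <- function(fitA, fitB, alpha = 0.05) {
  stopifnot(inherits(fitA, "tpc_fit"), inherits(fitB, "tpc_fit"))
  if (fitA$n != fitB$n ||
      !isTRUE(all.equal(fitA$temperature, fitB$temperature)) ||
      !isTRUE(all.equal(fitA$observed, fitB$observed)))
    stop("fits must be on the same observations")
  n <- fitA$n
  llA <- gaussian_ll_obs(fitA)
  llB <- gaussian_ll_obs(fitB)
  m <- llA - llB
  s <- stats::sd(m)
  if (!is.finite(s) || s < 1e-12) {
    z <- 0; p <- 1
  } else {
    z <- sum(m) / (sqrt(n) * s)
    p <- 2 * stats::pnorm(-abs(z))
  }
  verdict <- if (p >= alpha) "indistinguishable" else
    if (z > 0) "A_preferred" else "B_preferred"
  structure(list(z = z, p = p, n = n, verdict = verdict),
            class = "vuong_result")
}

gaussian_ll_obs <- function(fit) {
  sigma2 <- max(fit$rss / fit$n, 1e-300)
  resid <- fit$observed - fit$fitted
  -0.5 * log(2 * pi * sigma2) - resid^2 / (2 * sigma2)
}

#' @export
print.vuong_result <- function(x, ...) {
  cat(sprintf("Vuong non-nested test: z = %.4f, p = %.4g, n = %d -> %s\n",
              x$z, x$p, x$n, x$verdict))
  invisible(x)
}

#' Rank competing TPC fits and pick the best
#'
#' Models are ranked by ascending AIC. Any model within 2 AIC units of the
#' minimum is considered tied; ties are broken by the highest adjusted
#' R-squared, and models still tied after that are flagged for a Vuong test.
#'
#' @param fits list of `tpc_fit` objects for one strain.
#' @return list with `ranking` (data.frame: model, aic, adj_r2, rss,
#'   converged, in order), `best` (the winning `tpc_fit`), `best_model`
#'   (name) and `vuong_candidates` (character vector of models tied after
#'   both criteria; empty if decided).
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "tpc_fit")))
  ranking <- data.frame(
    model = vapply(fits, `[[`, character(1), "model"),
    aic = vapply(fits, `[[`, numeric(1), "aic"),
    adj_r2 = vapply(fits, `[[`, numeric(1), "adj_r2"),
    rss = vapply(fits, `[[`, numeric(1), "rss"),
    converged = vapply(fits, `[[`, logical(1), "converged"),
    stringsAsFactors = FALSE)
  ord <- order(ranking$aic)
  ranking <- ranking[ord, , drop = FALSE]
  fits <- fits[ord]
  rownames(ranking) <- NULL
  tied <- which(ranking$aic - ranking$aic[1] < 2)
  if (length(tied) > 1) {
    best_i <- tied[which.max(ranking$adj_r2[tied])]
    still <- tied[abs(ranking$adj_r2[tied] - ranking$adj_r2[best_i]) < 1e-12]
    vuong_candidates <- if (length(still) > 1) ranking$model[still]
      else character(0)
  } else {
    best_i <- 1L
    vuong_candidates <- character(0)
  }
  list(ranking = ranking, best = fits[[best_i]],
       best_model = ranking$model[best_i],
       vuong_candidates = vuong_candidates)
}

#' Summarise cardinal temperatures across strains
#'
#' Collects per-strain cardinal temperature estimates and reports the overall
#' thermal range (minimum `Tmin` to maximum `Tmax`) and the range of optimum
#' temperatures across strains.
#'
#' @param per_strain named list mapping strain to either a `tpc_fit` (CTMI)
#'   or a named list/vector with `Tmin`, `Topt`, `Tmax` and optionally
#'   `mu_opt`.
#' @return list of class `cardinal_summary`: `per_strain` data.frame
#'   (strain, Tmin, Topt, Tmax, mu_opt), `overall_tmin`, `overall_tmax`,
#'   `topt_range` (length-2 numeric `c(min, max)`).
#' @export
cardinal_summary <- function(per_strain) {
  stopifnot(length(per_strain) >= 1, !is.null(names(per_strain)))
  rows <- lapply(names(per_strain), function(s) {
    x <- per_strain[[s]]
    p <- if (inherits(x, "tpc_fit")) {
      if (x$model != "ctmi")
        stop("strain '", s, "': cardinal temperatures need a ctmi fit")
      x$params
    } else as.list(x)
    if (!all(c("Tmin", "Topt", "Tmax") %in% names(p)))
      stop("strain '", s, "': need Tmin, Topt, Tmax")
    data.frame(strain = s, Tmin = p$Tmin, Topt = p$Topt, Tmax = p$Tmax,
               mu_opt = if (!is.null(p$mu_opt)) p$mu_opt else NA_real_,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  structure(list(per_strain = df,
                 overall_tmin = min(df$Tmin),
                 overall_tmax = max(df$Tmax),
                 topt_range = c(min(df$Topt), max(df$Topt))),
            class = "cardinal_summary")
}

#' @export
print.cardinal_summary <- function(x, ...) {
  print(x$per_strain)
  cat(sprintf("overall thermal range: %.1f - %.1f degC; Topt range: %.1f - %.1f degC\n",
              x$overall_tmin, x$overall_tmax, x$topt_range[1], x$topt_range[2]))
  invisible(x)
}
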