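#' One-way analysis of variance
#'
#' Classical between/within decomposition across two or more groups.
#'
#' @param groups named list of numeric vectors (>= 2 groups, >= 2 values
#'   each).
#' @return list of class `anova_result`: `f`, `df_between`, `df_within`,
#'   `p`, plus the underlying `aov` fit.
#' @export
oneway_anova <- function(groups) {
  check_groups(groups)
  d <- groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = d)
  s <- summary(fit)[[1]]
  structure(list(f = s[["F value"]][1], df_between = s[["Df"]][1],
                 df_within = s[["Df"]][2], p = s[["Pr(>F)"]][1],
                 aov = fit),
            class = "anova_result")
}

#' Tukey HSD pairwise comparisons
#'
#' All pairwise group comparisons with studentized-range adjusted p-values
#' (via [stats::TukeyHSD()]; the studentized-range tail probabilities are
#' computed by numerical integration in `ptukey`).
#'
#' @param groups named list of numeric vectors.
#' @param alpha family-wise significance level (default 0.05).
#' @return list of class `tukey_result`: `pairs` data.frame (`group_a`,
#'   `group_b`, `mean_diff`, `q_stat`, `p_adj`, `significant`), `alpha`,
#'   `group_order` (input order, used for letter assignment).
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  check_groups(groups)
  if (any(grepl("-", names(groups), fixed = TRUE)))
    stop("group names must not contain '-'")
  d <- groups_to_df(groups)
  fit <- stats::aov(value ~ group, data = d)
  th <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  nm <- strsplit(rownames(th), "-", fixed = TRUE)
  mse <- sum(stats::residuals(fit)^2) / fit$df.residual
  ns <- vapply(groups, length, integer(1))
  pairs <- do.call(rbind, lapply(seq_along(nm), function(i) {
    ga <- nm[[i]][1]; gb <- nm[[i]][2]
    se_q <- sqrt(mse / 2 * (1 / ns[[ga]] + 1 / ns[[gb]]))
    data.frame(group_a = ga, group_b = gb, mean_diff = th[i, "diff"],
               q_stat = abs(th[i, "diff"]) / se_q,
               p_adj = th[i, "p adj"],
               significant = th[i, "p adj"] < alpha,
               stringsAsFactors = FALSE)
  }))
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, alpha = alpha, group_order = names(groups)),
            class = "tukey_result")
}

#' Compact letter display from pairwise comparisons
#'
#' Assigns letters so that two groups share at least one letter exactly when
#' their pairwise comparison is non-significant at `alpha` (the defining
#' invariant), using the insert-and-absorb algorithm. Letters are assigned
#' in the input group order, so the output is deterministic.
#'
#' @param tukey a `tukey_result` from [tukey_hsd()], or a data.frame with
#'   columns `group_a`, `group_b`, `p_adj`.
#' @param alpha significance level (defaults to the `tukey_result`'s own,
#'   else 0.05).
#' @param group_order optional character vector fixing the group order.
#' @return named character vector: group -> letter string.
#' @export
compact_letters <- function(tukey, alpha = NULL, group_order = NULL) {
  if (inherits(tukey, "tukey_result")) {
    if (is.null(alpha)) alpha <- tukey$alpha
    if (is.null(group_order)) group_order <- tukey$group_order
    pairs <- tukey$pairs
  } else {
    pairs <- tukey
    if (is.null(alpha)) alpha <- 0.05
  }
  stopifnot(all(c("group_a", "group_b", "p_adj") %in% names(pairs)))
  groups <- if (!is.null(group_order)) group_order else
    unique(c(pairs$group_a, pairs$group_b))
  # insert-and-absorb: start from one set holding everything, split on each
  # significant pair, drop sets that become subsets of another
  sets <- list(groups)
  sig <- pairs[pairs$p_adj < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$group_a[i]; b <- sig$group_b[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else new_sets <- c(new_sets, list(s))
    }
    new_sets <- new_sets[lengths(new_sets) > 0]
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) for (k in seq_along(new_sets)) {
      if (j != k && all(new_sets[[j]] %in% new_sets[[k]]) &&
          (length(new_sets[[j]]) < length(new_sets[[k]]) ||
           (length(new_sets[[j]]) == length(new_sets[[k]]) && j > k)))
        keep[j] <- FALSE
    }
    sets <- new_sets[keep]
  }
  # order sets by first member's position for stable letter assignment
  first_pos <- vapply(sets, function(s) min(match(s, groups)), numeric(1))
  sets <- sets[order(first_pos)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", length(groups)), groups)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters_pool[i])
  out
}

#' Generalized linear model fit (binomial / Poisson)
#'
#' Wrapper over [stats::glm()] (iteratively reweighted least squares) for
#' the families used across the pipeline, returning the coefficient
#' covariance from the final weighted information matrix.
#'
#' @param y response: counts (Poisson) or successes (binomial).
#' @param x predictor data.frame/matrix (or `NULL` for intercept-only).
#' @param denominators binomial trial counts (required for binomial
#'   families).
#' @param family `"binomial-logit"`, `"binomial-probit"` or `"poisson-log"`.
#' @return list of class `glm_result`: `coefficients`, `covariance`,
#'   `deviance`, `converged`, `family`, `fit` (the `glm` object).
#' @export
glm_fit <- function(y, x = NULL,
                    denominators = NULL,
                    family = c("binomial-logit", "binomial-probit",
                               "poisson-log")) {
  family <- match.arg(family)
  fam <- switch(family,
    "binomial-logit" = stats::binomial("logit"),
    "binomial-probit" = stats::binomial("probit"),
    "poisson-log" = stats::poisson("log"))
  d <- if (is.null(x)) data.frame(row.names = seq_along(y)) else
    as.data.frame(x)
  if (startsWith(family, "binomial")) {
    if (is.null(denominators))
      stop("binomial families need 'denominators'")
    if (any(y < 0 | y > denominators))
      stop("successes must lie in [0, denominators]")
    d$.resp <- NULL
    form <- if (ncol(d) > 0)
      stats::as.formula(paste("cbind(y, denominators - y) ~",
                              paste(names(d), collapse = " + ")))
      else stats::as.formula("cbind(y, denominators - y) ~ 1")
    dd <- cbind(d, y = y, denominators = denominators)
  } else {
    if (any(y < 0)) stop("Poisson counts must be >= 0")
    form <- if (ncol(d) > 0)
      stats::as.formula(paste("y ~", paste(names(d), collapse = " + ")))
      else stats::as.formula("y ~ 1")
    dd <- cbind(d, y = y)
  }
  fit <- suppressWarnings(stats::glm(form, family = fam, data = dd,
                                     control = stats::glm.control(
                                       epsilon = 1e-8, maxit = 100)))
  conv <- isTRUE(fit$converged) && !isTRUE(fit$boundary)
  structure(list(coefficients = stats::coef(fit),
                 covariance = stats::vcov(fit),
                 deviance = stats::deviance(fit),
                 converged = conv, family = family, fit = fit),
            class = "glm_result")
}

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 || is.null(names(groups)))
    stop("groups must be a named list with >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("each group needs >= 2 values")
  all_v <- unlist(groups)
  if (stats::var(all_v) <= 0) stop("all values identical: no variance")
  invisible(TRUE)
}

groups_to_df <- function(groups) {
  data.frame(value = unlist(groups, use.names = FALSE),
             group = factor(rep(names(groups),
                                vapply(groups, length, integer(1))),
                            levels = names(groups)))
}
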