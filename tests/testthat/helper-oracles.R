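# Independent oracle implementations used to cross-check the package's
# fitting routines on tiny instances. These deliberately use brute force or
# closed forms, never the code paths they validate.

# grouped-binomial logistic log-likelihood on a (b0, b1) grid, iteratively
# refined around the maximum; returns the ML (b0, b1) and LT50 = -b0/b1
grid_ml_logistic <- function(day, dead, n, rounds = 7) {
  b0r <- c(-20, 5); b1r <- c(1e-3, 3)
  ll_fun <- function(b0, b1) {
    p <- pmin(pmax(plogis(b0 + b1 * day), 1e-12), 1 - 1e-12)
    sum(dead * log(p) + (n - dead) * log(1 - p))
  }
  for (r in seq_len(rounds)) {
    b0s <- seq(b0r[1], b0r[2], length.out = 61)
    b1s <- seq(b1r[1], b1r[2], length.out = 61)
    ll <- outer(b0s, b1s, Vectorize(ll_fun))
    ij <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    b0 <- b0s[ij[1]]; b1 <- b1s[ij[2]]
    w0 <- diff(b0r) / 60; w1 <- diff(b1r) / 60
    b0r <- b0 + c(-2, 2) * w0
    b1r <- b1 + c(-2, 2) * w1
  }
  c(b0 = b0, b1 = b1, lt50 = -b0 / b1)
}

# hand product-limit estimator (no ties handling shortcuts)
km_hand <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ts, surv = NA_real_)
  for (i in seq_along(ts)) {
    n_risk <- sum(time >= ts[i])
    d <- sum(time == ts[i] & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[i] <- s
  }
  out
}

# hand two-group log-rank chi-squared with hypergeometric variance
logrank_hand <- function(time, event, group) {
  g <- sort(unique(group))
  stopifnot(length(g) == 2)
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk); n1 <- sum(at_risk & group == g[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == g[1])
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O1 - E1)^2 / V
}

# closed-form simple OLS via sum formulas
ols_hand <- function(x, y) {
  n <- length(x)
  beta <- (n * sum(x * y) - sum(x) * sum(y)) / (n * sum(x^2) - sum(x)^2)
  alpha <- mean(y) - beta * mean(x)
  c(intercept = alpha, slope = beta)
}

# defining invariant of a compact letter display: two groups share a letter
# exactly when their pairwise comparison is non-significant
cld_invariant_holds <- function(letters_map, pairs, alpha) {
  for (i in seq_len(nrow(pairs))) {
    a <- pairs$group_a[i]; b <- pairs$group_b[i]
    shared <- length(intersect(strsplit(letters_map[[a]], "")[[1]],
                               strsplit(letters_map[[b]], "")[[1]])) > 0
    nonsig <- pairs$p_adj[i] >= alpha
    if (shared != nonsig) return(FALSE)
  }
  TRUE
}

# per-observation Gaussian log-likelihood difference summed into the Vuong z,
# computed directly with dnorm
vuong_hand <- function(obs, fittedA, rssA, fittedB, rssB) {
  n <- length(obs)
  llA <- dnorm(obs, fittedA, sqrt(rssA / n), log = TRUE)
  llB <- dnorm(obs, fittedB, sqrt(rssB / n), log = TRUE)
  m <- llA - llB
  sum(m) / (sqrt(n) * sd(m))
}
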