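#' Temperature-dependent growth rate models
#'
#' Evaluate a thermal performance curve (TPC) at one or more temperatures.
#' Three model families describe the absolute radial growth rate (mm/day) of a
#' fungal colony as a function of incubation temperature:
#'
#' * `"linear"`: \eqn{\mu(T) = a + b T}, defined everywhere.
#' * `"lactin1"`: \eqn{\mu(T) = a (T - T_{min})^2 (T_{max} - T)} for
#'   \eqn{T_{min} \le T \le T_{max}}, 0 outside. This is the printed
#'   polynomial form with parameters `a` (empirical constant), `Tmin`, `Tmax`.
#' * `"lactin1_classic"`: the classical Lactin-1 exponential form
#'   \eqn{\mu(T) = e^{\rho T} - e^{\rho T_{max} - (T_{max} - T)/\Delta}},
#'   parameters `rho`, `Tmax`, `delta`; provided as a clearly named
#'   alternative, never the default.
#' * `"ctmi"`: the cardinal temperature model with inflection,
#'   \deqn{\mu(T) = \mu_{opt} \frac{(T - T_{max})(T - T_{min})^2}
#'   {(T_{opt} - T_{min})\left[(T_{opt} - T_{min})(T - T_{opt}) -
#'    (T_{opt} - T_{max})(T_{opt} + T_{min} - 2T)\right]}}
#'   for \eqn{T_{min} \le T \le T_{max}}, 0 outside, with parameters
#'   `mu_opt`, `Tmin`, `Topt`, `Tmax` (the cardinal temperatures).
#'   Algebraically \eqn{\mu(T_{opt}) = \mu_{opt}} and
#'   \eqn{\mu(T_{min}) = \mu(T_{max}) = 0}. The curve is well behaved on the
#'   whole thermal range when \eqn{T_{opt} \ge (T_{min} + T_{max})/2};
#'   below that the (linear-in-T) denominator has a root inside
#'   \eqn{(T_{min}, T_{opt})}, which is reported as a degeneracy error when
#'   an evaluation lands on it.
#'
#' Rates are floored at zero for the nonlinear models: negative values cannot
#' arise inside the cardinal range for admissible parameters, but the clamp
#' makes the fitted response well defined at every temperature the optimiser
#' may probe.
#'
#' @param model one of `"linear"`, `"lactin1"`, `"lactin1_classic"`, `"ctmi"`.
#' @param params named list or numeric vector of model parameters (see above).
#' @param temp numeric vector of temperatures (degrees C).
#' @return numeric vector of growth rates (mm/day), same length as `temp`.
#' @examples
#' eval_tpc("ctmi", list(mu_opt = 2, Tmin = 10, Topt = 27, Tmax = 40), 27)
#' eval_tpc("lactin1", list(a = 1e-4, Tmin = 5, Tmax = 40), 25)
#' @export
eval_tpc <- function(model, params, temp) {
  model <- match.arg(model, tpc_models())
  p <- as.list(params)
  stopifnot(is.numeric(temp))
  switch(model,
    linear = {
      need_params(p, c("a", "b"), model)
      p$a + p$b * temp
    },
    lactin1 = {
      need_params(p, c("a", "Tmin", "Tmax"), model)
      if (p$Tmin >= p$Tmax)
        stop("lactin1 requires Tmin < Tmax (got Tmin = ", p$Tmin,
             ", Tmax = ", p$Tmax, ")")
      mu <- p$a * (temp - p$Tmin)^2 * (p$Tmax - temp)
      mu[temp < p$Tmin | temp > p$Tmax] <- 0
      pmax(mu, 0)
    },
    lactin1_classic = {
      need_params(p, c("rho", "Tmax", "delta"), model)
      mu <- exp(p$rho * temp) - exp(p$rho * p$Tmax - (p$Tmax - temp) / p$delta)
      pmax(mu, 0)
    },
    ctmi = {
      need_params(p, c("mu_opt", "Tmin", "Topt", "Tmax"), model)
      if (!(p$Tmin < p$Topt && p$Topt < p$Tmax))
        stop("ctmi requires Tmin < Topt < Tmax (got ", p$Tmin, ", ",
             p$Topt, ", ", p$Tmax, ")")
      denom <- (p$Topt - p$Tmin) *
        ((p$Topt - p$Tmin) * (temp - p$Topt) -
         (p$Topt - p$Tmax) * (p$Topt + p$Tmin - 2 * temp))
      inside <- temp >= p$Tmin & temp <= p$Tmax
      if (any(inside & abs(denom) < 1e-12))
        stop("ctmi denominator degenerate (|denom| < 1e-12) at T = ",
             paste(temp[inside & abs(denom) < 1e-12], collapse = ", "))
      mu <- numeric(length(temp))
      mu[inside] <- p$mu_opt * (temp[inside] - p$Tmax) *
        (temp[inside] - p$Tmin)^2 / denom[inside]
      pmax(mu, 0)
    })
}

#' Supported thermal performance curve model names
#' @return character vector of model identifiers accepted by [eval_tpc()].
#' @export
tpc_models <- function() c("linear", "lactin1", "lactin1_classic", "ctmi")

#' Number of fitted parameters of a TPC model
#' @param model model name, see [tpc_models()].
#' @return integer parameter count k.
#' @export
tpc_n_params <- function(model) {
  model <- match.arg(model, tpc_models())
  c(linear = 2L, lactin1 = 3L, lactin1_classic = 3L, ctmi = 4L)[[model]]
}

tpc_param_names <- function(model) {
  switch(match.arg(model, tpc_models()),
    linear = c("a", "b"),
    lactin1 = c("a", "Tmin", "Tmax"),
    lactin1_classic = c("rho", "Tmax", "delta"),
    ctmi = c("mu_opt", "Tmin", "Topt", "Tmax"))
}

need_params <- function(p, names, model) {
  missing <- setdiff(names, names(p))
  if (length(missing))
    stop("model '", model, "' needs parameter(s): ",
         paste(missing, collapse = ", "))
  bad <- names[!vapply(p[names], function(x)
    is.numeric(x) && length(x) == 1 && is.finite(x), logical(1))]
  if (length(bad))
    stop("model '", model, "' parameter(s) not finite scalars: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
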