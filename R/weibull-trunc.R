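#' @keywords internal
check_weibull_params <- function(scale, shape) {
  if (!is.numeric(scale) || !is.numeric(shape) ||
      any(!is.finite(scale)) || any(!is.finite(shape)) ||
      any(scale <= 0) || any(shape <= 0)) {
    stop("`scale` and `shape` must be finite and positive", call. = FALSE)
  }
  invisible(TRUE)
}

#' @keywords internal
check_truncation <- function(lower, scale, shape) {
  if (any(!is.finite(lower)) || any(lower < 0)) {
    stop("truncation point `lower` must be finite and non-negative",
         call. = FALSE)
  }
  # survival past the truncation point; if essentially no mass remains the
  # truncated distribution is degenerate and quantiles blow up
  surv <- exp(-(lower / scale)^shape)
  if (any(surv < 1e-12)) {
    stop("degenerate truncation: survival past `lower` is below 1e-12",
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Weibull parameter pair
#'
#' A validated (scale, shape) pair for a Weibull transition-time
#' distribution.  Throughout the package time is measured in years since
#' the age-45 origin of the cohort, so `scale` is in years and `shape` is
#' dimensionless.
#'
#' @param scale Positive scale parameter (years).
#' @param shape Positive shape parameter.
#' @return An object of class `weibull_params`.
#' @examples
#' weibull_params(65, 2)   # disease onset hazard rising with age
#' @export
weibull_params <- function(scale, shape) {
  check_weibull_params(scale, shape)
  structure(list(scale = as.numeric(scale), shape = as.numeric(shape)),
            class = "weibull_params")
}

#' @export
print.weibull_params <- function(x, ...) {
  cat(sprintf("Weibull(scale = %g, shape = %g)\n", x$scale, x$shape))
  invisible(x)
}

#' Transition parameter set for the irreversible illness-death model
#'
#' Bundles the Weibull parameters of the two transitions out of the
#' "healthy" state: onset of disease (1 -> 2) and death without disease
#' (1 -> 3).  The 2 -> 3 transition is not parameterised because it affects
#' neither incident-case counting nor the analysis likelihood.
#'
#' @param healthy_to_diseased,healthy_to_dead [weibull_params()] objects.
#' @return An object of class `transition_set`.
#' @export
transition_set <- function(healthy_to_diseased, healthy_to_dead) {
  stopifnot(inherits(healthy_to_diseased, "weibull_params"),
            inherits(healthy_to_dead, "weibull_params"))
  structure(list(healthy_to_diseased = healthy_to_diseased,
                 healthy_to_dead = healthy_to_dead),
            class = "transition_set")
}

#' Left-truncated Weibull distribution
#'
#' Density, distribution function, quantile function and hazard for a
#' Weibull random variable left-truncated at `lower`: the conditional
#' distribution of `W | W > lower` for `W ~ Weibull(shape, scale)`.  With
#' `lower = 0` these reduce to the ordinary Weibull functions.  Left
#' truncation models delayed entry: a participant recruited `lower` years
#' after the age-45 time origin is only observed conditional on still being
#' event-free at entry.
#'
#' The quantile function uses the conditional-survival inversion
#' \deqn{t = \lambda \left( (l/\lambda)^{\rho} - \log(1-u) \right)^{1/\rho},}
#' which is the exact inverse of the truncated distribution function and is
#' the standard device for simulating event times under delayed entry.
#'
#' The hazard is truncation-invariant: conditioning on survival past
#' `lower` does not change the hazard at times beyond it, so `hweibull()`
#' takes no truncation argument.
#'
#' @param x,q Vector of times (years since the age-45 origin), `>= 0`.
#' @param p Vector of probabilities in `[0, 1)`.
#' @param scale,shape Weibull parameters, both positive.
#' @param lower Left-truncation point (years), `>= 0`.  An error is thrown
#'   if virtually no probability mass (survival below 1e-12) lies beyond it.
#' @return `dltweibull` the density, `pltweibull` the distribution
#'   function, `qltweibull` the quantile (always `>= lower`), `hweibull`
#'   the hazard.
#' @examples
#' qltweibull(0.5, scale = 65, shape = 2)          # marginal median, 54.1y
#' qltweibull(0.5, scale = 65, shape = 2, lower = 20)  # conditional on entry
#' hweibull(65, scale = 65, shape = 2)             # shape/scale at t = scale
#' @name ltweibull
NULL

#' @rdname ltweibull
#' @export
dltweibull <- function(x, scale, shape, lower = 0) {
  check_weibull_params(scale, shape)
  check_truncation(lower, scale, shape)
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  out <- stats::dweibull(x, shape = shape, scale = scale) /
    exp(-(lower / scale)^shape)
  out[x < lower] <- 0
  out
}

#' @rdname ltweibull
#' @export
pltweibull <- function(q, scale, shape, lower = 0) {
  check_weibull_params(scale, shape)
  check_truncation(lower, scale, shape)
  if (any(q < 0)) stop("`q` must be non-negative", call. = FALSE)
  # 1 - S(q)/S(l) computed through the cumulative hazard for stability
  out <- -expm1(-((q / scale)^shape - (lower / scale)^shape))
  out[q < lower] <- 0
  out
}

#' @rdname ltweibull
#' @export
qltweibull <- function(p, scale, shape, lower = 0) {
  check_weibull_params(scale, shape)
  check_truncation(lower, scale, shape)
  if (any(!is.finite(p)) || any(p < 0) || any(p >= 1)) {
    stop("`p` must lie in [0, 1)", call. = FALSE)
  }
  scale * ((lower / scale)^shape - log1p(-p))^(1 / shape)
}

#' @rdname ltweibull
#' @export
hweibull <- function(x, scale, shape) {
  check_weibull_params(scale, shape)
  if (any(x < 0)) stop("`x` must be non-negative", call. = FALSE)
  if (any(x == 0) && any(shape < 1)) {
    stop("hazard diverges at 0 for shape < 1", call. = FALSE)
  }
  (shape / scale) * (x / scale)^(shape - 1)
}

#' Cumulative Weibull transition hazard over an interval
#'
#' Integrated hazard of a Weibull transition over `(t1, t2]`, i.e.
#' `(t2/scale)^shape - (t1/scale)^shape`.  Additive over adjacent
#' intervals.
#'
#' @param t1,t2 Interval endpoints in years, `0 <= t1 <= t2` elementwise.
#' @inheritParams ltweibull
#' @return Non-negative cumulative hazard.
#' @export
weibull_cumhaz <- function(t1, t2, scale, shape) {
  check_weibull_params(scale, shape)
  if (any(t1 < 0) || any(t2 < t1)) {
    stop("need 0 <= t1 <= t2", call. = FALSE)
  }
  (t2 / scale)^shape - (t1 / scale)^shape
}

#' State-occupancy probabilities of the irreversible illness-death model
#'
#' Probabilities that a subject healthy at `t1` is still healthy, has
#' become diseased, or has died without disease by `t2`, given Weibull
#' cause-specific hazards for the 1 -> 2 and 1 -> 3 transitions.  Staying
#' healthy is
#' `p11 = exp(-Q12 - Q13)`; the diseased-by-`t2` probability is the
#' integral over the onset time `t` of `p11(t1, t) q12(t) p22(t, t2)`,
#' evaluated by adaptive quadrature.  When no 2 -> 3 hazard is supplied the
#' diseased state is treated as absorbing for counting purposes
#' (`p22 = 1`), so `p12` is the cumulative cause-specific incidence.
#'
#' @param t1,t2 Scalar interval endpoints, `0 <= t1 <= t2`.
#' @param transitions A [transition_set()].
#' @param hr12 Positive multiplier on the 1 -> 2 hazard (e.g. a subject's
#'   exposure hazard ratio); `0` is allowed and forces `p12 = 0`.
#' @param diseased_to_dead Optional [weibull_params()] for the 2 -> 3
#'   transition, used only inside `p22` when occupancy of the diseased
#'   state at `t2` (rather than ever-diseased) is wanted.
#' @param abs.tol Absolute quadrature tolerance.
#' @return Named numeric vector `c(p11, p12, p13)` summing to 1 within
#'   quadrature tolerance.
#' @examples
#' tr <- transition_set(weibull_params(65, 2), weibull_params(42, 4.3))
#' occupancy_probs(0, 21, tr)
#' @export
occupancy_probs <- function(t1, t2, transitions, hr12 = 1,
                            diseased_to_dead = NULL, abs.tol = 1e-8) {
  stopifnot(inherits(transitions, "transition_set"),
            length(t1) == 1, length(t2) == 1)
  if (t1 < 0 || t2 < t1) stop("need 0 <= t1 <= t2", call. = FALSE)
  if (!is.finite(hr12) || hr12 < 0) stop("`hr12` must be >= 0", call. = FALSE)
  dis <- transitions$healthy_to_diseased
  dth <- transitions$healthy_to_dead
  if (t2 == t1) {
    return(c(p11 = 1, p12 = 0, p13 = 0))
  }
  p11_fun <- function(t) {
    exp(-hr12 * weibull_cumhaz(t1, t, dis$scale, dis$shape) -
          weibull_cumhaz(t1, t, dth$scale, dth$shape))
  }
  p22_fun <- if (is.null(diseased_to_dead)) {
    function(t) rep(1, length(t))
  } else {
    function(t) exp(-weibull_cumhaz(t, t2, diseased_to_dead$scale,
                                    diseased_to_dead$shape))
  }
  p11 <- p11_fun(t2)
  p12 <- if (hr12 == 0) 0 else {
    integrand <- function(t) {
      p11_fun(t) * hr12 * hweibull(t, dis$scale, dis$shape) * p22_fun(t)
    }
    quad <- tryCatch(
      stats::integrate(integrand, t1, t2, abs.tol = abs.tol,
                       rel.tol = abs.tol, subdivisions = 500L),
      error = function(e) {
        stop("quadrature for p12 failed on (", t1, ", ", t2, "): ",
             conditionMessage(e), call. = FALSE)
      })
    quad$value
  }
  c(p11 = p11, p12 = p12, p13 = 1 - p11 - p12)
}
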