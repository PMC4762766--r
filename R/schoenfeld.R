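# Conventional closed-form comparator: Schoenfeld's (1983) sample-size
# formula for a binary covariate in a proportional-hazards model.

#' Schoenfeld required number of events
#'
#' Events needed to detect a hazard ratio `hr` for a binary covariate with
#' prevalence `p` at two-sided level `alpha` and the given power:
#' \deqn{d = \frac{(z_{1-\alpha/2} + z_{power})^2}{p(1-p)\,(\log hr)^2}.}
#' Symmetric in `hr` vs `1/hr`.
#'
#' @param hr Hazard ratio, `!= 1`.
#' @param p Covariate prevalence in `(0, 1)`.
#' @param alpha Two-sided significance level.
#' @param power Required power.
#' @return Required event count (real, not rounded).
#' @examples
#' schoenfeld_required_events(2, p = 0.5)  # 65.35
#' @export
schoenfeld_required_events <- function(hr, p, alpha = 0.05, power = 0.8) {
  .check_schoenfeld(p, alpha, power)
  if (any(!is.finite(hr)) || any(hr <= 0)) {
    stop("`hr` must be positive", call. = FALSE)
  }
  if (any(hr == 1)) {
    stop("`hr` = 1 needs infinitely many events", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  z^2 / (p * (1 - p) * log(hr)^2)
}

#' Schoenfeld minimum detectable hazard ratio
#'
#' Inverse of [schoenfeld_required_events()]: the smallest hazard ratio
#' `> 1` detectable with `d` events,
#' \deqn{MDHR = \exp\left(\frac{z_{1-\alpha/2} + z_{power}}
#'   {\sqrt{d\,p(1-p)}}\right).}
#' This conventional calculation assumes continuous monitoring and exact
#' covariate measurement, so it bounds the simulation MDHR from below on
#' matched scenarios.
#'
#' @param d Expected number of events, `> 0`.
#' @inheritParams schoenfeld_required_events
#' @return Hazard ratio `> 1` (full precision; round to 2 decimals for
#'   reporting).
#' @examples
#' schoenfeld_mdhr(4400, p = 0.1)              # 1.15
#' schoenfeld_mdhr(4400, p = 0.1, alpha = 1e-4)  # 1.27
#' @export
schoenfeld_mdhr <- function(d, p, alpha = 0.05, power = 0.8) {
  .check_schoenfeld(p, alpha, power)
  if (any(!is.finite(d)) || any(d <= 0)) {
    stop("`d` must be positive", call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2) + stats::qnorm(power)
  exp(z / sqrt(d * p * (1 - p)))
}

.check_schoenfeld <- function(p, alpha, power) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1)) {
    stop("`p` must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0) || any(alpha >= 1)) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  if (any(!is.finite(power)) || any(power <= 0) || any(power >= 1)) {
    stop("`power` must lie in (0, 1)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Conventional MDHR table over diseases, prevalences and alphas
#'
#' Tabulates [schoenfeld_mdhr()] for every combination of the supplied
#' expected event counts, exposure prevalences and significance levels,
#' in the layout of the usual reporting tables (MDHR at 2 decimals).
#'
#' @param events Named numeric vector of expected event counts, e.g.
#'   `c(diabetes = 6100, dementia = 4400, parkinsons = 420)`.
#' @param prevalences Exposure prevalences.
#' @param alphas Significance levels.
#' @param power Required power.
#' @return data.frame with columns `disease`, `events`, `prevalence`,
#'   `alpha`, `mdhr`.
#' @export
conventional_mdhr_table <- function(events,
                                    prevalences = c(0.01, 0.1, 0.2),
                                    alphas = 0.05, power = 0.8) {
  if (is.null(names(events))) names(events) <- paste0("d", seq_along(events))
  grid <- expand.grid(disease = names(events), prevalence = prevalences,
                      alpha = alphas, stringsAsFactors = FALSE)
  grid$events <- events[grid$disease]
  grid$mdhr <- round(schoenfeld_mdhr(grid$events, grid$prevalence,
                                     grid$alpha, power), 2)
  grid[c("disease", "events", "prevalence", "alpha", "mdhr")]
}
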