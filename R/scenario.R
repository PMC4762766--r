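# Scenario definition: one fully specified simulation cell (cohort design,
# exposures, effect sizes, frailty, transition parameters, analysis alpha).

.idm_diseases <- c("diabetes", "dementia", "parkinsons")

# Death (1 -> 3) Weibull, shared by all disease presets.
.idm_death_params <- c(scale = 42, shape = 4.3)

#' Disease presets for the three index conditions
#'
#' Published Weibull transition parameters and baseline prevalences for the
#' three diseases used to span the spectrum from very common / fast
#' progressing (type-2 diabetes) through relatively common (dementia) to
#' rare / slowly progressing (Parkinson's disease).  Onset parameters
#' (scale, shape): diabetes 65, 2.0; dementia 48, 5.6; Parkinson's 130,
#' 3.3.  Death from the healthy state uses scale 42, shape 4.3 for every
#' preset.  Baseline disease prevalence (used for prevalent-case
#' exclusion counts) is 0.14 for diabetes and 0.02 for the other two.
#'
#' @param disease One of `"diabetes"`, `"dementia"`, `"parkinsons"`.
#' @return A list of class `disease_preset` with elements `label`,
#'   `transitions` (a [transition_set()]) and `baseline_prevalence`.
#' @examples
#' disease_preset("dementia")
#' @export
disease_preset <- function(disease = c("diabetes", "dementia", "parkinsons")) {
  disease <- match.arg(disease)
  onset <- switch(disease,
    diabetes   = weibull_params(65, 2.0),
    dementia   = weibull_params(48, 5.6),
    parkinsons = weibull_params(130, 3.3))
  prev <- switch(disease, diabetes = 0.14, dementia = 0.02, parkinsons = 0.02)
  structure(
    list(label = disease,
         transitions = transition_set(
           healthy_to_diseased = onset,
           healthy_to_dead = weibull_params(.idm_death_params[["scale"]],
                                            .idm_death_params[["shape"]])),
         baseline_prevalence = prev),
    class = "disease_preset")
}

#' @export
print.disease_preset <- function(x, ...) {
  cat(sprintf("Disease preset '%s'\n", x$label))
  cat(sprintf("  onset : Weibull(scale = %g, shape = %g)\n",
              x$transitions$healthy_to_diseased$scale,
              x$transitions$healthy_to_diseased$shape))
  cat(sprintf("  death : Weibull(scale = %g, shape = %g)\n",
              x$transitions$healthy_to_dead$scale,
              x$transitions$healthy_to_dead$shape))
  cat(sprintf("  baseline prevalence: %g\n", x$baseline_prevalence))
  invisible(x)
}

#' Define a simulation scenario
#'
#' A scenario is the complete specification of one simulation cell: cohort
#' design, exposure prevalences and misclassification rates, effect sizes
#' (hazard ratios), frailty, Weibull transition parameters and the
#' significance level of the analysis.  Defaults encode the reference
#' cohort design: 30,000 participants recruited uniformly between ages 45
#' and 85, followed for 21 years with study visits every 3 years, annual
#' loss-to-follow-up rate 0.005, and log-normal frailty with standard
#' deviation 0.585 on the log-hazard scale (a 10-fold baseline-risk ratio
#' between the 97.5th and 2.5th population percentiles).
#'
#' @param disease Disease preset label; supplies the transition parameters
#'   unless `transitions` is given explicitly.
#' @param n_subjects Cohort size.
#' @param entry_age_min,entry_age_max Recruitment age window in years;
#'   entry ages are drawn uniformly on it.
#' @param followup_years Length of follow-up after entry, years.
#' @param visit_interval Years between study visits for panel (visit-based)
#'   disease ascertainment, or `"continuous"` for exact onset-time
#'   observation.
#' @param ltfu_rate Exponential loss-to-follow-up rate per year.
#' @param prevalence_env,prevalence_gen Prevalence of the binary
#'   environmental and genetic exposures.
#' @param misclass_env,misclass_gen Non-differential misclassification
#'   probabilities for the observed exposures; must be `< 0.5`.
#' @param hr_env,hr_gen,hr_gxe True hazard ratios of the environmental
#'   main effect, genetic main effect and their interaction on the onset
#'   hazard.
#' @param frailty_sd Standard deviation of the Normal frailty added to the
#'   log onset hazard; `0` disables frailty.
#' @param alpha Two-sided significance level of the analysis.
#' @param transitions Optional [transition_set()] overriding the preset.
#' @return An object of class `idm_scenario`.
#' @examples
#' sc <- scenario("dementia", prevalence_env = 0.1, hr_env = 1.5)
#' sc
#' @export
scenario <- function(disease = c("diabetes", "dementia", "parkinsons"),
                     n_subjects = 30000,
                     entry_age_min = 45, entry_age_max = 85,
                     followup_years = 21,
                     visit_interval = 3,
                     ltfu_rate = 0.005,
                     prevalence_env = 0.1, prevalence_gen = 0.1,
                     misclass_env = 0, misclass_gen = 0,
                     hr_env = 1, hr_gen = 1, hr_gxe = 1,
                     frailty_sd = 0.585,
                     alpha = 0.05,
                     transitions = NULL) {
  disease <- match.arg(disease)
  if (is.null(transitions)) {
    transitions <- disease_preset(disease)$transitions
  }
  stopifnot(inherits(transitions, "transition_set"))
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1) {
    stop("`n_subjects` must be a positive integer", call. = FALSE)
  }
  if (!(entry_age_min < entry_age_max)) {
    stop("`entry_age_min` must be below `entry_age_max`", call. = FALSE)
  }
  if (entry_age_min < 45) {
    stop("entry ages are measured from the age-45 time origin; ",
         "`entry_age_min` must be >= 45", call. = FALSE)
  }
  if (followup_years <= 0) stop("`followup_years` must be > 0", call. = FALSE)
  continuous <- identical(visit_interval, "continuous")
  if (!continuous) {
    visit_interval <- as.numeric(visit_interval)
    if (!is.finite(visit_interval) || visit_interval <= 0) {
      stop("`visit_interval` must be positive or \"continuous\"",
           call. = FALSE)
    }
    k <- followup_years / visit_interval
    if (abs(k - round(k)) > 1e-8) {
      stop("`visit_interval` must divide `followup_years`", call. = FALSE)
    }
  }
  for (nm in c("prevalence_env", "prevalence_gen")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v > 1) {
      stop("`", nm, "` must lie in [0, 1]", call. = FALSE)
    }
  }
  for (nm in c("misclass_env", "misclass_gen")) {
    v <- get(nm)
    if (!is.finite(v) || v < 0 || v >= 0.5) {
      stop("`", nm, "` must lie in [0, 0.5)", call. = FALSE)
    }
  }
  for (nm in c("hr_env", "hr_gen", "hr_gxe")) {
    v <- get(nm)
    if (!is.finite(v) || v <= 0) {
      stop("`", nm, "` must be a finite positive hazard ratio",
           call. = FALSE)
    }
  }
  if (!is.finite(frailty_sd) || frailty_sd < 0) {
    stop("`frailty_sd` must be >= 0", call. = FALSE)
  }
  if (!is.finite(ltfu_rate) || ltfu_rate < 0) {
    stop("`ltfu_rate` must be >= 0", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(disease = disease,
         n_subjects = n_subjects,
         entry_age_min = as.numeric(entry_age_min),
         entry_age_max = as.numeric(entry_age_max),
         followup_years = as.numeric(followup_years),
         visit_interval = if (continuous) "continuous" else visit_interval,
         ltfu_rate = as.numeric(ltfu_rate),
         prevalence_env = as.numeric(prevalence_env),
         prevalence_gen = as.numeric(prevalence_gen),
         misclass_env = as.numeric(misclass_env),
         misclass_gen = as.numeric(misclass_gen),
         hr_env = as.numeric(hr_env),
         hr_gen = as.numeric(hr_gen),
         hr_gxe = as.numeric(hr_gxe),
         frailty_sd = as.numeric(frailty_sd),
         alpha = as.numeric(alpha),
         transitions = transitions),
    class = "idm_scenario")
}

#' @export
print.idm_scenario <- function(x, ...) {
  obs <- if (identical(x$visit_interval, "continuous")) "continuous"
         else sprintf("visits every %g y", x$visit_interval)
  cat(sprintf("Illness-death simulation scenario: %s\n", x$disease))
  cat(sprintf("  n = %d, entry ages U(%g, %g), follow-up %g y, %s\n",
              x$n_subjects, x$entry_age_min, x$entry_age_max,
              x$followup_years, obs))
  cat(sprintf("  exposures: env p = %g (misclass %g), gen p = %g (misclass %g)\n",
              x$prevalence_env, x$misclass_env,
              x$prevalence_gen, x$misclass_gen))
  cat(sprintf("  hazard ratios: env %g, gen %g, gxe %g; frailty sd %g\n",
              x$hr_env, x$hr_gen, x$hr_gxe, x$frailty_sd))
  cat(sprintf("  alpha = %g, LTFU rate %g/y\n", x$alpha, x$ltfu_rate))
  invisible(x)
}

#' Population-average hazard multiplier of a scenario
#'
#' The simulator gives subject `i` the onset-hazard multiplier
#' `m_i = exp(bE xE + bG xG + bGxE xE xG + f_i)` with independent Bernoulli
#' exposures and Normal frailty.  To keep the marginal onset hazard
#' anchored at the preset Weibull, the baseline hazard is divided by the
#' population mean of `m_i`, which has the closed form
#' \deqn{E[m] = e^{\sigma^2/2} \sum_{(x_E, x_G)} P(x_E, x_G)
#'   e^{\beta_E x_E + \beta_G x_G + \beta_{G\times E} x_E x_G}.}
#'
#' @param scenario An [scenario()] object.
#' @return The positive calibration constant `E[m]`; 1 when all hazard
#'   ratios are 1 and frailty is absent.
#' @examples
#' calibrate_baseline_multiplier(scenario("diabetes", hr_env = 1,
#'                                        frailty_sd = 0))
#' @export
calibrate_baseline_multiplier <- function(scenario) {
  stopifnot(inherits(scenario, "idm_scenario"))
  pE <- scenario$prevalence_env
  pG <- scenario$prevalence_gen
  bE <- log(scenario$hr_env)
  bG <- log(scenario$hr_gen)
  bI <- log(scenario$hr_gxe)
  cells <- expand.grid(xE = 0:1, xG = 0:1)
  probs <- ifelse(cells$xE == 1, pE, 1 - pE) *
    ifelse(cells$xG == 1, pG, 1 - pG)
  mean_exposure <- sum(probs * exp(bE * cells$xE + bG * cells$xG +
                                     bI * cells$xE * cells$xG))
  mean_exposure * exp(scenario$frailty_sd^2 / 2)
}

#' Expected number of prevalent cases excluded at baseline
#'
#' Participants already living with the disease at recruitment are not at
#' risk of incident disease; their expected count is simply the cohort size
#' times the baseline disease prevalence of the preset.
#'
#' @param n_subjects Cohort size.
#' @param preset A [disease_preset()].
#' @return Expected prevalent-case count.
#' @examples
#' expected_prevalent_cases(30000, disease_preset("dementia"))  # 600
#' @export
expected_prevalent_cases <- function(n_subjects, preset) {
  stopifnot(inherits(preset, "disease_preset"))
  if (!is.finite(n_subjects) || n_subjects < 0) {
    stop("`n_subjects` must be >= 0", call. = FALSE)
  }
  n_subjects * preset$baseline_prevalence
}
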