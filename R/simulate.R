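# Cohort simulator for the irreversible illness-death model: latent truth,
# observation schemes (continuous vs panel), exposure misclassification.
#
# All times are in years since the age-45 origin except `t_ltfu`, which is
# years after entry.  `l` is the entry offset (entry age - 45) and acts as
# the left-truncation point: both latent transition times are drawn
# conditional on exceeding `l`, i.e. on being alive and disease-free at
# recruitment.

#' Deterministic replicate seeds from a master seed
#'
#' Every source of randomness in a Monte-Carlo run flows from one master
#' seed; replicate `i` uses `replicate_seed(master_seed, i)`.  Reusing the
#' same master seed therefore reproduces every dataset, and reusing the
#' same replicate seeds across compared settings implements common random
#' numbers.
#'
#' @param master_seed Integer master seed.
#' @param i Replicate index (1-based), possibly a vector.
#' @return Integer seed(s) in `[0, 2^31 - 2]`.
#' @export
replicate_seed <- function(master_seed, i) {
  as.integer((as.double(master_seed %% 2147483647L) * 48271 + i * 104729) %%
               2147483646)
}

#' Draw the latent truth of a simulated cohort
#'
#' Generates, for each subject: entry offset `l` uniform on the recruitment
#' age window; independent Bernoulli exposures; Normal frailty on the log
#' hazard; the latent disease-onset time `t12` from the left-truncated
#' Weibull whose hazard is the calibrated baseline times
#' `exp(bE xE + bG xG + bGxE xE xG + f)`; the latent death time `t13` from
#' the death Weibull left-truncated at `l`; and an exponential
#' loss-to-follow-up time.  Under proportional hazards a multiplier `m` on
#' the hazard is a Weibull with scale `lambda0 * m^(-1/shape)`, which is
#' how the subject-specific scale is formed.  The baseline is divided by
#' [calibrate_baseline_multiplier()] so the population-average multiplier
#' is 1 and the marginal onset hazard matches the preset.
#'
#' Draws occur in a fixed order (l, xE, xG, f, u12, u13, ltfu), so two
#' scenarios differing only in effect sizes reuse identical uniforms under
#' a common seed.
#'
#' @param scenario An [scenario()] object.
#' @param seed Integer seed for this dataset.
#' @return A data.frame with one row per subject and columns `l`, `x_env`,
#'   `x_gen`, `frailty`, `t12`, `t13`, `t_ltfu`.
#' @export
draw_cohort_truth <- function(scenario, seed) {
  stopifnot(inherits(scenario, "idm_scenario"))
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is required", call. = FALSE)
  }
  n <- scenario$n_subjects
  dis <- scenario$transitions$healthy_to_diseased
  dth <- scenario$transitions$healthy_to_dead
  calib <- calibrate_baseline_multiplier(scenario)

  set.seed(as.integer(seed))
  l <- stats::runif(n, scenario$entry_age_min - 45,
                    scenario$entry_age_max - 45)
  x_env <- stats::rbinom(n, 1L, scenario$prevalence_env)
  x_gen <- stats::rbinom(n, 1L, scenario$prevalence_gen)
  frailty <- if (scenario$frailty_sd > 0) {
    stats::rnorm(n, 0, scenario$frailty_sd)
  } else {
    # draw anyway so the uniform stream is identical with and without
    # frailty under a common seed
    stats::rnorm(n, 0, 1) * 0
  }
  log_m <- log(scenario$hr_env) * x_env + log(scenario$hr_gen) * x_gen +
    log(scenario$hr_gxe) * x_env * x_gen + frailty - log(calib)
  scale12 <- dis$scale * exp(-log_m / dis$shape)
  u12 <- stats::runif(n)
  t12 <- scale12 * ((l / scale12)^dis$shape - log1p(-u12))^(1 / dis$shape)
  u13 <- stats::runif(n)
  t13 <- dth$scale * ((l / dth$scale)^dth$shape - log1p(-u13))^(1 / dth$shape)
  t_ltfu <- if (scenario$ltfu_rate > 0) {
    stats::rexp(n, rate = scenario$ltfu_rate)
  } else {
    stats::rexp(n, rate = 1) * 0 + Inf
  }
  data.frame(l = l, x_env = x_env, x_gen = x_gen, frailty = frailty,
             t12 = t12, t13 = t13, t_ltfu = t_ltfu)
}

#' Convert latent trajectories to observed analysis records
#'
#' Applies the observation scheme.  Under `"continuous"` monitoring the
#' onset time is observed exactly whenever it precedes death, loss to
#' follow-up and the end of follow-up; otherwise the record is
#' right-censored at the earliest of those.  Under the `"panel"` scheme
#' disease status is ascertained only at scheduled visits `l + k * delta`
#' (`k = 0, ..., followup/delta`): an onset at `t12` is recorded as an
#' event at the first visit at or after it, provided the subject is still
#' under observation at that visit (strictly before death and loss to
#' follow-up; the final visit at `l + followup` counts).  Onsets the
#' subject does not survive to report are censored at the usual censoring
#' time.  Death and loss to follow-up are treated as exactly observed
#' (registry-style ascertainment); only disease onset is interval-detected.
#'
#' @param truths Output of [draw_cohort_truth()].
#' @param scenario The generating [scenario()]; supplies follow-up length
#'   and visit interval.
#' @param scheme `"continuous"`, `"panel"`, or `NULL` to take the scheme
#'   from `scenario$visit_interval`.
#' @return A data.frame with columns `l`, `t` (observed time, years since
#'   the age-45 origin), `event` (1 = incident disease, 0 = censored) and
#'   the true exposures `x_env`, `x_gen`.
#' @export
apply_observation <- function(truths, scenario, scheme = NULL) {
  stopifnot(inherits(scenario, "idm_scenario"))
  if (is.null(scheme)) {
    scheme <- if (identical(scenario$visit_interval, "continuous"))
      "continuous" else "panel"
  }
  scheme <- match.arg(scheme, c("continuous", "panel"))
  if (nrow(truths) == 0) {
    return(data.frame(l = numeric(), t = numeric(), event = integer(),
                      x_env = integer(), x_gen = integer()))
  }
  l <- truths$l
  end_fu <- l + scenario$followup_years
  cens <- pmin(truths$t13, l + truths$t_ltfu, end_fu)
  if (scheme == "continuous") {
    event <- as.integer(truths$t12 < cens)
    t_obs <- ifelse(event == 1L, truths$t12, cens)
  } else {
    delta <- scenario$visit_interval
    if (!is.numeric(delta)) {
      stop("panel observation needs a numeric `visit_interval`",
           call. = FALSE)
    }
    # first scheduled visit at or after onset
    visit <- l + delta * ceiling(pmax(truths$t12 - l, 0) / delta)
    detected <- truths$t12 <= end_fu & visit <= end_fu &
      visit < truths$t13 & visit < l + truths$t_ltfu
    event <- as.integer(detected)
    t_obs <- ifelse(detected, visit, cens)
  }
  data.frame(l = l, t = t_obs, event = event,
             x_env = truths$x_env, x_gen = truths$x_gen)
}

#' Apply non-differential exposure misclassification
#'
#' Flips each subject's observed exposure independently with the scenario's
#' misclassification probability, once per subject per dataset and
#' independently of the outcome (non-differential error).  True exposures
#' drive the event times; the flipped `x_env_obs` / `x_gen_obs` columns
#' are what the analysis sees.  Event times are untouched.
#'
#' @param records Output of [apply_observation()].
#' @param scenario The [scenario()] holding `misclass_env`, `misclass_gen`.
#' @param seed Integer seed for the flip draws.
#' @return `records` with added columns `x_env_obs`, `x_gen_obs`.
#' @export
apply_misclassification <- function(records, scenario, seed) {
  stopifnot(inherits(scenario, "idm_scenario"))
  if (missing(seed) || is.null(seed) || !is.finite(seed)) {
    stop("a finite integer `seed` is required", call. = FALSE)
  }
  n <- nrow(records)
  set.seed(as.integer(seed))
  flip_env <- if (scenario$misclass_env > 0) {
    stats::rbinom(n, 1L, scenario$misclass_env)
  } else rep(0L, n)
  flip_gen <- if (scenario$misclass_gen > 0) {
    stats::rbinom(n, 1L, scenario$misclass_gen)
  } else rep(0L, n)
  records$x_env_obs <- as.integer(xor(records$x_env, flip_env))
  records$x_gen_obs <- as.integer(xor(records$x_gen, flip_gen))
  records
}

#' Simulate one analysis-ready dataset
#'
#' Convenience wrapper running [draw_cohort_truth()],
#' [apply_observation()] and [apply_misclassification()] with seeds
#' derived from one dataset seed.
#'
#' @inheritParams draw_cohort_truth
#' @param scheme Observation scheme passed to [apply_observation()].
#' @return Analysis-ready data.frame with columns `l`, `t`, `event`,
#'   `x_env_obs`, `x_gen_obs`, `x_env`, `x_gen`.
#' @examples
#' sc <- scenario("diabetes", n_subjects = 500, prevalence_env = 0.2)
#' head(simulate_dataset(sc, seed = 1))
#' @export
simulate_dataset <- function(scenario, seed, scheme = NULL) {
  truths <- draw_cohort_truth(scenario, seed)
  rec <- apply_observation(truths, scenario, scheme)
  rec <- apply_misclassification(rec, scenario,
                                 seed = replicate_seed(seed, 1L))
  rec[c("l", "t", "event", "x_env_obs", "x_gen_obs", "x_env", "x_gen")]
}

#' Expected cumulative incident cases over follow-up
#'
#' Expected number of incident disease cases detected by each year of
#' follow-up, scaled to the cohort size.  Two independent routes are
#' provided: `"mc"` averages the cumulative event counts of simulated
#' cohorts (under the scenario's scheme, frailty and effects), while
#' `"quadrature"` integrates the competing-risks cause-specific incidence
#' of the population-average hazard over the entry-age distribution,
#' including the exponential loss-to-follow-up thinning.  The quadrature
#' route assumes a homogeneous cohort (multiplier 1 for everyone) and
#' continuous detection, so with frailty or panel observation the two
#' routes agree only approximately.
#'
#' @param scenario An [scenario()] object.
#' @param horizon_years Largest follow-up year reported; must not exceed
#'   the scenario's follow-up.
#' @param n_reps Monte-Carlo replicates (`"mc"` route).
#' @param seed Master seed (`"mc"` route).
#' @param method `"mc"` or `"quadrature"`.
#' @return data.frame with columns `year` (0, 1, ..., horizon) and
#'   `expected_cases`.
#' @export
expected_incident_trajectory <- function(scenario, horizon_years = NULL,
                                         n_reps = 20, seed = 1,
                                         method = c("mc", "quadrature")) {
  stopifnot(inherits(scenario, "idm_scenario"))
  method <- match.arg(method)
  if (is.null(horizon_years)) horizon_years <- scenario$followup_years
  if (horizon_years > scenario$followup_years + 1e-9) {
    stop("`horizon_years` exceeds the scenario's follow-up", call. = FALSE)
  }
  years <- 0:floor(horizon_years)
  if (method == "mc") {
    counts <- matrix(0, nrow = n_reps, ncol = length(years))
    for (r in seq_len(n_reps)) {
      rec <- apply_observation(
        draw_cohort_truth(scenario, replicate_seed(seed, r)), scenario)
      elapsed <- rec$t - rec$l
      for (j in seq_along(years)) {
        counts[r, j] <- sum(rec$event == 1L & elapsed <= years[j])
      }
    }
    data.frame(year = years, expected_cases = colMeans(counts))
  } else {
    dis <- scenario$transitions$healthy_to_diseased
    dth <- scenario$transitions$healthy_to_dead
    r_ltfu <- scenario$ltfu_rate
    l_lo <- scenario$entry_age_min - 45
    l_hi <- scenario$entry_age_max - 45
    # P(onset observed within y years | entry at l): cause-specific
    # incidence with death as competing risk, thinned by LTFU survival
    p_case <- function(l, y) {
      if (y == 0) return(0)
      f <- function(t) {
        exp(-weibull_cumhaz(l, t, dis$scale, dis$shape) -
              weibull_cumhaz(l, t, dth$scale, dth$shape) -
              r_ltfu * (t - l)) * hweibull(t, dis$scale, dis$shape)
      }
      stats::integrate(f, l, l + y, rel.tol = 1e-8)$value
    }
    cases <- vapply(years, function(y) {
      outer_f <- function(lv) vapply(lv, p_case, numeric(1), y = y)
      stats::integrate(outer_f, l_lo, l_hi, rel.tol = 1e-7)$value /
        (l_hi - l_lo)
    }, numeric(1))
    data.frame(year = years, expected_cases = scenario$n_subjects * cases)
  }
}

#' Read and write the tab-separated cohort dataset dialect
#'
#' Datasets are exchanged as TSV with header columns `l`, `t`, `event`,
#' `x_env_obs`, `x_gen_obs`, `x_env`, `x_gen`; times in years since the
#' age-45 origin, `event = 1` for incident disease.
#'
#' @param records Analysis-ready data.frame from [simulate_dataset()].
#' @param path Output/input file path.
#' @return `write_cohort_tsv()` returns `path` invisibly;
#'   `read_cohort_tsv()` the data.frame.
#' @export
write_cohort_tsv <- function(records, path) {
  cols <- c("l", "t", "event", "x_env_obs", "x_gen_obs", "x_env", "x_gen")
  missing_cols <- setdiff(cols, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  utils::write.table(records[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_tsv
#' @export
read_cohort_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
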