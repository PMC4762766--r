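# Monte-Carlo power estimation and minimum-detectable-hazard-ratio search.

.scan_covariates <- function(coefficient) {
  if (coefficient == "gxe") c("env", "gen", "gxe") else coefficient
}

#' Estimate statistical power by Monte-Carlo simulation
#'
#' Power is the proportion of independently simulated datasets in which
#' the Wald test of the target coefficient rejects at the scenario's
#' significance level.  The target coefficient's hazard ratio in the
#' scenario is replaced by `true_hr`; all other effects are taken from the
#' scenario as given (for main-effect scans leave the other hazard ratios
#' at 1; for interaction scans set both main effects to 1.5, the usual
#' convention of this design).  Replicate `r` uses
#' `replicate_seed(master_seed, r)`, so runs with equal master seeds share
#' datasets across compared settings (common random numbers).
#'
#' By default main-effect scans fit only the scanned exposure and
#' interaction scans fit all three terms; with rare exposures the unused
#' interaction cell frequently carries zero events, and omitting
#' zero-effect nuisance terms keeps every replicate identifiable.
#'
#' @param scenario An [scenario()] object (fixes alpha, design, nuisance
#'   effects).
#' @param coefficient Target coefficient: `"env"`, `"gen"` or `"gxe"`.
#' @param true_hr True hazard ratio of the target coefficient.
#' @param n_reps Number of simulated datasets.
#' @param master_seed Master seed; every source of randomness derives
#'   from it.
#' @param covariates Terms of the fitted analysis model; default as
#'   described above.
#' @param failure_budget Largest tolerated fraction of replicates whose
#'   fit fails or is non-identifiable; such replicates are excluded from
#'   the denominator and reported, and exceeding the budget is an error.
#' @return An object of class `idm_power`: list with `power`,
#'   `rejections`, `n_used`, `n_reps`, `n_failed`, `mc_interval` (95%
#'   Clopper-Pearson), `true_hr`, `coefficient`, `alpha`, `master_seed`.
#' @examples
#' sc <- scenario("diabetes", n_subjects = 1500, prevalence_env = 0.3,
#'                frailty_sd = 0)
#' estimate_power(sc, "env", true_hr = 2, n_reps = 20, master_seed = 1)
#' @export
estimate_power <- function(scenario, coefficient = c("env", "gen", "gxe"),
                           true_hr, n_reps, master_seed,
                           covariates = NULL, failure_budget = 0.01) {
  stopifnot(inherits(scenario, "idm_scenario"))
  coefficient <- match.arg(coefficient)
  if (!is.finite(true_hr) || true_hr <= 0) {
    stop("`true_hr` must be positive", call. = FALSE)
  }
  if (n_reps < 1) stop("`n_reps` must be >= 1", call. = FALSE)
  if (is.null(covariates)) covariates <- .scan_covariates(coefficient)
  sc <- scenario
  sc[[paste0("hr_", coefficient)]] <- true_hr

  rejections <- 0L
  n_failed <- 0L
  for (r in seq_len(n_reps)) {
    rec <- simulate_dataset(sc, seed = replicate_seed(master_seed, r))
    res <- tryCatch({
      fit <- fit_weibull_ph(rec, covariates = covariates)
      if (!fit$converged || !fit$identifiable) NULL
      else wald_test(fit, coefficient, alpha = sc$alpha)$reject
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L
    else if (res) rejections <- rejections + 1L
  }
  if (n_failed > failure_budget * n_reps) {
    stop(sprintf("%d of %d replicates failed to fit (budget %.1f%%)",
                 n_failed, n_reps, 100 * failure_budget), call. = FALSE)
  }
  n_used <- n_reps - n_failed
  ci <- as.numeric(stats::binom.test(rejections, n_used)$conf.int)
  structure(list(power = rejections / n_used, rejections = rejections,
                 n_used = n_used, n_reps = n_reps, n_failed = n_failed,
                 mc_interval = ci, true_hr = true_hr,
                 coefficient = coefficient, alpha = sc$alpha,
                 master_seed = master_seed, disease = sc$disease),
            class = "idm_power")
}

#' @export
print.idm_power <- function(x, ...) {
  cat(sprintf(
    "Power %.3f (%d/%d reject; 95%% MC interval %.3f-%.3f)\n",
    x$power, x$rejections, x$n_used, x$mc_interval[1], x$mc_interval[2]))
  cat(sprintf("  %s, coefficient %s, true HR %.2f, alpha %g%s\n",
              x$disease, x$coefficient, x$true_hr, x$alpha,
              if (x$n_failed) sprintf(", %d failed fits", x$n_failed) else ""))
  invisible(x)
}

#' Effect-size category of a minimum detectable hazard ratio
#'
#' Half-open bins: small `(1, 1.5]`, moderate `(1.5, 2]`, large `(2, 3]`,
#' substantial `> 3`.
#'
#' @param hr Hazard ratio(s) `> 1` (may be `Inf` for the `">3.00"`
#'   sentinel).
#' @return Character vector of categories.
#' @examples
#' classify_effect(c(1.5, 2.01, 3.01))
#' @export
classify_effect <- function(hr) {
  if (any(!is.na(hr) & hr <= 1)) {
    stop("`hr` must exceed 1", call. = FALSE)
  }
  cut(hr, breaks = c(1, 1.5, 2, 3, Inf),
      labels = c("small", "moderate", "large", "substantial"),
      right = TRUE) |> as.character()
}

#' Find the minimum detectable hazard ratio by bisection
#'
#' The MDHR is the smallest true hazard ratio detected with probability
#' `target_power` at the scenario's significance level and cohort size.
#' Power is assumed nondecreasing in the hazard ratio; bisection on
#' `hr_bracket` then converges to the crossing point.  All bracket points
#' share replicate seeds (common random numbers), which makes the
#' estimated power *differences* between nearby hazard ratios far more
#' stable than independent runs.  If power at the upper bracket end is
#' below target the sentinel `">3.00"` (for the default bracket) is
#' returned.  An optional coarse pre-scan (at a quarter of the replicates)
#' guards against gross non-monotonicity, which is reported as a warning
#' with the trace attached.
#'
#' @inheritParams estimate_power
#' @param target_power Required power (default 0.80).
#' @param reps_per_point Replicates per evaluated hazard ratio.
#' @param hr_bracket Search interval, default `c(1, 3)`.
#' @param resolution Bracket width at which bisection stops; the MDHR is
#'   reported to 2 decimals.
#' @param prescan Run the 5-point monotonicity pre-scan.
#' @return An object of class `idm_mdhr`: list with `mdhr` (numeric, `Inf`
#'   when undetectable within the bracket), `label` (e.g. `"1.61"` or
#'   `">3.00"`), `category`, `trace` (data.frame of evaluated points),
#'   `target_power`, `reps_per_point`, `coefficient`, `alpha`,
#'   `master_seed`.
#' @export
find_mdhr <- function(scenario, coefficient = c("env", "gen", "gxe"),
                      target_power = 0.8, reps_per_point = 1000,
                      hr_bracket = c(1, 3), resolution = 0.01,
                      master_seed = 1, covariates = NULL, prescan = TRUE) {
  stopifnot(inherits(scenario, "idm_scenario"))
  coefficient <- match.arg(coefficient)
  if (hr_bracket[1] < 1 || hr_bracket[2] <= hr_bracket[1]) {
    stop("`hr_bracket` must satisfy 1 <= lower < upper", call. = FALSE)
  }
  trace <- data.frame(hr = numeric(), power = numeric(), reps = integer())
  eval_power <- function(hr, reps) {
    pe <- estimate_power(scenario, coefficient, true_hr = hr,
                         n_reps = reps, master_seed = master_seed,
                         covariates = covariates)
    trace <<- rbind(trace,
                    data.frame(hr = hr, power = pe$power, reps = reps))
    pe
  }

  if (prescan) {
    pre_reps <- max(20L, ceiling(reps_per_point / 4))
    grid <- seq(hr_bracket[1] + 0.05 * diff(hr_bracket), hr_bracket[2],
                length.out = 5)
    pw <- vapply(grid, function(h) eval_power(h, pre_reps)$power, numeric(1))
    mc_se <- sqrt(pmax(pw * (1 - pw), 0.25 / pre_reps) / pre_reps)
    drops <- diff(pw) < -2 * (mc_se[-1] + mc_se[-length(mc_se)])
    if (any(drops)) {
      warning("power pre-scan is non-monotone beyond Monte-Carlo noise; ",
              "bisection may be unreliable (see trace)", call. = FALSE)
    }
  }

  top <- eval_power(hr_bracket[2], reps_per_point)
  if (top$power < target_power) {
    out <- list(mdhr = Inf, label = sprintf(">%.2f", hr_bracket[2]),
                category = classify_effect(Inf))
  } else {
    lo <- hr_bracket[1]; hi <- hr_bracket[2]
    while (hi - lo > resolution) {
      mid <- (lo + hi) / 2
      if (eval_power(mid, reps_per_point)$power >= target_power) {
        hi <- mid
      } else {
        lo <- mid
      }
    }
    mdhr <- round(hi, 2)
    out <- list(mdhr = mdhr, label = sprintf("%.2f", mdhr),
                category = classify_effect(mdhr))
  }
  structure(c(out, list(trace = trace, target_power = target_power,
                        reps_per_point = reps_per_point,
                        coefficient = coefficient, alpha = scenario$alpha,
                        master_seed = master_seed,
                        disease = scenario$disease)),
            class = "idm_mdhr")
}

#' @export
print.idm_mdhr <- function(x, ...) {
  cat(sprintf("Minimum detectable hazard ratio: %s (%s effect)\n",
              x$label, x$category))
  cat(sprintf("  %s, coefficient %s, alpha %g, target power %g, %d reps/point\n",
              x$disease, x$coefficient, x$alpha, x$target_power,
              x$reps_per_point))
  invisible(x)
}

#' Run a grid of power or MDHR cells
#'
#' Evaluates one row per cell over a list of scenarios.  Each cell is
#' deterministic given the master seed (cell `j` uses
#' `replicate_seed(master_seed, 10000 + j)` as its own master seed) and
#' the run is resumable: when `out_csv` exists, cells whose `cell` id is
#' already present are skipped and new rows appended.  Cell-level failures
#' are recorded in the `error` column and do not stop the run.
#'
#' @param cells A named list; each element is a list with components
#'   `scenario` (an [scenario()]), `coefficient`, and either `true_hr`
#'   (power mode) or nothing (mdhr mode).
#' @param mode `"power"` or `"mdhr"`.
#' @param n_reps Replicates per cell (power) or per bisection point
#'   (mdhr).
#' @param master_seed Master seed of the whole grid.
#' @param out_csv Optional CSV path for persistent, resumable results.
#' @param ... Further arguments passed to [estimate_power()] or
#'   [find_mdhr()].
#' @return data.frame with one row per cell (scenario descriptors plus
#'   `power`/`mc_lower`/`mc_upper` or `mdhr`/`category`, and `error`).
#' @export
run_grid <- function(cells, mode = c("power", "mdhr"), n_reps = 1000,
                     master_seed = 1, out_csv = NULL, ...) {
  mode <- match.arg(mode)
  if (length(cells) == 0) {
    return(data.frame(cell = character(), disease = character()))
  }
  if (is.null(names(cells)) || any(names(cells) == "")) {
    names(cells) <- sprintf("cell%02d", seq_along(cells))
  }
  done <- character(0)
  prev <- NULL
  if (!is.null(out_csv) && file.exists(out_csv)) {
    prev <- utils::read.csv(out_csv, stringsAsFactors = FALSE)
    done <- prev$cell
  }
  rows <- list()
  for (j in seq_along(cells)) {
    id <- names(cells)[j]
    if (id %in% done) next
    cell <- cells[[j]]
    sc <- cell$scenario
    seed_j <- replicate_seed(master_seed, 10000L + j)
    base <- data.frame(
      cell = id, disease = sc$disease, coefficient = cell$coefficient,
      alpha = sc$alpha, prevalence_env = sc$prevalence_env,
      prevalence_gen = sc$prevalence_gen,
      misclass_env = sc$misclass_env, misclass_gen = sc$misclass_gen,
      scheme = if (identical(sc$visit_interval, "continuous"))
        "continuous" else sprintf("panel%g", sc$visit_interval),
      n_reps = n_reps, seed = seed_j, stringsAsFactors = FALSE)
    row <- tryCatch({
      if (mode == "power") {
        pe <- estimate_power(sc, cell$coefficient, true_hr = cell$true_hr,
                             n_reps = n_reps, master_seed = seed_j, ...)
        cbind(base, data.frame(true_hr = cell$true_hr, power = pe$power,
                               mc_lower = pe$mc_interval[1],
                               mc_upper = pe$mc_interval[2],
                               n_failed = pe$n_failed, error = ""))
      } else {
        md <- find_mdhr(sc, cell$coefficient, reps_per_point = n_reps,
                        master_seed = seed_j, ...)
        cbind(base, data.frame(mdhr = md$label, category = md$category,
                               error = ""))
      }
    }, error = function(e) {
      cbind(base, if (mode == "power") {
        data.frame(true_hr = cell$true_hr, power = NA_real_,
                   mc_lower = NA_real_, mc_upper = NA_real_,
                   n_failed = NA_integer_, error = conditionMessage(e))
      } else {
        data.frame(mdhr = NA_character_, category = NA_character_,
                   error = conditionMessage(e))
      })
    })
    rows[[id]] <- row
    if (!is.null(out_csv)) {
      fresh <- !file.exists(out_csv)
      utils::write.table(row, out_csv, sep = ",", row.names = FALSE,
                         col.names = fresh, append = !fresh, quote = TRUE)
    }
  }
  new <- do.call(rbind, rows)
  out <- if (is.null(prev)) new else rbind(prev, new)
  rownames(out) <- NULL
  out
}
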