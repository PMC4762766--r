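# Left-truncated Weibull PH likelihood, MLE, Wald and LR tests.

test_that("likelihood reduces to the exponential closed form", {
  # shape fixed at 1, no truncation, no censoring, no covariates: the MLE
  # of the scale is total time / events
  set.seed(1)
  t <- rexp(500, rate = 1 / 30)
  rec <- data.frame(l = 0, t = t, event = 1L, x_env = 0L, x_gen = 0L)
  fit <- fit_weibull_ph(rec, covariates = character(0), fix_shape = 1)
  expect_equal(exp(fit$estimates[["log_scale"]]), sum(t) / length(t),
               tolerance = 1e-6)
  # likelihood value at the optimum matches the exponential log-likelihood
  lam <- sum(t) / length(t)
  expect_equal(fit$loglik, sum(dexp(t, 1 / lam, log = TRUE)),
               tolerance = 1e-8)
})

test_that("negative log-likelihood matches a direct density evaluation", {
  sc <- tiny_scenario(n = 400, hr_env = 1.5)
  rec <- simulate_dataset(sc, seed = 3)
  par <- c(log(60), log(2.2), 0.3)
  nll <- weibull_ph_nloglik(par, rec, covariates = "env")
  # independent evaluation from the truncated density / survival, with the
  # PH multiplier folded into the scale
  m <- exp(0.3 * rec$x_env_obs)
  sc_i <- exp(par[1]) * m^(-1 / exp(par[2]))
  ll <- sum(ifelse(rec$event == 1L,
                   log(dltweibull(rec$t, sc_i, exp(par[2]), lower = rec$l)),
                   log(1 - pltweibull(rec$t, sc_i, exp(par[2]),
                                      lower = rec$l))))
  expect_equal(nll, -ll, tolerance = 1e-8)
  expect_equal(weibull_ph_nloglik(par, rec[0, ], covariates = "env"), 0)
  expect_error(weibull_ph_nloglik(c(NA, 0, 0), rec, "env"), "non-finite")
})

test_that("analytic gradient matches numerical differentiation", {
  sc <- tiny_scenario(n = 300, hr_env = 2)
  rec <- simulate_dataset(sc, seed = 9)
  X <- idmpower:::ph_design(rec, c("env", "gen"))
  par <- c(log(55), log(1.8), 0.4, -0.2)
  g <- idmpower:::.wph_grad(par, rec$l, rec$t, rec$event, X)
  eps <- 1e-6
  g_num <- vapply(seq_along(par), function(j) {
    pp <- par; pm <- par
    pp[j] <- pp[j] + eps; pm[j] <- pm[j] - eps
    (idmpower:::.wph_ll(pp, rec$l, rec$t, rec$event, X) -
       idmpower:::.wph_ll(pm, rec$l, rec$t, rec$event, X)) / (2 * eps)
  }, numeric(1))
  expect_equal(unname(g), g_num, tolerance = 1e-4)
})

test_that("records with zero risk time are rejected as data errors", {
  rec <- data.frame(l = c(5, 7), t = c(10, 7), event = c(1L, 0L),
                    x_env = 0L, x_gen = 0L)
  expect_error(fit_weibull_ph(rec, covariates = character(0)),
               "zero risk time")
})

test_that("the MLE recovers generating parameters on analysis-model data", {
  # simulated under the analysis model itself (no frailty, continuous,
  # no misclassification): estimates within 3 SE of truth
  sc <- scenario("diabetes", n_subjects = 30000, prevalence_env = 0.3,
                 prevalence_gen = 0.3, hr_env = 1.5, frailty_sd = 0,
                 visit_interval = "continuous")
  fit <- fit_weibull_ph(simulate_dataset(sc, seed = 123),
                        covariates = "env")
  expect_true(fit$converged)
  expect_lt(abs(fit$estimates[["beta_env"]] - log(1.5)),
            3 * fit$se[["beta_env"]])
  expect_lt(abs(exp(fit$estimates[["log_shape"]]) - 2),
            3 * exp(fit$estimates[["log_shape"]]) * fit$se[["log_shape"]])
  # the fitted baseline is the unexposed scale: preset 65 inflated by the
  # calibration constant c through lambda0 * c^(1/shape)
  base_scale <- 65 * calibrate_baseline_multiplier(sc)^(1 / 2)
  expect_lt(abs(exp(fit$estimates[["log_scale"]]) - base_scale),
            3 * exp(fit$estimates[["log_scale"]]) * fit$se[["log_scale"]])
})

test_that("the MLE agrees with an independent left-truncated Weibull fitter", {
  skip_if_not_installed("flexsurv")
  sc <- scenario("dementia", n_subjects = 5000, prevalence_env = 0.2,
                 hr_env = 1.8, frailty_sd = 0, visit_interval = "continuous")
  rec <- simulate_dataset(sc, seed = 77)
  fit <- fit_weibull_ph(rec, covariates = "env")
  fs <- flexsurv::flexsurvreg(
    survival::Surv(l, t, event) ~ x_env_obs, data = rec, dist = "weibullPH")
  expect_equal(fit$estimates[["beta_env"]],
               unname(fs$res["x_env_obs", "est"]), tolerance = 1e-4)
  expect_equal(fit$se[["beta_env"]], unname(fs$res["x_env_obs", "se"]),
               tolerance = 1e-3)
  expect_equal(exp(fit$estimates[["log_shape"]]),
               unname(fs$res["shape", "est"]), tolerance = 1e-4)
  # flexsurv's weibullPH "scale" is the rate m in S(t) = exp(-m t^shape),
  # i.e. m = lambda^-shape in this package's parameterization
  expect_equal(exp(fit$estimates[["log_scale"]]),
               unname(fs$res["scale", "est"])^(-1 / unname(fs$res["shape", "est"])),
               tolerance = 1e-4)
})

test_that("refitting identical records reproduces estimates bit-identically", {
  sc <- tiny_scenario(n = 800, hr_env = 1.5)
  rec <- simulate_dataset(sc, seed = 55)
  f1 <- fit_weibull_ph(rec, covariates = "env")
  f2 <- fit_weibull_ph(rec, covariates = "env")
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$vcov, f2$vcov)
})

test_that("degenerate designs are flagged instead of failing silently", {
  sc <- tiny_scenario(n = 500, prevalence_env = 0)
  rec <- simulate_dataset(sc, seed = 6)
  fit <- fit_weibull_ph(rec, covariates = "env")
  expect_false(fit$identifiable)
})

test_that("Wald test uses the strict-boundary rejection rule", {
  fit <- structure(list(
    estimates = c(log_scale = 4, log_shape = 0.7, beta_env = 0),
    se = c(log_scale = 0.1, log_shape = 0.1, beta_env = 0.2),
    covariates = "env"), class = "idm_fit")
  w <- wald_test(fit, "env", alpha = 0.05)
  expect_equal(w$p_value, 1)
  expect_false(w$reject)
  # |z| exactly at the critical value does not reject
  fit$estimates[["beta_env"]] <- qnorm(0.975) * 0.2
  expect_false(wald_test(fit, "env", alpha = 0.05)$reject)
  fit$estimates[["beta_env"]] <- (qnorm(0.975) + 1e-6) * 0.2
  expect_true(wald_test(fit, "env", alpha = 0.05)$reject)
  fit$se[["beta_env"]] <- 0
  expect_error(wald_test(fit, "env"), "undefined")
})

test_that("Wald and likelihood-ratio decisions agree on repeated datasets", {
  sc <- scenario("diabetes", n_subjects = 2000, prevalence_env = 0.3,
                 hr_env = 1.5, frailty_sd = 0, visit_interval = "continuous")
  agree <- logical(100)
  for (r in seq_len(100)) {
    rec <- simulate_dataset(sc, seed = replicate_seed(2718, r))
    w <- wald_test(fit_weibull_ph(rec, covariates = "env"), "env", 0.05)
    l <- lr_test(rec, "env", covariates = "env", alpha = 0.05)
    agree[r] <- w$reject == l$reject
  }
  expect_gte(mean(agree), 0.99)
})

test_that("Wald 95% intervals attain nominal coverage under the analysis model", {
  sc <- scenario("diabetes", n_subjects = 2000, prevalence_env = 0.3,
                 hr_env = 1.5, frailty_sd = 0, visit_interval = "continuous")
  n_rep <- 300
  cover <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    fit <- fit_weibull_ph(simulate_dataset(sc, seed = replicate_seed(31, r)),
                          covariates = "env")
    lo <- fit$estimates[["beta_env"]] - qnorm(0.975) * fit$se[["beta_env"]]
    hi <- fit$estimates[["beta_env"]] + qnorm(0.975) * fit$se[["beta_env"]]
    cover[r] <- lo <= log(1.5) && log(1.5) <= hi
  }
  # 0.95 within 3 binomial SE at 300 replicates
  expect_lt(abs(mean(cover) - 0.95), 3 * sqrt(0.95 * 0.05 / n_rep))
})
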