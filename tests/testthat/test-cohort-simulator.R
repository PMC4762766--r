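# Latent-truth generation, observation schemes, misclassification.

test_that("latent transition times follow the left-truncated Weibull", {
  # homogeneous cohort: probability-integral transform of t12 given entry
  # must be uniform (sampler-vs-CDF oracle)
  sc <- scenario("diabetes", n_subjects = 1e5, prevalence_env = 0,
                 prevalence_gen = 0, frailty_sd = 0)
  truth <- draw_cohort_truth(sc, seed = 2024)
  expect_true(all(truth$t12 > truth$l))
  expect_true(all(truth$t13 > truth$l))
  u12 <- pltweibull(truth$t12, 65, 2, lower = truth$l)
  expect_gt(suppressWarnings(ks.test(u12, "punif"))$p.value, 0.01)
  u13 <- pltweibull(truth$t13, 42, 4.3, lower = truth$l)
  expect_gt(suppressWarnings(ks.test(u13, "punif"))$p.value, 0.01)
})

test_that("exposures, frailty and loss to follow-up match their laws", {
  sc <- scenario("dementia", n_subjects = 1e5, prevalence_env = 1,
                 prevalence_gen = 0.1, frailty_sd = 0.585)
  truth <- draw_cohort_truth(sc, seed = 5)
  expect_true(all(truth$x_env == 1))
  expect_equal(mean(truth$x_gen), 0.1, tolerance = 0.01)
  expect_equal(sd(truth$frailty), 0.585, tolerance = 0.01)
  # LTFU ~ Exponential(0.005): mean 200 years
  expect_equal(mean(truth$t_ltfu), 200, tolerance = 0.02 * 200)
  # entry offsets span the age window measured from the age-45 origin,
  # with the moments of a uniform draw
  expect_gte(min(truth$l), 0)
  expect_lte(max(truth$l), 40)
  expect_lt(abs(mean(truth$l) - 20), 0.15)       # 3 SE at n = 1e5
  expect_lt(abs(sd(truth$l) - 40 / sqrt(12)), 0.15)
})

test_that("proportional hazards holds in the generator", {
  # with an exposure HR, the PIT of t12 under the subject-specific scale
  # must still be uniform
  sc <- scenario("parkinsons", n_subjects = 3e4, prevalence_env = 0.5,
                 prevalence_gen = 0, hr_env = 2, frailty_sd = 0)
  truth <- draw_cohort_truth(sc, seed = 12)
  calib <- calibrate_baseline_multiplier(sc)
  m <- exp(log(2) * truth$x_env) / calib
  sc_i <- 130 * m^(-1 / 3.3)
  u <- pltweibull(truth$t12, sc_i, 3.3, lower = truth$l)
  expect_gt(suppressWarnings(ks.test(u, "punif"))$p.value, 0.01)
})

test_that("continuous observation records the exact onset or censoring time", {
  sc <- scenario("diabetes", n_subjects = 4, visit_interval = "continuous",
                 followup_years = 21)
  truths <- data.frame(
    l = c(5, 5, 5, 5), x_env = 0L, x_gen = 0L, frailty = 0,
    t12 = c(10, 40, 12, 28),     # onset at l+5, after fu, after death, l+23
    t13 = c(50, 50, 11, 50),
    t_ltfu = c(100, 100, 100, 100))
  rec <- apply_observation(truths, sc, scheme = "continuous")
  expect_equal(rec$event, c(1L, 0L, 0L, 0L))
  expect_equal(rec$t, c(10, 26, 11, 26))
  expect_true(all(rec$t > rec$l))
})

test_that("panel observation detects onset at the first later visit", {
  sc <- scenario("diabetes", n_subjects = 5, visit_interval = 3,
                 followup_years = 21)
  truths <- data.frame(
    l = rep(2, 5), x_env = 0L, x_gen = 0L, frailty = 0,
    t12 = c(2 + 4.2, 2 + 4.2, 2 + 20.5, 2 + 6.0, 2 + 2.0),
    t13 = c(2 + 20, 2 + 5, 2 + 30, 2 + 30, 2 + 2.5),
    t_ltfu = c(100, 100, 100, 100, 100))
  rec <- apply_observation(truths, sc, scheme = "panel")
  # onset l+4.2 detected at visit l+6 when death (l+20) comes later
  expect_equal(rec$t[1], 2 + 6); expect_equal(rec$event[1], 1L)
  # same onset censored at death l+5 before the l+6 visit
  expect_equal(rec$t[2], 2 + 5); expect_equal(rec$event[2], 0L)
  # onset at l+20.5 detected at the final visit l+21
  expect_equal(rec$t[3], 2 + 21); expect_equal(rec$event[3], 1L)
  # onset exactly at a visit time is recorded at that visit
  expect_equal(rec$t[4], 2 + 6); expect_equal(rec$event[4], 1L)
  # death before the first post-onset visit censors at death
  expect_equal(rec$t[5], 2 + 2.5); expect_equal(rec$event[5], 0L)
})

test_that("panel events always sit on scheduled visit times, never before onset", {
  sc <- scenario("dementia", n_subjects = 2e4, prevalence_env = 0.1,
                 visit_interval = 3)
  truth <- draw_cohort_truth(sc, seed = 31)
  rec <- apply_observation(truth, sc, scheme = "panel")
  ev <- rec$event == 1L
  expect_true(all(rec$t[ev] >= truth$t12[ev]))
  k <- (rec$t[ev] - rec$l[ev]) / 3
  expect_equal(k, round(k), tolerance = 1e-9)
  expect_true(all(rec$t[ev] - rec$l[ev] <= 21 + 1e-9))
})

test_that("empty cohorts produce empty observation output", {
  sc <- scenario("diabetes", n_subjects = 1)
  empty <- draw_cohort_truth(sc, seed = 1)[0, ]
  expect_equal(nrow(apply_observation(empty, sc)), 0)
})

test_that("misclassification is non-differential and leaves times untouched", {
  sc <- scenario("diabetes", n_subjects = 1e5, prevalence_env = 0.3,
                 prevalence_gen = 0.3, misclass_env = 0.1,
                 misclass_gen = 0.01)
  rec <- apply_observation(draw_cohort_truth(sc, seed = 8), sc)
  rec0 <- rec
  rec <- apply_misclassification(rec, sc, seed = 99)
  expect_identical(rec$t, rec0$t)
  expect_identical(rec$event, rec0$event)
  flips_env <- rec$x_env_obs != rec$x_env
  flips_gen <- rec$x_gen_obs != rec$x_gen
  expect_lt(abs(mean(flips_env) - 0.10), 0.005)
  expect_lt(abs(mean(flips_gen) - 0.01), 0.003)
  # independence of the outcome (non-differential)
  expect_lt(abs(cor(as.numeric(flips_env), rec$event)), 0.01)
  # rate 0 copies the truth
  sc0 <- scenario("diabetes", n_subjects = 100)
  rec0 <- apply_misclassification(
    apply_observation(draw_cohort_truth(sc0, seed = 3), sc0), sc0, seed = 4)
  expect_identical(rec0$x_env_obs, rec0$x_env)
})

test_that("LTFU-only censoring over 20 years stays below the no-competition bound", {
  sc <- scenario("diabetes", n_subjects = 5e4, followup_years = 20,
                 visit_interval = "continuous", prevalence_env = 0)
  truth <- draw_cohort_truth(sc, seed = 21)
  ltfu_frac <- mean(truth$t_ltfu < 20 &
                      truth$t_ltfu < pmin(truth$t12, truth$t13) - truth$l)
  expect_lte(ltfu_frac, 1 - exp(-0.1) + 0.01)
})

test_that("Monte-Carlo and quadrature incident trajectories agree without frailty", {
  sc <- scenario("diabetes", n_subjects = 2e4, prevalence_env = 0,
                 prevalence_gen = 0, frailty_sd = 0,
                 visit_interval = "continuous")
  mc <- expected_incident_trajectory(sc, 21, n_reps = 8, seed = 17,
                                     method = "mc")
  qd <- expected_incident_trajectory(sc, 21, method = "quadrature")
  final_mc <- mc$expected_cases[mc$year == 21]
  final_qd <- qd$expected_cases[qd$year == 21]
  # 8 replicates of 20k: binomial SE of the mean count
  se <- sqrt(final_qd * (1 - final_qd / sc$n_subjects) / 8)
  expect_lt(abs(final_mc - final_qd), 3 * se)
  expect_equal(qd$expected_cases[qd$year == 0], 0)
  expect_true(all(diff(qd$expected_cases) >= 0))
})

test_that("datasets are reproducible from the seed and round-trip as TSV", {
  sc <- tiny_scenario(n = 300)
  a <- simulate_dataset(sc, seed = 42)
  b <- simulate_dataset(sc, seed = 42)
  expect_identical(a, b)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cohort_tsv(a, path)
  back <- read_cohort_tsv(path)
  expect_equal(back$t, a$t)
  expect_equal(back$event, a$event)
  expect_equal(back$x_env_obs, a$x_env_obs)
})
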