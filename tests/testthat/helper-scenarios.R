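# Small scenario factories shared across test files.  Sizes are kept well
# below the reference cohort so the unit suite stays fast; the full-size
# checks live in test-acceptance.R.

tiny_scenario <- function(n = 2000, disease = "diabetes", frailty_sd = 0,
                          hr_env = 1, prevalence_env = 0.3, ...) {
  scenario(disease, n_subjects = n, prevalence_env = prevalence_env,
           prevalence_gen = 0.3, frailty_sd = frailty_sd,
           hr_env = hr_env, visit_interval = "continuous", ...)
}

# diabetes-preset transition set, used by distribution-level tests
diabetes_transitions <- function() {
  transition_set(weibull_params(65, 2.0), weibull_params(42, 4.3))
}
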