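# Example scenario: dementia incidence in a 30,000-person cohort followed
# 21 years with visits every 3 years; environmental exposure prevalence
# 0.1 measured with 10% misclassification.  Usable directly with the CLI:
#   Rscript inst/cli/idmpower.R power --config <this file> \
#       --out power.csv --hr 1.5 --reps 1000 --seed 1
disease: dementia
n_subjects: 30000
entry_age_min: 45.0
entry_age_max: 85.0
followup_years: 21.0
visit_interval: 3.0
ltfu_rate: 0.005
prevalence_env: 0.1
prevalence_gen: 0.1
misclass_env: 0.1
misclass_gen: 0.0
hr_env: 1.0
hr_gen: 1.0
hr_gxe: 1.0
frailty_sd: 0.585
alpha: 0.05
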