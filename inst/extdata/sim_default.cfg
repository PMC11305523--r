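# Default forward-simulation run: pre-obstetrics equilibrium followed by
# relaxation of childbirth-mortality selection at the 1940 transition.
# Schedules use the historical-scale figures: LMDR 15%, neonatal mortality
# 14%, obesity relative risk 4 on both, 6 births per woman; the modern
# schedule keeps the relative risks but at modern mortality (LMDR 0.01%,
# neonatal 0.3%).
transition_generation: 4
n_generations: 12
initial_freq: 0.10
generation_years: 25
transition_year: 1940
mode: deterministic
convention: terminal
pre_lmdr: 0.15
pre_neonatal_rate: 0.14
pre_rr_maternal: 4
pre_rr_perinatal: 4
pre_fertility: 6
post_lmdr: 0.0001
post_neonatal_rate: 0.003
post_rr_maternal: 4
post_rr_perinatal: 4
post_fertility: 2.5
arch_n_loci: 1000
arch_effect_per_allele: 0.1
arch_baseline_bmi: 25
arch_reference_freq: 0.10
arch_dosage: haploid
arch_env_sd: 3
arch_obesity_threshold: 30
seed: 1
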