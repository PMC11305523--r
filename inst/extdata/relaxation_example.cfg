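# Worked relaxation example: a population stable at 10% obesogenic pool
# under a per-generation gain and loss of exactly 0.5 (maternal-only
# selection, LMDR 1/7, relative risk 4: loss = 1 - (1 - 4/7)/(1 - 1/7)
# = 0.5). When obstetrics removes the loss, the pool rises 10% -> 15% in
# one generation and 22.5% the next.
transition_generation: 2
n_generations: 6
initial_freq: 0.10
generation_years: 25
transition_year: 1940
mode: deterministic
convention: terminal
pre_lmdr: 0.142857142857143
pre_neonatal_rate: 0
pre_rr_maternal: 4
pre_rr_perinatal: 1
pre_fertility: 6
post_lmdr: 0
post_neonatal_rate: 0
post_rr_maternal: 1
post_rr_perinatal: 1
post_fertility: 2.5
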