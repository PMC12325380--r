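# Small demonstration pipeline configuration: a simulated twin cohort with
# dual parental raters, all analysis stages, modest sizes so the full run
# finishes in about a minute.
input: simulate
seed: 20
n_mz_pairs: 400
n_dz_pairs: 400
multirater: yes
lmm_cohort: ntr
lmm_n: 500
digits: 2
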