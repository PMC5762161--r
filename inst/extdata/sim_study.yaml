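# Default Monte-Carlo study grid: type-I error (effect = 0) of the naive,
# subject-based and mixed analyses across intraclass correlations and
# cluster sizes, plus one powered scenario. Components are on the SD scale;
# icc_subject = sigma_subject^2 / (sigma_subject^2 + sigma_residual^2).
n_reps: 1000
alpha: 0.05
scenarios:
  null_icc0_m5:
    layout: {n_groups: 2, subjects_per_group: 20, samples_per_subject: 5, replicates_per_sample: 1}
    components: {subject: 0.0, sample: 0.0, residual: 1.0}
    effect: 0.0
  null_icc10_m5:
    layout: {n_groups: 2, subjects_per_group: 20, samples_per_subject: 5, replicates_per_sample: 1}
    components: {subject: 0.3333, sample: 0.0, residual: 1.0}
    effect: 0.0
  null_icc50_m20:
    layout: {n_groups: 2, subjects_per_group: 20, samples_per_subject: 20, replicates_per_sample: 1}
    components: {subject: 1.0, sample: 0.0, residual: 1.0}
    effect: 0.0
  powered_nested:
    layout: {n_groups: 2, subjects_per_group: 6, samples_per_subject: 2, replicates_per_sample: 3}
    components: {subject: 0.4, sample: 0.2, residual: 0.1}
    effect: 0.4
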