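# Default group specifications for the synthetic cohort sampler: the
# reference cohort of 23 benign and 45 metastatic retropharyngeal lymph
# nodes. Parameter entries are mean/sd of a truncated normal; category
# probabilities are given as counts.
benign:
  n_nodes: 23
  parameters:
    adc:        {mean: 0.655, sd: 0.063}
    ddc:        {mean: 0.721, sd: 0.073}
    alpha_sem:  {mean: 0.685, sd: 0.047}
    d_froc:     {mean: 0.631, sd: 0.065}
    beta_froc:  {mean: 0.714, sd: 0.071}
    mu_froc:    {mean: 3.235, sd: 0.291}
    d_ctrw:     {mean: 0.782, sd: 0.084}
    alpha_ctrw: {mean: 0.694, sd: 0.110}
    beta_ctrw:  {mean: 0.821, sd: 0.027}
  miad_counts: [13, 9, 1]       # [6,8), [8,10), >=10 mm
  maxad_counts: [6, 17, 0]      # [6,10), [10,20), >=20 mm
  homogeneous_count: 16
  well_defined_count: 20
metastatic:
  n_nodes: 45
  parameters:
    adc:        {mean: 0.615, sd: 0.068}
    ddc:        {mean: 0.622, sd: 0.077}
    alpha_sem:  {mean: 0.748, sd: 0.044}
    d_froc:     {mean: 0.559, sd: 0.061}
    beta_froc:  {mean: 0.789, sd: 0.040}
    mu_froc:    {mean: 3.461, sd: 0.278}
    d_ctrw:     {mean: 0.688, sd: 0.074}
    alpha_ctrw: {mean: 0.649, sd: 0.082}
    beta_ctrw:  {mean: 0.889, sd: 0.040}
  miad_counts: [21, 8, 16]
  maxad_counts: [20, 24, 1]
  homogeneous_count: 29
  well_defined_count: 35
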