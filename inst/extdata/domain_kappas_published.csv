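# Published inter-rater reliability of the risk-of-bias tool on 109
# physiotherapy trials: weighted kappa per item, blinded external panel vs
# Cochrane review authors, and within the external panel, with the
# published 95% CIs and interpretation labels.
domain,n,kappa_vs_cochrane,ci_low_vs_cochrane,ci_high_vs_cochrane,label_vs_cochrane,kappa_within_panel,ci_low_within_panel,ci_high_within_panel,label_within_panel
sequence_generation,109,0.62,0.46,0.76,good agreement,0.71,0.58,0.84,good agreement
allocation_concealment,108,0.30,0.12,0.43,slight agreement,0.79,0.65,0.93,good agreement
blinding_participants_personnel,86,0.15,0.04,0.24,poor agreement,0.56,0.54,0.59,fair agreement
blinding_outcome_assessment,97,0.41,0.37,0.48,slight agreement,0.54,0.36,0.62,fair agreement
incomplete_outcome_data,96,0.24,0.07,0.32,slight agreement,0.71,0.69,0.73,good agreement
selective_reporting,87,0.13,0.05,0.32,poor agreement,0.50,0.29,0.63,fair agreement
other_bias,78,-0.04,-0.08,0.04,poor agreement,0.32,0.25,0.42,fair agreement
overall,108,0.02,-0.06,0.06,poor agreement,0.55,0.40,0.70,fair agreement
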