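cell_id,A1,A2,B1,B2
g0_clear,0.9,0.05,0.03,0.02
g2s_no_hard,0.3,0.3,0.2,0.2
g2_within,0.6,0.55,0.05,0
g3_cross,0.6,0.05,0.55,0
g2_tie_at_hard,0.5,0.5,0,0
g3_tie_at_hard,0.5,0,0.5,0
g1_uniform,0.25,0.25,0.25,0.25
g2s_override,0.55,0.4,0.03,0.02
g3s_override,0.55,0.03,0.4,0.02
g2s_soft_only,0.45,0.35,0.1,0.1
g3s_soft_only,0.45,0.1,0.35,0.1
g1_soft_boundary,0.3,0.29,0.2,0.21
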