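gene_id	ct_target_mut	ct_control_mut	ct_target_wt	ct_control_wt
gshA	18.2	15.1	21.9	15.0
yagM	19.5	15.0	24.1	15.2
ybcK	20.1	15.2	24.8	15.1
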