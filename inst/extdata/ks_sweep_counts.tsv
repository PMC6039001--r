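datamart	n_sizes	n_tests	n_excluded	n_p_le_1e6	n_p_le_1e3
DM1	46	3165	9	125	426
DM2	54	3704	22	298	766
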