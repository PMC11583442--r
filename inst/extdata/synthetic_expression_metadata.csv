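sample_id,condition
sample_001,control
sample_002,treated
sample_003,control
sample_004,treated
sample_005,control
sample_006,treated
sample_007,control
sample_008,treated
sample_009,control
sample_010,treated
sample_011,control
sample_012,treated
sample_013,control
sample_014,treated
sample_015,control
sample_016,treated
sample_017,control
sample_018,treated
sample_019,control
sample_020,treated
sample_021,control
sample_022,treated
sample_023,control
sample_024,treated
sample_025,control
sample_026,treated
sample_027,control
sample_028,treated
sample_029,control
sample_030,treated
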