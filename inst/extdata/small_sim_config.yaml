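# bundled small simulation profile for end-to-end runs
seed: 5
n_loci: 12
n_reads: 4000
on_target_fraction: 0.5
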