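n_plus: 10
n_minus: 10
L: 12
mode: preaggregated
seed: 11
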