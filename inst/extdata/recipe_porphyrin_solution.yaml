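n_porphyrin: 4
n_salt_pairs: 0
L: 10
seed: 304
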