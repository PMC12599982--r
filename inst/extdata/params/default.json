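{"A": 0.3, "alpha": 31.7, "beta": 1.4, "f_min": 1.4, "f_max": 2.3, "T": 6}
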