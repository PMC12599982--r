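{"A": 0.1, "alpha": 65.4, "beta": 77.1, "f_min": 0.8, "f_max": 2.8, "T": 10}
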