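time rate
10 0.004
13 0.006
16 0.009
20 0.013
24 0.018
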