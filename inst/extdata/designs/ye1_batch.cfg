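# Mini-bioreactor batch template (YE1-style): 10 mL, OD600 0.3,
# 9 g/L glucose, 10 g/L yeast extract
OD0 = 0.3
od_factor = 0.37
S0 = 9
YE0 = 10
V0 = 0.01
t_end = 10
reactor.DOT_star = 100
reactor.kLa = 1000
reactor.H = 14000
reactor.tau = 0.008
feed.kind = none
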