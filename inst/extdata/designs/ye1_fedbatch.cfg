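# Mini-bioreactor fed-batch template (YE1-style): 8 h batch, then an
# exponential bolus feed (pulses every 5 min, mu_set 0.2 1/h, Si 400 g/L)
# with 30 uL/h evaporation
OD0 = 0.3
od_factor = 0.37
S0 = 9
YE0 = 10
V0 = 0.01
t_end = 14
reactor.DOT_star = 100
reactor.kLa = 1000
reactor.H = 14000
reactor.tau = 0.008
feed.kind = bolus
feed.Si = 400
feed.t_start = 8
feed.F0 = 5e-5
feed.mu_set = 0.2
feed.pulse_interval = 0.0833333333333333
feed.evaporation = 3e-5
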