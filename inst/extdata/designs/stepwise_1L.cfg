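# 1 L stirred-tank stepwise fed-batch template (illustrative schedule:
# the operator-adjusted rates of a real run are not reproducible)
X0 = 0.05
S0 = 15
YE0 = 10
V0 = 1
t_end = 30
reactor.DOT_star = 100
reactor.kLa = 300
reactor.H = 14000
reactor.tau = 0.008
feed.kind = stepwise
feed.Si = 600
feed.stop_mass = 100
feed.steps_file = stepwise_1L_steps.csv
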