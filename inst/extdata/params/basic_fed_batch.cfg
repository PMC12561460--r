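# Basic model, batch + fed-batch reference estimates
q_S_max = 1.62
q_m = 0.04
q_Ac_max = 0.42
Y_XS_em = 0.42
Y_XA = 0.37
Y_OS = 1.07
Y_OA = 1.07
Y_AS = 0.67
K_S = 0.05
K_qSox = 30.20
K_A = 0.66
Ki_A_S = 2.64
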