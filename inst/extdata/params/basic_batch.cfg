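# Basic model, batch-phase reference estimates
q_S_max = 1.02
q_m = 0.04
q_Ac_max = 0.70
Y_XS_em = 0.83
Y_XA = 0.27
Y_OS = 1.07
Y_OA = 1.07
Y_AS = 0.67
K_S = 0.05
K_qSox = 42.16
K_A = 0.81
Ki_A_S = 0.28
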