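# One-fraction model, batch-phase reference estimates
q_S_max = 0.46
q_YEFA_max = 1.99
q_m = 0.04
q_Ac_max = 0.89
Y_XS_em = 0.33
Y_X_YEFA = 0.41
Y_XA = 0.28
Y_OS = 1.07
Y_OA = 1.07
Y_AS = 0.67
Y_O_YE = 1.16
K_S = 0.05
K_YEFA = 0.07
K_qSox = 16.20
K_A = 1.00
Ki_A_S = 0.05
Ki_YEFA_qSox = 1.13
d_YE_AB = 1
d_YE_BC = 1
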