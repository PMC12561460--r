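# Three-fraction model, batch + fed-batch reference estimates
q_S_max = 0.71
q_YEFA_max = 1.60
q_YEFB_max = 0.31
q_m = 0.04
q_Ac_max = 0.64
Y_XS_em = 0.43
Y_X_YEFA = 0.53
Y_X_YEFB = 0.21
Y_XA = 0.42
Y_OS = 1.07
Y_OA = 1.07
Y_AS = 0.67
Y_O_YE = 1.16
K_S = 0.05
K_YEFA = 0.05
K_YEFB = 0.10
K_qSox = 34.49
K_A = 0.86
Ki_YEFB_qSox = 49.34
Ki_A_S = 0.008
Ki_YEFA_qSox = 0.01
d_YE_AB = 0.21
d_YE_BC = 0.54
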