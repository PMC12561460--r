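# Two-fraction model, batch-phase reference estimates
q_S_max = 0.55
q_YEFA_max = 1.71
q_YEFB_max = 0.23
q_m = 0.04
q_Ac_max = 0.37
Y_XS_em = 0.42
Y_X_YEFA = 0.52
Y_X_YEFB = 0.14
Y_XA = 0.30
Y_OS = 1.07
Y_OA = 1.07
Y_AS = 0.67
Y_O_YE = 1.16
K_S = 0.05
K_YEFA = 0.77
K_YEFB = 1.28
K_qSox = 65.21
K_A = 0.25
Ki_YEFB_qSox = 25.88
Ki_A_S = 2.33
Ki_YEFA_qSox = 0.49
d_YE_AB = 0.61
d_YE_BC = 1
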