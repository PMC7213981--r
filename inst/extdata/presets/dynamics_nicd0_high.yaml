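# Signal-duration dynamics preset (high baseline abundance)
NICD0: 20000
Gamma_up: 0.008333333333333333
Gamma_p: 0.125
slope_normalized: -0.0294
N_e: 5.4
k_alpha: 1
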