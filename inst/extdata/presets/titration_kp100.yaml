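# Steady-state titration over synthetic site numbers
NICD0: 2000
Gamma_up: 0.008333333333333333
Gamma_p: 0.125
k_p: 1.0
k_alpha: 1
N_e: 5.4
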