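# Phosphorylation-rate grid over plausible baseline abundances
# (1e2-1e4 molecules/nucleus) and unphosphorylated half-lives (0.5-16 h)
Gamma_p: 0.125
slope_normalized: -0.0294
N_e: 5.4
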