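# T-type (low-voltage-activated) calcium channel gating parameters,
# CA1 pyramidal formulation (Jaffe et al. 1994 rate functions as used in the
# Poirazi et al. 2003 CA1 model). Voltage in mV, rates in ms^-1.
#   alpha_m(v) = am_a * (am_v0 - v) / (exp((am_v0 - v)/am_k) - 1)
#   beta_m(v)  = bm_a * exp(-v / bm_k)
#   alpha_h(v) = ah_a * exp(-v / ah_k)
#   beta_h(v)  = 1 / (exp((bh_v0 - v)/bh_k) + 1)
param	value
am_a	0.2
am_v0	19.26
am_k	10.0
bm_a	0.009
bm_k	22.03
ah_a	1e-6
ah_k	16.26
bh_v0	29.79
bh_k	10.0
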