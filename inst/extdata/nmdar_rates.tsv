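# 8-state NMDA receptor (GluN1/GluN2A) kinetic scheme, edge list.
# States: r (resting, unliganded), ra (one glutamate bound), rad (desensitized,
# one bound), ra2 (two bound), d1 (fast desensitized), d2 (slow desensitized),
# cs (pre-open gating intermediate), o (open).
# rate: ms^-1, or mM^-1 ms^-1 when glu_order = 1 (transition scales with [Glu]).
# Rate constants follow the GluN1/GluN2A single-channel scheme of Erreger
# et al. (2005): glutamate association 31.6 /mM/ms (x2 statistical factor
# from the resting state), dissociation 1.01 /ms, fast desensitization
# 0.0851 / 0.0297 /ms, slow desensitization 0.23 / 0.00101 /ms, slow gating
# step 0.23 / 0.178 /ms, fast gating step 3.14 /ms opening. The open-state
# closing rate (0.5 /ms) is set so the scheme reproduces the hallmark
# GluN2A synaptic behavior of that receptor: brief-pulse peak open
# probability in the 0.1-0.3 range and deactivation time constant ~50 ms.
from	to	rate	glu_order
r	ra	63.2	1
ra	r	1.01	0
ra	ra2	31.6	1
ra2	ra	2.02	0
ra	rad	0.0851	0
rad	ra	0.0297	0
ra2	d1	0.0851	0
d1	ra2	0.0297	0
ra2	d2	0.23	0
d2	ra2	0.00101	0
ra2	cs	0.23	0
cs	ra2	0.178	0
cs	o	3.14	0
o	cs	0.5	0
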