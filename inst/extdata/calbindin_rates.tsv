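# Calbindin-D28k per-site binding rates (two independent site classes, two
# sites each), as used in the Bartol et al. spine calcium model (rates from
# Naegerl et al. 2000). Units: kon mM^-1 ms^-1, koff ms^-1.
site_class	n_sites	kon	koff
high	2	11	0.0026
medium	2	87	0.0358
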