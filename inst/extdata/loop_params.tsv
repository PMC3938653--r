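param	value	description
hairpin_base	5.40	penalty (kcal/mol) for a 3-nt hairpin loop
bulge_base	3.80	penalty for a 1-nt bulge loop
internal_base	1.70	penalty for a 2-nt (1x1) internal loop
loop_log_coef	1.0785	coefficient of the logarithmic loop-size extrapolation (1.75*R*T at 310 K)
asym_coef	0.48	internal-loop asymmetry penalty per unpaired-nt difference
asym_max	3.00	cap on the asymmetry penalty
ml_a	3.40	multiloop closing penalty
ml_b	0.40	multiloop per-branch penalty (closing helix included)
ml_c	0.00	multiloop per-unpaired-nt penalty
max_loop	30	largest combined unpaired size of a bulge/internal loop
min_hairpin	3	minimum unpaired nucleotides in a hairpin loop
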