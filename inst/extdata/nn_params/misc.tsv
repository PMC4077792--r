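# Miscellaneous nearest-neighbor model terms (kcal/mol unless stated).
# ml_*: affine multibranch-loop model  a + b * branches + c * unpaired.
# terminal_au: per helix end closed by AU/UA/GU/UG.
# ninio: internal-loop asymmetry penalty per unit |n1 - n2|, capped at ninio_max.
# lxc: logarithmic loop-length extrapolation coefficient (1.75 * RT at 37 C).
# max_loop: largest bulge/internal loop considered by the fold engine (nt).
# min_hairpin: minimum unpaired bases in a hairpin loop.
param	value
ml_close	9.3
ml_branch	-0.9
ml_unpaired	0.0
terminal_au	0.5
ninio	0.6
ninio_max	3.0
lxc	1.079
max_loop	30
min_hairpin	3
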