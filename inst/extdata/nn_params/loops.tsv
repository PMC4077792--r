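# Loop initiation free energies at 37 C, kcal/mol, by number of unpaired bases.
# NA = size not possible for that loop type. Sizes beyond the last row are
# extrapolated as dG(n) = dG(n_max) + lxc * ln(n / n_max) (see misc.tsv).
size	hairpin	bulge	internal
1	NA	3.8	NA
2	NA	2.8	1.5
3	5.7	3.2	1.6
4	5.6	3.6	1.7
5	5.6	4.0	1.8
6	5.4	4.4	2.0
7	5.9	4.6	2.2
8	5.6	4.7	2.3
9	6.4	4.8	2.4
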