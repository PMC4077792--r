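# spacerfold

Secondary-structure constraint analysis of nuclear ribosomal internal
transcribed spacers (ITS1/ITS2).

The ITS spacers are the workhorse nuclear markers of plant molecular
systematics, usually analysed under the assumption that they evolve
neutrally. They are, however, excised from the rRNA primary transcript by
processing machinery that reads their *secondary structure*. `spacerfold`
implements the complete analysis for asking whether spacer sequences are
under selective constraint to preserve that structure, for anyone who wants
to run the test on their own sequence sets:

1. **Fold** — minimum-free-energy (MFE) secondary structure under a
   nearest-neighbor thermodynamic model (Zuker-style dynamic programming,
   energies in kcal/mol at 37 °C), plus enumeration of all distinct
   suboptimal structures within a percentage band of the MFE
   (Wuchty-style best-first search with an mfold-style distinctness
   window).
2. **Census** — decompose each structure into helices and loops and count
   paired bases, hairpins (exterior-anchored substructures with ≥ 4 base
   pairs; branched substructures count once) and stems.
3. **Null model** — random sequences matched one-to-one in length and in
   pooled G+C content to a reference set.
4. **Statistics** — two-way ANOVA (class × dataset half, type-II sums of
   squares) of MFE and ensemble size between real and random sequences;
   under constraint the real class shows `E_MFE(real) < E_MFE(random)` with
   the energy/count ratio unchanged.
5. **Phylogeny** — map per-taxon hairpin counts onto a user-supplied newick
   tree and reconstruct ancestral counts by Fitch–Hartigan parsimony
   (polytomies and ambiguous tips such as `6/7` handled natively).
6. **Synthetic data** — scaffold sequences with designed stem–loop ground
   truth and matched random partners, so the whole pipeline is testable
   without any downloads.

## Worked example

Twenty synthetic sequences — ten structure-constrained ITS-like scaffolds
(half ITS1-like ≈ 260 nt, half ITS2-like ≈ 185 nt), ten random partners
matched in length and pooled GC (54.9%):

```r
library(spacerfold)

ds      <- its_like_dataset(n_per_class = 10, seed = 2024)
model   <- energy_model()
census  <- structure_census(ds$records, model, max_count = 30)
metrics <- merge(census, ds$truth[c("seq_id", "class", "half")], by = "seq_id")

summarize_metrics(metrics, responses = c("mfe_energy", "n_hairpins"), by = "class")
#>   group     metric  n   mean median   min   max
#>  RANDOM mfe_energy 10 -52.00  -51.5 -76.0 -34.1
#>   SYNTH mfe_energy 10 -60.38  -58.1 -87.4 -34.1
#>  RANDOM n_hairpins 10   2.60    2.0   1.0   5.0
#>   SYNTH n_hairpins 10   3.30    3.5   1.0   6.0

anova_two_way(metrics, "mfe_energy")
#> two-way ANOVA on mfe_energy
#>         term    sumsq df         F            p
#>        class  351.122  1  7.650467 1.377472e-02
#>         half 4205.000  1 91.621183 5.031536e-08
#>  interaction   59.168  1  1.289190 2.729203e-01
#>    residuals  734.328 16        NA           NA
```

The constrained class folds about 8 kcal/mol lower than its matched random
partner (class effect p ≈ 0.01 at this small desk scale; the package's test
suite runs the same contrast at 50 sequences per class, where
p < 10⁻⁶). The `half` effect simply reflects that longer ITS1-like
sequences fold lower than shorter ITS2-like ones — which is exactly why the
null is length-matched.

A single sequence, end to end:

```r
st <- fold_mfe(ds$records[1, ], model)
st
#> secondary structure of h1_synth_001 (273 nt): 72 pairs, energy -78.7 kcal/mol
pairs_to_dotbracket(st$pairs, st$length)
count_hairpins(build_element_tree(st))
enumerate_suboptimal(ds$records[1, ], model, max_pct_diff = 10, max_count = 50)
```

Structures read and write as Vienna dot-bracket and CT files
(`write_dotbracket()`, `write_ct()`), sequences as FASTA (`read_fasta()`
degaps alignments and maps T→U). A command-line front end wraps the same
stages:

```sh
exec/spacerfold simulate --out run/sim --n 50 --k 5 --seed 1
exec/spacerfold fold     --fasta run/sim/dataset.fasta --out run/fold
exec/spacerfold census   --structures run/fold
exec/spacerfold phylo    --newick tree.nwk --tip-states counts.tsv --out run/phy
```

Every command writes a JSON manifest (arguments, seed, package version)
next to its outputs.

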