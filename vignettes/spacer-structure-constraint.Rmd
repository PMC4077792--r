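---
title: "Testing secondary-structure constraint in ITS spacers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing secondary-structure constraint in ITS spacers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spacerfold)
```

## The question

The internal transcribed spacers ITS1 and ITS2 of the nuclear rRNA cistron
are excised from the primary transcript by structure-guided processing, yet
they are routinely treated as neutrally evolving markers in phylogenetics.
If the spacers are in fact under selective constraint to maintain a working
secondary structure, two signatures are expected relative to unconstrained
sequence of the same composition:

* the folded minimum free energy (MFE) should be substantially lower
  (more negative), and
* the number of plausible alternative structures near the MFE should be
  smaller — a constrained sequence has one dominant fold, a random sequence
  has many interchangeable mediocre ones.

`spacerfold` implements the full pipeline for this test: fold, enumerate
near-optimal alternatives, census the fold topology, generate a
composition-matched random null, compare the classes with a two-way ANOVA,
and map hairpin counts onto a phylogeny with parsimony.

## The thermodynamic model

Folding uses the standard nearest-neighbor loop decomposition: a structure's
free energy is the sum over its loops of

* **stacking terms** for adjacent base pairs within helices (6×6 table over
  AU, UA, GC, CG, GU, UG; Watson–Crick stacks are all stabilizing),
* **loop initiation penalties** for hairpin, bulge and internal loops by
  length, extrapolated as `dG(n) = dG(n_max) + 1.079 · ln(n / n_max)`
  beyond the tabulated sizes,
* an **affine multibranch term** `a + b · branches + c · unpaired`
  (defaults 9.3, −0.9, 0.0 kcal/mol),
* a **terminal AU/GU penalty** (0.5 kcal/mol) at every helix end not closed
  by a G–C pair, and
* an **asymmetry (Ninio) penalty** for internal loops, 0.6 kcal/mol per
  unit of asymmetry capped at 3.0.

The parameter values are a published Turner-style 37 °C set rounded to
0.1 kcal/mol, shipped as three plain-text tables under
`inst/extdata/nn_params/` (`stack.tsv`, `loops.tsv`, `misc.tsv`) and fully
swappable via `energy_model(param_dir = ...)`. All folding arithmetic is
done in integer tenths of kcal/mol, so dynamic-programming results are exact
and platform-independent.

Deliberate simplifications, and what they cost: dangling ends, coaxial
stacking, terminal-mismatch bonuses and special small-loop tables are
omitted. These are second-order refinements for the *contrast* between
sequence classes, but they all stabilize real folds, so absolute energies
from this engine are systematically **less negative** (by roughly 15–25% on
~200–290 nt inputs) than those from full-featured implementations of the
Turner model. Comparisons within this package — ITS-like versus matched
random — are unaffected, because both classes are folded under the same
model; published absolute energies should only be expected to match this
engine's output to within that offset.

Minimum hairpin loop is 3 unpaired bases; GU wobble pairs are allowed;
lonely pairs are permitted (they simply earn no stacking term); bulge and
internal loops are capped at 30 unpaired bases (the standard search cap);
pseudoknots are out of model.

## Folding and suboptimal enumeration

MFE folding fills the usual Zuker-style matrices (paired `C`, multibranch
components `M`/`M1`, exterior `F`). Suboptimal enumeration does not re-fold:
both jobs are served by one best-first search over an *unambiguous*
production grammar on those matrices, in which each partial structure
carries an exact lower bound on every completion. Structures therefore pop
off the priority queue in non-decreasing energy order, the first completion
is the MFE structure, and every distinct structure is generated exactly
once. Ties are broken by fixed insertion order, making results fully
deterministic.

`enumerate_suboptimal()` keeps structures within `max_pct_diff` percent of
the MFE (default 10%). With `window >= 1` a newly generated structure is
accepted only if it contains at least one base pair at Chebyshev distance
`>= window` from every pair of every previously accepted structure — the
distinctness criterion familiar from mfold-class programs (default: 3 for
sequences under 200 nt, else 5). `window = 0` disables the novelty filter
entirely, so the ensemble is the complete set of distinct structures in the
band; this is what the exhaustive oracle tests use on short sequences. We
define `window = 0` as "no filter" rather than "distance ≥ 0" because the
latter would reject structures whose pairs are all shared with previously
accepted ones (e.g. sub-structures), and the band enumeration would no
longer be complete.

The search is exact within the band but resource-bounded: it stops after
`max_count` accepted structures (default 50), `max_gen` node expansions, or
`max_queue` frontier states, and flags truncation in the result. A 10% band
around the MFE of a 250-nt sequence contains astronomically many
structures, so *some* bound is inherent to the method; ensemble sizes are
reported exactly as mfold-style tools report them — counts capped at the
requested maximum under the requested window.

## Topology census

`build_element_tree()` decomposes a structure uniquely into helices (maximal
runs of stacked pairs; a bulge or internal loop terminates a helix) and the
loops they close, rooted at the exterior loop. The census then scores each
*exterior-anchored candidate* — the substructure hanging off each child
helix of the exterior loop:

* a candidate counts as **one hairpin** if it contains at least `min_bonds`
  base pairs in total (default 4, "four bonds = eight nucleotides") and
  closes at least one loop. Single and branched candidates count once, no
  matter how deeply the nested structure sits.
* `bond_rule = "anchor"` switches the bond threshold from the whole
  substructure to the anchor helix alone (the alternative reading of the
  four-bond rule).
* a finite `max_sep` switches to a stricter reading in which the anchor
  helix must reach a hairpin loop through at most `max_sep` intervening
  loop elements; candidates that fail are counted as **stems** ("structures
  that do not form immediate loops"). This is not the default because folded
  arms of realistic 180–290 nt sequences routinely carry two or more
  interior loops between the exterior anchor and the first hairpin loop, and
  the strict rule would reclassify most genuine arms as stems. Under the
  default census `count_stems()` is zero by construction.

Hairpin counts depend only on pairing topology, never on sequence identity.

## The matched random null

`generate_matched()` draws, for each requested length, a sequence of exactly
that length whose G+C count is fixed at `round(length × gc_target)`;
G/C and A/U split their allocations uniformly at random. Matching is exact
per sequence by count, not merely in expectation, which removes composition
as a nuisance-variance axis: pooled GC of the null set deviates from the
target only through per-sequence rounding, bounded by
`0.5 · n_sequences / total_length`. `match_from_reference()` copies the
reference lengths one-to-one and targets the references' pooled GC — the
"overall" reading of composition matching; per-sequence GC matching is a
straightforward variation but is not the default. Randomization is
mononucleotide; dinucleotide-preserving shuffles are out of scope.

## Class comparison

`anova_two_way()` fits `response ~ class * half` by least squares and
reports type-II sums of squares (via `car::Anova`) with exact F p-values.
The two factors are the only two in the design: sequence class (real vs
random) and dataset half (ITS1-matched vs ITS2-matched). Zero-variance
responses are flagged and reported as `NA` rather than fitted. The
energy-to-count ratio test divides each sequence's MFE by its ensemble size
and runs the same machinery; under a coupled-scaling null (both metrics
shift together between classes) the ratio shows no class effect even when
each raw metric separates the classes decisively —
`ratio_null_simulation()` generates exactly that null, with class-dependent
ensemble sizes and energies tied to them through a shared per-structure
energy plus small multiplicative noise. A strictly noise-free coupling would
make the ratio constant and the ANOVA degenerate, which is why the
simulation carries the noise term. No multiple-testing correction is
applied.

## Ancestral hairpin counts

`fitch_root_states()` implements the Fitch–Hartigan parsimony pass for
unordered characters on rooted, possibly multifurcating trees: each node's
state set is the set of states attaining maximal coverage among its
children's sets, and the score grows by the number of uncovered children.
For binary nodes this reduces to classic Fitch intersection/union. Tips with
no observation are pruned before the pass (they constrain nothing); tips
with several observed counts (`"6/7"`) enter as ambiguous state sets,
handled natively by the set operations. The tree is always user input —
this package never infers topology.

## Synthetic data: what it does and does not emulate

`make_structured()` builds ITS-like sequences with known ground truth:
`k` stem–loop units (stem, loop, reverse-complement stem) separated by
spacers. Design choices that matter:

* the G+C budget is exactly `round(L × gc_target)` and is allocated
  hierarchically — stems first (capped at 75% G–C pairs, because all-G/C
  stems are unavoidably complementary to one another and zip across units),
  then loops, then spacers — so the segments whose pairing potential
  matters most stay as A/U-rich as the target permits;
* unpaired segments are A/U-rich (75% in aggregate) and A-heavy within the
  A/U mass (70/30), since scarce U suppresses spurious A–U helices between
  spacers;
* every segment, stems included, is rearranged (random restarts, then local
  swaps) until none of its 4-mers can pair — Watson–Crick or wobble — with
  anything already placed.

Under the package defaults relevant to testing (3 units, stem 8, loop 5,
spacer 10), the MFE fold recovers the designed hairpin count in at least
90% of seeds, which is what makes the downstream census testable without
real data. `its_like_dataset()` assembles the two-factor study design:
half the structured sequences ITS1-like (6 units, ≈260 nt), half ITS2-like
(4 units, ≈185 nt), each with a length- and GC-matched random partner
(pooled target 54.9%), spacer lengths jittered ±3 nt per sequence.

These scaffolds emulate the *statistical* structure of the real contrast —
designed low-energy folds versus matched random sequence at identical
composition — not ITS biology: there is no sequence homology, no
conservation gradient along the spacer, no indel process, and no
compensatory-substitution history on a tree. Passing tests demonstrate that
the pipeline detects structural constraint where it exists and not where it
does not; they say nothing about any particular real taxon.

## Numerical and interface choices

* All coordinates are 1-based inclusive throughout the R API, matching both
  R convention and the CT file convention on disk.
* Energies are reported to 0.1 kcal/mol; internal arithmetic is integer
  tenths, so equality tests in the suite are exact.
* Traceback/tie-breaks: fixed case order and queue insertion order;
  re-running any fold or enumeration reproduces results bit-exactly.
* Degenerate inputs: sequences shorter than 5 nt fold to the open chain at
  0.0 kcal/mol; empty FASTA input yields an empty table with a warning;
  ambiguity codes (N, R, Y, …) are retained in sequences but never pair.
* Problem sizes in the shipped tests were chosen for a single-CPU desk run:
  exhaustive-oracle folds up to 18 nt (hundreds of sequences), band
  enumeration oracles up to 14 nt, ANOVA calibration with 1000 null
  replicates, a 50-vs-50 synthetic study for the headline contrast.

## Known limitations

* Absolute energies carry the documented offset against full Turner
  implementations; only within-model contrasts are calibrated.
* Ensemble sizes depend on the enumeration settings (band width, window,
  cap), which published studies rarely state; treat absolute counts as
  qualitative and contrasts as the meaningful output.
* The stem/hairpin split beyond the default reading is heuristic; the
  strict `max_sep` variant is provided for sensitivity analysis, not as a
  biological claim.
* Parsimony mapping assumes the supplied topology; uncertainty in the tree
  is not propagated.
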