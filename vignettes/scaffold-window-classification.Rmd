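---
title: "Scaffold-window classification: model, tuning and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scaffold-window classification: model, tuning and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scaffmatch)
```

## The model

`scaffmatch` classifies a query molecule as an endogenous biochemical
or a synthetic compound by exact structure containment against a list
of biochemical *scaffolds*. Two structures match when the smaller is an
exact substructure of the larger: an injective atom mapping preserving
element symbol and formal charge, carrying every bond onto a bond of
the same type (single, double, triple, aromatic). A match is scored by
the heavy-atom-count ratio

$$Sc = \frac{AC(\text{smaller})}{AC(\text{larger})} \in (0, 1],$$

which is 1 exactly when the two structures have equal atom counts.

The key efficiency device is the *scaffold window*. For a candidate
with $AC$ heavy atoms and thresholds $subThr, superThr \in (0, 1]$,

$$minAC = \lfloor AC \cdot subThr \rfloor, \qquad
  maxAC = \lceil AC / superThr \rceil,$$

and only scaffolds with atom counts in $[minAC, maxAC]$ are searched:
any substructure match from a scaffold smaller than $minAC$, or
superstructure match from one larger than $maxAC$, would necessarily
score below its threshold. Within the window, scaffolds are visited in
order of $|AC(s) - AC|$, ties going to the larger count. Because the
score is a monotone function of the atom-count distance on each side,
the first match encountered is the best-scoring match in the window,
and the search stops there.

Four decision rules use this machinery. SSF declares the candidate
biological at the first match. SSSF finds the best substructure score
$Sc_{sub}$ and best superstructure score $Sc_{super}$ (0 when a
direction has no match; an identical scaffold counts as a substructure
match, contributing 1 to that direction only) and declares biological
iff $Sc_{sub} + Sc_{super} \ge sumThr$. SSB and SSSB are the same rules
with independent thresholds per atom-count bin.

## Structure perception and matching

Canonicalization, aromaticity perception and hydrogen handling are
delegated to Open Babel (via ChemmineOB): every input record — SMILES
or SDF — is converted to canonical SMILES on entry, so Kekulé and
aromatic notations of the same ring, and any permutation of the input
atom order, yield one structure. Atom and bond tables are read from
Open Babel's MOL2 output, which is the only interchange format in the
toolchain that carries the aromatic bond perception explicitly (MDL
SDF is written kekulized); formal charges come from the `M  CHG`
property lines of the SDF output. Atom counts are heavy-atom counts by
default (`atom_count(m, "all")` includes hydrogens), since SMILES
hydrogens are implicit and a count must not depend on notation.

Containment itself is a VF2 subgraph isomorphism (igraph) on a
*subdivided* coloured graph: one vertex per atom, coloured by element
and formal charge, plus one vertex per bond, coloured by bond order,
joined to its endpoints. In the subdivided form atoms are never
adjacent to atoms, so induced and non-induced embeddings coincide, and
VF2 computes exactly the required monomorphism — extra bonds of the
larger molecule between mapped atoms (e.g. a chain embedding into a
ring) do not block a match. The test suite cross-checks this path
against an independent brute-force injective-mapping enumerator on
hundreds of random labelled graphs.

Stereochemistry is ignored throughout: matching is two-dimensional by
design. Identical structures are reported as a substructure match with
score 1.

## Tunable parameters

| parameter | meaning | range | default used in examples |
|---|---|---|---|
| `sub_thr` | substructure threshold; lower bound on `Sc` for scaffold-in-candidate matches | (0, 1] | 0.5 |
| `super_thr` | superstructure threshold; lower bound on `Sc` for candidate-in-scaffold matches | (0, 1] | 0.5–0.51 |
| `sum_thr` | cutoff on `Sc_sub + Sc_super` (SSSF/SSSB only) | (0, 2] | 1.0–1.2 |
| bins | atom-count partition for SSB/SSSB | — | five equal-width bins of [4, 53] |

The five default bins (4–13, 14–23, 24–33, 34–43, 44–53) are the
equal-width partition of the candidate range; the underlying reports
never state a specific partition, so the scheme is exposed as
configuration (`bin_scheme()`) and echoed in output headers.
`min_atom_count()` clamps `minAC` to at least 1 so tiny candidates with
small thresholds never produce a zero bound.

## Threshold tuning and evaluation

`run_nested_cv()` estimates accuracy while tuning thresholds. Each
repeat: a stratified 2-fold outer split (stratification by class and
atom-count bin); on each outer-training half a 5-fold inner CV, where
every inner fold is evaluated with the scaffold list restricted to the
biological training compounds *outside* that fold, and the threshold
where sensitivity equals specificity is recorded; the five cutoffs are
averaged and applied to the outer test half, whose biological members
are likewise excluded from the scaffold list. This leakage guard is
asserted structurally on every fold. Confusion counts are pooled over
the two outer folds, giving one `SENS`/`SPEC`/`MCC` triple per repeat;
the report shows means and *sample* standard deviations (n − 1) across
repeats.

The sensitivity-equals-specificity rule is stated for a single scalar
cutoff, but the first-match rules have two thresholds. They are tuned
by grid search over $(subThr, superThr) \in \{0.05, \dots, 1.00\}^2$
(step 0.05), minimizing $|SENS - SPEC|$ with ties broken by larger MCC,
then larger `sub_thr` (smaller windows, faster searches), then larger
`super_thr` for determinism. For the sum-score rules the pair is fixed
the same way and `sum_thr` is then tuned on the observed sum-score grid
(`tune_cutoff()`: minimize $|SENS - SPEC|$, ties by MCC then smaller
cutoff). The binned methods repeat the tuning per bin, inheriting the
global tuning when a fold's bin lacks one of the classes. These
resolutions of the underspecified two-parameter case are package design
choices.

Degenerate cases are handled explicitly: an MCC denominator of zero is
reported as 0 with a flag; a score distribution with a single unique
value returns that value from `tune_cutoff()` with a degeneracy flag.

`run_loocv()` audits a scaffold list: each in-range scaffold is removed
from the index, classified against the remaining ones, and restored;
scaffolds above the evaluation range stay in the index throughout and
participate as superstructure partners only.

## The synthetic data generator

`make_labeled_dataset()` emulates the structure of a curated training
setup without any database download. Scaffolds are distinct members of
four nested chain-growing families (alkanes, primary alcohols,
carboxylic acids, branched ethers), in which the *n*-atom member is
provably a substructure of every larger member. Biological candidates
strictly contain a randomly chosen scaffold (same family, 1–4 more
atoms) with probability `containment_fraction`, otherwise they are
structural copies of a scaffold. Synthetic candidates are
alternating-single/triple carbon chains: they contain no two
consecutive single C–C bonds, so no saturated scaffold of four or more
atoms can embed in them, and their triple bonds embed in no family
member — non-containment is a theorem of the construction, not a
sampling accident, and is nevertheless re-certified by the matcher at
generation time. Atom-count histograms of the two candidate classes
are matched exactly when the class sizes are equal.

Defaults — 24 scaffolds spanning 4–30 atoms, 32 biological and 32
synthetic candidates, `containment_fraction = 1` — were chosen once as
a desk-scale emulation: large enough for the 2-fold/5-fold nested CV
structure to be populated in every stratum, small enough that a full
15-repeat experiment (including the pairwise match table) runs in
seconds. All randomness flows from the single integer seed through a
scoped RNG, so identical specs produce byte-identical SMILES files.

What the generator does *not* emulate: real chemical diversity, ring
systems beyond benzene-like test cases, charge chemistry, or the
near-miss structures that make real synthetic/biochemical
discrimination hard. Passing tests on these fixtures demonstrate the
*contracts* — containment, windowing, ordering, early termination,
leakage-guarded tuning — not field accuracy on database chemistry;
accuracy on real collections depends on the scaffold list supplied by
the user.

## Numerical and degenerate-input choices

* Window bounds use `floor` for `minAC` (the bracket choice consistent
  with the 9-atom worked example: $\lfloor 9 \times 0.5 \rfloor = 4$)
  and `ceiling` for `maxAC`.
* Ties at equal atom-count distance go to the larger count (the
  superstructure side), matching the documented 9, 10, 8 search order;
  within one atom-count bucket, stable input order is kept — the
  underlying reports are silent here, and this is recorded as a choice,
  not inferred intent.
* Equal-count non-identical scaffolds can match (a path embeds in a
  ring of the same size) and then score 1; score 1 therefore implies
  equal atom counts, identity only up to such embeddings.
* Curation applies its six rules in a fixed order with first-failure
  attribution; the charge rule keys on *per-atom* formal charge (a
  zwitterion is charged even when its net charge is zero), with the
  quaternary-amine and sulfonium exceptions checked per charged atom.
* Polymer detection is marker-based only (Sgroup `SRU` lines, wildcard
  atoms in the source record); no heuristic repeat detection.
* An empty scaffold window is a valid result (nonbiological at zero
  comparisons); an atom count outside a bin scheme yields an explicit
  `out_of_range` status rather than a label.

## Problem sizes in the shipped tests

The test suite and acceptance checks run entirely on generated data:
matcher/oracle equivalence on 500+ random graphs of up to 8 heavy
atoms; the best-first guarantee on 200+ randomized windows; ground
truth recovery and a 15-repeat permutation-null control on the default
64-candidate fixture; leave-one-out contracts on 6–12 scaffold lists.
These sizes were chosen so the whole suite completes in about a minute
while still exercising every contract; all of them scale up linearly
with the generator parameters if heavier validation is wanted.

## Known limitations

* Aromaticity follows Open Babel's perception model; toolkits with a
  different aromaticity model may disagree on borderline rings.
* The matcher treats aromatic and Kekulé bonds as distinct types after
  perception; an aromatic ring never matches a deliberately localized
  single/double pattern that Open Babel does not perceive as aromatic.
* `match_table()` is quadratic in the dataset sizes; it is intended for
  the CV tuner at training scale, not for screening millions of
  candidates (screening uses the windowed early-terminating scan).
* The permutation-null control draws a fresh label permutation per
  repeat; a single fixed permutation would leave a shared sampling bias
  of order $1/\sqrt{n}$ in the mean MCC across repeats.
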