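---
title: "Scoring coarse-grained RNA 3D models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring coarse-grained RNA 3D models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rnascore)
```

## The representation

Everything in this package operates on a one-point-per-nucleotide
representation of RNA: the C1′ ribose carbon, a natural single-atom proxy
because it sits between the backbone and the base. A structure is a
`coord_chain` — an ordered tibble of residues with a number, a one-letter
code and an optional coordinate. "Optional" matters: experimental
structures routinely leave residues unsolved, and every metric here is
defined with respect to the *solved* reference length `Lref`. Residue
order is file order; numbering gaps and insertion codes are carried
through untouched, because crystal-structure numbering is not an index.

## TM-score, d0 and the three metric modes

The template-modeling score of a model against a reference, for a fixed
residue alignment, is

$$\mathrm{TM} \;=\; \max_{R,\,t}\; \frac{1}{L_\mathrm{ref}}
  \sum_{i=1}^{L_\mathrm{align}} \frac{1}{1 + (d_i/d_0)^2},$$

with the maximum taken over rigid superpositions $(R, t)$ of the model,
$d_i$ the post-superposition distance of the $i$-th aligned C1′ pair in
Å, and $d_0$ the RNA-specific distance scale

$$d_0 = 0.6\,(L_\mathrm{ref} - 0.5)^{1/2} - 2.5 \quad (L_\mathrm{ref} \ge 30),$$

with fixed values 0.3, 0.4, 0.5, 0.6, 0.7 Å for references shorter than
12, of 12–15, 16–19, 20–23 and 24–29 solved residues (`d0_of()`). The
normalization makes values comparable across lengths, with one widely
used consequence baked into `is_correct_fold()`: a score above 0.45
indicates a shared global fold. Because the sum is divided by the
reference's solved length, the score is asymmetric — `tm_align(a, b)` and
`tm_align(b, a)` answer different questions, and all leaderboard code
normalizes by the experimental reference.

The three user-facing metrics differ only in how the alignment arises:

* **`tm_score()`** (sequence-dependent): residue *i* of the model pairs
  with residue *i* of the reference, restricted to positions solved in
  both. This penalizes numbering mistakes.
* **`tm_align()`** (sequence-independent): the alignment itself is
  optimized, using chain order only; nucleotide identity and numbering
  are ignored entirely.
* **`rmsd_c1()`**: plain Kabsch RMSD over the same-rank solved pairing —
  the classical, outlier-sensitive complement.

## Optimizing the superposition

The maximum over superpositions cannot be found by a single least-squares
fit: the TM functional rewards concentrating the fit on the
well-modelled core and ignoring outliers. `optimize_superposition()`
therefore distinguishes two regimes.

*Small pairings (≤ 10 pairs) are solved exactly.* Every candidate
superposition that matters is the Kabsch fit of some subset of pairs, so
the code enumerates all subsets of ≥ 3 pairs, fits each and scores all
pairs. At ≤ 10 pairs this is at most 968 fits — cheap, deterministic, and
free of heuristic failure modes.

*Larger pairings use fragment-seeded iterative refinement*, the standard
approach for this functional: seeds are Kabsch fits of contiguous
aligned fragments (lengths $L$, $L/2$, $L/4$, minimum 4, start offsets at
stride half the fragment length); from each seed the pairs within a
distance cutoff are re-fit and the TM over *all* pairs recorded, with the
cutoff starting at $d_0 + 1.5$ Å, shrinking by 0.5 Å whenever the kept
set stops changing, floored at 0.5 Å, for at most 30 iterations per
seed. At least three pairs are always kept (the three closest, if the
cutoff would keep fewer).

## The alignment search in `tm_align`

`tm_align()` jointly optimizes alignment and superposition. Starting
alignments are the gapless threadings at every offset. From each start
the search alternates: optimize the superposition over the current
alignment as above, then realign by global dynamic programming on the
score matrix $S_{ij} = 1/(1 + (d(m_i, r_j)/d_0)^2)$ with gap-open
penalty −0.6 and gap extension 0. Each evaluated superposition proposes
two realignments — the −0.6-gap alignment and a zero-gap alignment,
which is the TM-optimal monotone alignment for that superposition since
every matched pair contributes a positive term. Proposals feed a
work-stack with a global cap and a cache of alignments already
evaluated; the search stops when no new alignment appears. Among
equal-TM alignments the larger, then lexicographically smallest one wins,
making results reproducible to the bit.

Two design points deserve emphasis:

* **Tiny chains are handled exactly.** For chains of ≤ 8 solved residues
  each, threading-style searches are qualitatively wrong: the optimum is
  governed by isolated well-matching residue triples (any two
  near-congruent triangles superpose almost perfectly), which no
  threading seed can reach. Since the TM value is monotone under
  alignment inclusion — adding a pair adds a positive term, and the
  superposition family of a superset contains that of the subset — the
  global optimum is attained on an inclusion-maximal monotone alignment.
  The small-chain branch therefore enumerates the maximal monotone
  alignments and solves each exactly. The test suite verifies this
  branch against an independent brute-force oracle that enumerates
  *every* monotone alignment of ≥ 3 pairs and every superposition
  subset, without using the maximality argument.
* **For mid-sized chains (9–10 residues) every monotone 3-pair alignment
  is added to the start set**, retaining sensitivity to triple-governed
  optima where full enumeration is no longer the point.

Scores from this implementation may differ in detail from other
TM-align-family programs, whose exact heuristics are not specified by
their published descriptions; the contracts tested here are the ones
stated above (exactness on tiny chains, self-identity, rigid-motion
invariance, dominance over the sequence-forced mode, and the
$L_\mathrm{align}/L_\mathrm{ref}$ bound).

## Leaderboard aggregation

`per_target_score()` implements the best-of rule: a submission's five
models are each scored against every alternative ground-truth
conformation of the target, and the best value is kept (max for TM
metrics, min for RMSD). Unscorable model/conformation pairs (fewer than
three shared solved residues) are skipped; a target with no scorable
pair raises an unscorable error rather than fabricating a value.
`leaderboard_mean()` averages per group over present targets only;
missing entries are never imputed. `best_of_two()` combines a group's
two selected algorithms per target before averaging.

`zscores()` standardizes scores within each target in two passes:
pass one over all groups, pass two after removing groups with pass-one
$z < -2$, with the final z of **every** group — including the trimmed
ones — computed against the pass-two statistics. This keeps poor groups
comparable instead of dropping them. RMSD is negated before
standardization so larger z is uniformly better. Two conventions had to
be fixed where the procedure is usually left unstated: the standard
deviation uses the sample convention (n − 1), exposed as `sd_type`; and
a pass-two standard deviation of zero (all surviving scores equal) sets
every z for that target to 0.

`compare_groups()` runs a *paired* one-sided t-test on per-target
differences. Pairing is the defensible choice because both groups are
scored on identical targets whose difficulty varies over orders of
magnitude; an unpaired test would mostly measure target spread. No
multiple-testing correction is applied — callers comparing many pairs
should apply their own. With zero-variance differences the t statistic
degenerates and p is returned as 0, 1 or 0.5 by the sign of the mean.
Ranking (`rank_groups()`) is competition-style: ties share the minimum
rank, the next group skips ranks; direction is descending except for
RMSD.

## Ensemble selection

`select_ensemble()` reduces 15 candidate conformations (five each from
three source models) to five. The selection is seeded with two anchors —
Protenix conformation 2 and TBM conformation 1, which count toward the
five — and then grows greedily: each step scores every unselected
candidate as

$$\mathrm{score} = w_\mathrm{model}\,(w_\mathrm{div}\cdot\mathrm{diversity}
  - w_\mathrm{dist}\cdot\mathrm{distance\_to\_priors})$$

and adds the arg-max. Diversity is the mean pairwise Kabsch-aligned C1′
RMSD of the candidate to the *current* selection (recomputed every
step); distance-to-priors is the mean RMSD to the anchors. The model
reliability weights default to 0.75 (protenix), 0.15 (tbm), 0.10
(boltz). The balance weights $w_\mathrm{div}$ and $w_\mathrm{dist}$
default to 1.0 each and are exposed in `ensemble_config()`: the
structure of the rule — reliability-gated diversity minus drift — is the
contribution, not a particular tuning. Ties are broken by source order
then conformation index, so runs are reproducible. Tests verify each
greedy step against an exhaustive arg-max over the remaining candidates.

## The synthetic generator

`generate_chain()` produces three chain families: ideal helices (rise
2.8 Å, twist 32.7°, radius 9.4 Å — idealized A-form-like C1′ geometry;
package constants chosen for plausible inter-residue spacing, not
measured values), self-avoiding random coils (step 5.9 ± 0.5 Å,
3 Å clash distance — the C1′–C1′ virtual bond scale), and two-helix
chains joined at a configurable bend angle, which give targets with
genuinely distinct alternative conformations. `perturb_chain()` adds
iid Gaussian coordinate noise (Kabsch RMSD → σ√3 at large n). All
generators are pure functions of an explicit seed and never touch the
global RNG stream.

`make_fixture_suite()` assembles these into a complete on-disk
mini-competition: three targets (30-mer helix; 40-mer bent chain with
two ground-truth conformations at bend angles 70° and 110°; 25-mer
coil), three groups of five-model submissions at noise levels 0.5 Å
(near-native), 2 Å (intermediate) and independent coils (decoys), and a
15-candidate ensemble directory at source-specific noise levels
1.0/1.5/2.5 Å. The noise levels were fixed once, before any tests were
written against them, to span clearly separated accuracy regimes.

What the synthetic data does *not* emulate deserves equal emphasis: no
base pairing, no excluded-volume realism beyond the clash distance, no
experimental-error structure, no length/composition distribution of real
targets. Passing tests on this data demonstrates that the *rules* —
metrics, aggregation, selection — are implemented correctly, not that
any predictor is accurate on real RNA.

## Noise, the fold threshold, and an honest boundary case

A useful calibration fact falls out of the acceptance computations: for
40-mers ($d_0 = 1.271$ Å), per-coordinate Gaussian noise of σ = 1 Å
(RMSD ≈ 1.7 Å) produces optimized TM-align scores with mean ≈ 0.46 —
*straddling* the 0.45 fold threshold, with roughly half the replicates
on either side. One Ångström of coordinate noise per axis is, for a
40-nucleotide chain, exactly the boundary of what this metric calls the
same fold; at σ = 0.75 Å essentially every replicate is above the
threshold, at σ = 2 Å essentially none. The acceptance script reports
the measured rates rather than rounding them to a verdict. Random coils
against a helix sit far below the threshold (TM ≈ 0.1–0.2) in every
replicate.

## Problem sizes and determinism

The test and acceptance workloads use 200 chain pairs of 4–8 residues
for the enumeration-oracle comparison, 100 pairs for the metric axioms,
100 replicates for the threshold rates at n = 40, and 50 seeded
15-candidate instances for the greedy selector — sizes chosen so the
brute-force oracles stay exact while the full suite completes in a few
minutes. Every random quantity descends from an explicit seed;
leaderboard and ensemble outputs are byte-identical across reruns, which
the tests assert.

## Known limitations

* Single chains only: no multimer scoring, circular permutations, or
  ligand/protein context (deliberately out of scope for the C1′
  representation).
* The TM-align heuristic above ~10 residues is exact-in-spirit but not
  certified optimal; its guarantees are the tested invariants.
* The PDB writer emits minimal single-conformer C1′ records; mmCIF is
  not supported.
* One-sided paired t-tests assume approximately normal per-target
  differences; with 10–20 targets this is an approximation, and no
  multiplicity correction is applied internally.
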