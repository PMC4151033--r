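---
title: "Methods: stochastic local alignment of protein structures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stochastic local alignment of protein structures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gibbsmotif)
```

## The problem and the model

Given N protein structures reduced to their Cα traces, we seek N
substructures of w residues — one per structure, not necessarily contiguous
in sequence — whose mutual geometry is maximally conserved. The objective is
the average pairwise superposition RMSD: for every pair of structures the
selected residues are paired column-wise and superposed by an optimal proper
rigid-body transform, and the N(N−1)/2 RMSDs are averaged. The search space
is combinatorial and the problem class is NP-hard, so the package performs a
stochastic local search: a Markov chain Monte Carlo scheme in which one
structure's contribution is resampled at a time from a conditional
distribution proportional to a similarity score (Gibbs sampling). All
similarity scores are functions of *intra-structure* Cα distances only;
superposition enters only through the final ranking score and the seed
gate. This makes every sampling decision invariant under rigid transforms of
any input structure.

A search run iterates over amino-acid triplet fingerprints. The fingerprint
fixes which residue triples ("seeds": pairwise closer than the candidate
radius) are admissible in the bootstrap phase, which partitions the
enormous seed space into 20³ = 8000 tractable, restartable slices.

The three phases per fingerprint:

* **Bootstrap** samples an alignment of N seeds. The conditional weight of
  a candidate seed is the inverse of the product, over the other N−1
  structures, of `PairDist` — itself the product over the three residue
  pairs of the absolute difference of internal distances. The chain starts
  from one uniformly drawn candidate per structure and stops when the
  alignment has not changed for k(N, α) consecutive steps (see below).
* **Extension** adds one column per Gibbs sweep until width w, restricted
  to residues within the candidate radius of the current row. The weight
  multiplies a substitution-table symbol similarity with the inverse
  product of distance-profile discrepancies against the other structures'
  currently sampled candidates.
* **Refinement** deletes the worst column — the one maximising the
  `badness` sum of pairwise distance-profile discrepancies — and re-extends,
  `IterRefine` times. If re-extension finds no candidates the deleted
  column is restored and refinement ends early.

Alignments from all fingerprints are ranked by ascending average RMSD and
greedily filtered for redundancy.

## The stopping rule

The chain stops when the state is unchanged for k consecutive steps, with

k = max { k′ : ((N−1)/N)^k′ > α },

the longest run for which the probability that some structure was *never*
resampled still exceeds α. "Unchanged" means the resampled element equals
the one it replaced; any change resets the counter. Two consequences are
worth stating plainly. First, α is a genuine accuracy/speed dial: smaller α
means longer chains and better convergence. Second, the rule *concedes* a
miss probability of order α per structure: with probability ≈ α the stall
window elapses without ever touching some structure, freezing whatever that
structure holds. A hard step cap (`max_steps`, default 5000 per chain)
additionally guarantees termination for pathological inputs where no state
ever concentrates; neither the stall rule nor the cap is reached in typical
use.

## Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `w` | — (required) | residues | alignment width; family-specific |
| `alpha` | 0.05 | probability | stall-rule threshold; accuracy/speed trade-off |
| `iter_refine` | 10 | iterations | refinement rounds |
| `avg_overlap` | 50 | % | greedy redundancy filter; 100 disables |
| `seed_rmsd_gate` | 1.0 | Å | max average RMSD for a seed alignment to extend |
| `candidate_radius` | 10.0 | Å | seed clique / extension candidate cutoff |
| `max_fingerprints` | 8000 | — | fingerprint enumeration cap |
| `max_steps` | 5000 | steps | hard chain cap (degenerate-input guard) |
| `rng_seed` | 1 | — | single seed for the whole run |

The defaults for α, `iter_refine`, the 1 Å gate, the 10 Å radius and the
50 % overlap threshold are the established working values for this family
of methods; `w` has no sensible universal default because conserved motifs
range from 4-residue catalytic sites to 20-residue fold cores.

## Numerical choices

**RMSD definition.** We use the standard RMSD — divide the summed squared
deviations by the number of paired residues k and take the square root.
(A variant definition that normalises by w while summing k terms, and omits
the radical, circulates in the literature; only the standard form yields
values in Å units comparable across widths, and all quantities this package
reports are labelled Å.)

**QCP and its near-zero handoff.** The production RMSD route finds the
largest eigenvalue of the 4×4 quaternion key matrix by Newton–Raphson on
its characteristic quartic (50 iterations maximum, relative tolerance
1e-11), giving rmsd² = 2(E₀ − λ_max)/k without forming a rotation matrix.
That expression is a difference of two large, nearly equal numbers: in
double precision it cannot resolve RMSDs below roughly 1e-7 of the
coordinate scale. Whenever the QCP result is below 1e-4 Å — or the Newton
iteration fails to converge, as can happen for degenerate (collinear,
k ≤ 2) point sets — the result is recomputed from the explicit Kabsch SVD
rotation with determinant correction, measuring the deviations of the
actually rotated coordinates. That route is exact near zero and restricts
the optimum to proper rotations, so mirror images score strictly positive.
Bitwise-identical inputs short-circuit to exactly 0, keeping ranking ties
exact. Degenerate sets (k = 1, collinear) remain legal: the rotation is
underdetermined but the minimal RMSD is well-defined.

**Floored inversions in log space.** The similarity scores invert products
of |ΔDist| factors that are exactly zero for identical geometry. Each
factor and each per-structure product is floored at ε = 1e-6 before
inversion, so a geometrically perfect candidate is maximally — and
finitely — likely (weight ε^−(N−1) rather than ∞). Inside the sampler these
products are accumulated as sums of logs and exponentiated after
subtracting the maximum, which is under/overflow-safe for any N and w. The
raw score functions (`pair_dist_seeds`, `pair_dist_aligned`, `badness`)
return unfloored products, preserving "zero iff identical geometry".

**Tie-breaks.** The refinement argmax over column badness breaks ties to
the lowest column index; ranking ties keep discovery order (stable sort);
all stochastic choices flow from the single seeded RNG, so a run is exactly
reproducible from its manifest.

## Design choices where the design was open

* **Fingerprint matching is unordered by default.** The 10 Å clique
  condition on a seed is orderless, so an ordered reading of fingerprints
  makes the 8000-triplet enumeration visit each geometric candidate set up
  to 6 times. We canonicalise: a seed (stored in ascending index order)
  matches a fingerprint if the two sorted symbol multisets agree, and the
  driver deduplicates the enumeration to its 1540 distinct multisets. The
  strict ordered interpretation remains available (`ordered_fingerprints`).
* **The seed gate tests the average**, not each pair: a seed alignment
  enters extension iff its *average* pairwise RMSD is ≤ 1 Å. The gate is
  checked once, at seed stage, not re-checked per added column.
* **One bootstrap attempt per fingerprint.** The outer loop over thousands
  of fingerprints already provides restarts; per-fingerprint retries would
  multiply runtime for little coverage gain.
* **Extension candidates exclude residues already in the row**, so rows
  never contain duplicates; refinement may delete and later re-add the same
  column content.
* **Substitution table positivity.** Raw BLOSUM log-odds entries are ≤ 0
  for many pairs, which breaks a product of similarities. The default table
  is BLOSUM62 mapped through s ↦ 2^s — order-preserving, strictly positive,
  and exact inverse of the log-odds construction. A shift transform and
  user-supplied matrices (NCBI text format) are configuration points.
* **Overlap is counted against kept alignments** (standard greedy
  non-redundancy) and per residue identity (structure id + residue index),
  not per column position. Filtering is idempotent and monotone in the
  threshold.

## The synthetic benchmark

`generate_planted_motif_set()` is the package's primary test substrate. It
splices rigid copies of an ideal α-helix Cα template (rise 1.5 Å, radius
2.3 Å, 100° turn per residue — compact enough that adjacent triples satisfy
the 10 Å clique) into self-avoiding random coils (3.7–3.9 Å consecutive
spacing, 2.5 Å self-avoidance), applying a uniformly random rotation, a
clash-free translation, and isotropic Gaussian coordinate noise per copy.
Motif symbols are shared across structures; ground-truth indices are
recorded.

What this emulates: a conserved local 3D motif embedded at arbitrary
sequence positions and orientations in otherwise unrelated chains, with
realistic Cα spacing and controllable coordinate noise. What it does not
emulate: real secondary-structure mixtures, side chains, sequence
correlations between motif and context, partially conserved motifs, or
motif variants with insertions. Passing the planted-motif tests therefore
demonstrates the machinery recovers a clean common substructure signal; it
does not quantify performance on real, partially conserved binding sites.

Test problem sizes were chosen to exercise every phase at desk scale: the
end-to-end recovery check uses 5 structures of 108 residues (100-residue
coils + 8-residue motif, σ = 0.1 Å, w = 8) over 10 seeded runs, with the
fingerprint set restricted to the planted motif's triplets; the bootstrap
convergence check uses 4 structures of 6 isolated seed candidates each over
50 runs. The bootstrap fixture draws its decoy triangles with a 1 Å
separation margin in side space from the planted triple and from each
other, so the planted combination is the unique consistent signal — without
such a margin random decoys occasionally form a second, unplanned
consistent quadruple and the fixture's ground truth is ill-posed.

## Known limitations

* The sampler's conditionals are sharply peaked (products over N−1
  structures), so chains behave near-greedily: each fingerprint converges
  to a local optimum and global coverage relies on the fingerprint
  restarts. Lowering α lengthens chains and measurably improves per-chain
  convergence at proportional cost.
* The stopping rule's α-fraction of "frozen structure" misses is inherent;
  reporting relies on many fingerprints, not on any single chain.
* Column-wise residue pairing is established stochastically during
  extension; the method does not search over column permutations, and
  sequence-order-independent superposition is out of scope.
* Scores use Cα geometry and residue identity only — no side-chain
  chemistry, surface accessibility, or physicochemical pseudo-centres.
* No statistical significance (E-value) model is attached to reported
  alignments; the average RMSD ranking is the only ordering.
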