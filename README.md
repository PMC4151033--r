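# gibbsmotif

Multiple **local** alignment of protein 3D structures by Gibbs sampling.

Given N protein structures P = {P₁, …, P_N} represented by their Cα traces,
`gibbsmotif` searches for N substructures of w residues (w ≥ 3), one per
structure, whose geometry is maximally conserved. Alignment quality is the
average root-mean-square deviation (RMSD) after optimal rigid-body
superposition over all N(N−1)/2 structure pairs, pairing residues
column-wise — lower is better. Typical uses are detecting conserved
structural motifs and binding/catalytic sites shared by distantly related
proteins, where sequence similarity is too weak to help.

## The algorithm

Exact multiple structural alignment is intractable (the underlying matching
problem is NP-hard), so the search is stochastic. Every run iterates over
amino-acid triplet *fingerprints* (AAA, AAC, …; 20³ = 8000 ordered
triplets), and for each fingerprint performs three phases:

1. **Bootstrap.** A *seed* is a triple of residues, pairwise closer than
   10 Å, whose symbols match the fingerprint. A Markov chain over alignments
   of N seeds (one per structure) resamples one structure's seed at a time
   from a distribution proportional to

   `Sim(X) = 1 / Π_{i≠j} PairDist(X, Sᵢ)`,

   where `PairDist(A, B) = Π_{i<j} |Dist(Aᵢ,Aⱼ) − Dist(Bᵢ,Bⱼ)|` compares
   intra-structure Cα distances. The chain stops once the alignment is
   unchanged for k consecutive steps, with k the largest integer such that
   `((N−1)/N)^k > α` — i.e. long enough that every structure was touched
   with probability ≥ 1 − α since the last change.
2. **Extension.** Seed alignments with average pairwise RMSD ≤ 1 Å grow one
   column per Gibbs sweep until width w. Candidates are unused residues
   within 10 Å of the current substructure; scores multiply a BLOSUM-derived
   symbol similarity with the inverse product of distance-profile
   discrepancies.
3. **Refinement.** For `IterRefine` rounds, the column maximising the
   *badness* score (the summed pairwise distance-profile discrepancy of a
   column against the rest of the alignment) is deleted and one extension
   step restores width w.

Collected alignments are sorted by ascending average RMSD and greedily
filtered: an alignment whose residues overlap the already-kept ones by more
than `AvgOverlap` percent (on average across structures) is discarded.

Superposition RMSD uses the quaternion characteristic-polynomial (QCP)
method — the largest eigenvalue of the 4×4 quaternion key matrix obtained by
Newton–Raphson — with a classical Kabsch SVD solution as cross-check and as
the accurate route near zero RMSD.

Defaults follow the established accuracy/speed trade-off: α = 0.05,
IterRefine = 10, AvgOverlap = 50 %, seed gate 1 Å, candidate radius 10 Å.
`w` is family-specific and must be chosen by the user.

## Worked example

The package ships a planted-motif generator: rigid, noisy copies of an
ideal α-helical 8-residue template spliced into self-avoiding random-coil
decoys, with ground truth recorded.

```r
library(gibbsmotif)
fx <- generate_planted_motif_set(4, motif_size = 8, decoy_length = 60,
                                 noise_sigma = 0.1, rng_seed = 42)
fit <- gibbsmotif(fx$structures, w = 8, rng_seed = 1,
                  fingerprints = planted_motif_fingerprints(fx))
fit
#> Gibbs-sampling local structural motif search
#>   4 structures, w = 8, alpha = 0.05, IterRefine = 10
#>   40 fingerprints searched, 30 alignments found, 1 kept after overlap filter (<= 50%)
#>   best alignment: avg RMSD 0.242 A (fingerprint EFT)
fit$alignments[[1]]
#> Local structural alignment: 4 structures x 8 residues, avg RMSD 0.242 A
#>   fingerprint: EFT
#>   synth01      22 27 26 23 24 21 28 25
#>   synth02      8 13 12 9 10 7 14 11
#>   synth03      28 33 32 29 30 27 34 31
#>   synth04      49 54 53 50 51 48 55 52
sapply(1:4, function(i)
  query_motif_coverage(fit$alignments[[1]]$rows[i, ], fx$truth[[i]]))
#> [1] 100 100 100 100
```

The best alignment recovers the planted motif exactly in every structure
(100 % query motif coverage) at 0.24 Å average pairwise RMSD — the residual
expected from the σ = 0.1 Å coordinate noise.

The same search runs from the shell on PDB files:

```sh
Rscript inst/scripts/gibbsmotif --w 8 --rng-seed 1 --out results structs/*.pdb
```

which writes `alignments.tsv`, optionally `alignments.json`, and a
`manifest.json` sufficient to reproduce the run.

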