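---
title: "Fragment-seeded structure alignment: model, parameters, and numerics"
author: "fragalign"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fragment-seeded structure alignment: model, parameters, and numerics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fragalign)
```

## The problem and the model

`fragalign` aligns two protein backbones given only their C-alpha
traces, and ranks a database of structures against a target.  A
structure alignment is an ordered set of residue pairs
R = {(q_i, p_i)} — strictly increasing in both chains, so the
correspondence is sequential — together with the proper rigid-body
transform T that superimposes the target over the database chain.  The
pipeline is seed-and-refine:

1. **Fragment seeding.**  Chains are tiled N- to C-terminally with
   non-overlapping fragments of L_f = 8 residues, so a chain of length L
   holds floor(L / L_f) fragments and up to 7 trailing residues that are
   only alignable at residue level.  A fragment is summarized by the 28
   intra-fragment Cα–Cα distances in lexicographic pair order; this
   feature vector is invariant to rigid motion (and to reflection —
   mirror images are indistinguishable at this stage and are resolved
   later, because the superposition engine only admits proper
   rotations).  Two fragments are compared with the inverse-cosine score
   s_f = 1 − arccos(⟨D_A, D_B⟩ / (‖D_A‖ ‖D_B‖)), which is 1 for
   parallel feature vectors and has the floor 1 − π.
2. **Matched fragment sets (MFS).**  Fragment pairs scoring at least
   tau_f become match candidates.  Every order-consistent candidate
   pair whose fragment-centroid distances agree within eps_d seeds an
   MFS: the set of all candidates compatible with both anchor members
   under the same test.  An MFS is scored
   S_MFS = w1 N_Q/N_f^Q + w2 N_P/N_f^P + w3 min(N_Q,N_P)/max(N_Q,N_P):
   coverage of either chain plus a balance term that favours sets of
   comparable cardinality.  Near-duplicate sets are removed greedily by
   Jaccard overlap of their member fragments, and the top N_seed sets
   continue.  If no MFS exists at all, the single fallback MFS holding
   every fragment of both chains is used, so an alignment is always
   attempted.
3. **Fragment-level DP.**  Within one MFS, dynamic programming over the
   fragment score submatrix (gap penalty G_f) selects an ordered
   fragment correspondence, which expands into an initial residue
   alignment: fragment pair (i, j) contributes residue pairs
   (i·L_f + t, j·L_f + t).
4. **Residue-level DP.**  The optimal transform of the current
   alignment's paired coordinates superimposes the whole target; every
   residue pair is scored with the TM-align function
   S_r = 1 / (1 + (d_ij/d0)²), where d0(L) = 1.24 (L − 15)^{1/3} − 1.8 Å
   (floored at 0.5 Å) and L is the shorter chain length; DP with gap
   penalty G_r = 0 re-aligns all residues, including trailing ones that
   belong to no fragment.
5. **Maximal-subset search.**  MaxSub-style: each of the
   L_R − L_W + 1 windows of length L_W along the alignment seeds a
   superposition, which is iteratively (N_MS rounds) extended with every
   alignment pair closer than the 4.0 Å cutoff.  The refined member set
   with the best TM-score, S_a = (1/L_norm) Σ 1/(1 + (d_i/d0)²)
   normalized by the shorter chain length, becomes the maximal subset M.
   Its transform superimposes the whole target once more, and the
   next-round alignment is rebuilt from the residue-level DP path
   restricted to pairs strictly inside the cutoff — routing through the
   DP keeps the alignment ordered, which raw proximity selection would
   not guarantee.  Steps 4–5 repeat N_iter times per seed; the best
   alignment (by S_a) across seeds and rounds is kept, near-duplicate
   per-seed alignments are dropped each round with the same Jaccard
   rule, and the loop exits early once the surviving alignment set is
   stable (the keep-best rule makes further rounds a no-op).
6. **Assessment.**  The report carries Ne = |R|, the cRMSD of the final
   pairs under their own optimal superposition,
   RMSD100 = cRMSD / (1 + ln(Ne/100)) (the cRMSD expected for
   100-residue chains), the TM-score, PSI — the percentage of pairs
   within 4.0 Å on the scale of the shorter chain length k — and the
   z-score (PSI − μ_PSI(k)) / σ_PSI(k) with the fitted null
   μ_PSI = 375.64 k^−0.5295 and σ_PSI = 99.67 k^−0.5885.  The PSI
   denominator must be on a chain-length scale for this null to apply,
   which is why k = min(L_Q, L_P) is used; the same k normalizes the
   TM-score, so S_a = 1 is attainable for identical structures.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `l_f` | 8 residues | fragment length; fixed by the fragment model |
| `tau_f` | 0.8 | fragment-match threshold on s_f in (1 − π, 1] |
| `eps_d` | 2.0 Å | centroid-distance compatibility tolerance |
| `jaccard_threshold` | 0.7 | redundancy cut for MFS and per-round alignments |
| `w` | (1/3, 1/3, 1/3) | MFS score weights |
| `g_f` | −0.6 | fragment-level gap penalty |
| `g_r` | 0 | residue-level gap penalty (by construction) |
| `l_w` | 4 pairs | MaxSub seed window |
| `n_ms` | 4 | superpose-and-extend iterations per window |
| `cutoff` | 4.0 Å | extension / PSI / final-pair cutoff, strict `<` |
| `d0_min` | 0.5 Å | floor of the TM-score distance scale |
| `n_iter` | 3 | refinement rounds |
| `n_seed` | 20 | seed MFS count carried forward |
| `max_anchor_pairs` | 200 | cap on matched pairs enumerated as anchors |

Where the method itself fixes a value (L_f, G_r, the 4.0 Å cutoff, the
z-score constants, the RMSD100 and d0 formulas), that value is used as
given.  The remaining knobs are package choices: `tau_f`, `eps_d`,
`jaccard_threshold`, equal `w`, `g_f` (borrowed from the TM-align
family's gap conventions), `l_w` and `n_ms` (small seed windows in the
spirit of MaxSub), and the anchor cap, which bounds the seeding cost at
O(cap²) while keeping every high-scoring match available as an anchor.
All are exposed through `align_params()`.

## Numerical choices

* **QCP superposition.**  The minimal RMSD is obtained from the largest
  eigenvalue of the 4×4 quaternion key matrix, found by Newton iteration
  on its quartic characteristic polynomial seeded at half the total
  centered inner variance (relative tolerance 1e-13, at most 60
  iterations); the rotation comes from the corresponding eigenvector.
  Degenerate spectra — collinear or planar point sets, where the largest
  root is (near-)multiple and the quartic is ill-conditioned — are
  detected by slow convergence or a vanishing polynomial derivative and
  routed to the exact symmetric eigen-decomposition; this is never a
  user-facing error.  Near RMSD 0 the identity E − 2λ cancels
  catastrophically for elongated structures, so when the formula value
  falls below 1e-3 Å the residual is re-evaluated directly from the
  superimposed coordinates, which is second-order exact at the optimum.
  A pure-R Kabsch implementation (SVD with determinant sign correction)
  serves as the independent oracle; the two agree to well below 1e-6 Å
  over random and near-degenerate instances.
* **DP semantics.**  End gaps are free on both chains: the boundary
  row/column is zero, a match may open a fresh path, and the traceback
  starts at the best cell anywhere in the matrix, so only residues
  skipped between matched pairs pay the gap penalty.  Tie-breaking is
  deterministic (diagonal > up > left; later cells win score ties),
  making whole-pipeline runs byte-reproducible.
* **Cosine quantization.**  arccos amplifies 1e-15 rounding noise near
  cos = 1 into 1e-8 score noise, enough to reorder seed rankings between
  a structure and its rigidly moved copy (ideal helices, whose fragments
  are all congruent, are the worst case).  The cosine is therefore
  quantized at 1e-9 before arccos, and the residue score matrix at 1e-9,
  which makes alignment results invariant under rigid motion of either
  input to ~1e-12 while being far below any scientifically meaningful
  score difference.
* **Cutoffs and guards.**  The 4.0 Å rule is a strict inequality
  (a pair at exactly 4.0 Å is excluded).  RMSD100's denominator crosses
  zero near Ne ≈ 37, so shorter alignments report raw cRMSD with a
  `short_alignment` flag.  Chains shorter than one fragment fall back to
  a residue-only seed (`residue_only` flag); a pair with no viable
  alignment reports Ne = 0 and `no_alignment` instead of failing, and in
  a database search such rows sort last.

## Synthetic fixtures: what they do and do not show

`generate_helix()` (canonical α-helix: 1.5 Å rise, 100° twist, 2.3 Å
radius — ~3.8 Å Cα spacing), `perturb_trace()` (isotropic Gaussian
coordinate noise), `rigid_copy()` (uniform random rotation, translation
in [−50, 50] Å) and `random_walk_trace()` (fixed 3.8 Å steps,
self-avoiding below 3.0 Å) are deterministic given their seed and
emulate the geometric regime of real backbones: correct bond spacing,
compactness-free decoys, and realistic noise scales.  They do **not**
emulate secondary-structure diversity, domain architecture, insertions/
deletions between homologs, or the length and similarity distributions
of real fold databases.  Passing the suite therefore demonstrates the
algorithmic contracts — optimality of the DP and subset searches,
superposition correctness, fixed points, rigid invariance, noise
recovery and decoy separation — not benchmark-level accuracy on real
fold classification, which would require curated structure sets.
An ideal helix is additionally self-similar under register shifts, which
makes it a deliberately adversarial test of seeding determinism rather
than a typical input.

## Problem sizes used in the checks

The packaged checks run pairs of 80–400 residues, 20-seed noise and
decoy panels at 100–150 residues, oracle comparisons on 1000 random
superposition instances, 500 small DP matrices, and 100 maximal-subset
instances — sizes chosen so the full suite exercises every code path in
a few minutes on one CPU while leaving the statistical conclusions
(rates over 20 trials, worst cases over hundreds of instances) stable
across seeds.

## Known limitations

* Alignments are sequential; circular permutations and non-sequential
  topological matches are out of scope.
* Seeding cost is O(N_f^Q · N_f^P) per pair — fine at desk scale, not
  indexed for millions of comparisons.
* Only Cα atoms are used; mmCIF input and multi-chain assemblies are
  not supported.
* The z-score null constants are used as published constants for
  single-chain PSI at minimum chain length k; they are not re-fitted to
  the synthetic fixtures.
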