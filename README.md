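# enmodes

Coarse-grained elastic-network analysis of protein motion modes in R.

Large multi-domain proteins — vinculin's five-domain auto-inhibited
arrangement is the motivating example — change conformation through slow,
collective motions that are largely determined by the topology of the
folded structure, not by chemical detail. `enmodes` computes these motions
from a single Cα trace with the two standard harmonic models:

* **GNM** (Gaussian network model): nodes within a cutoff $r_c$
  (default 7.3 Å) are joined by identical springs; the $N \times N$
  Kirchhoff matrix $\Gamma$ ($\Gamma_{ij} = -1$ for contacts, diagonal =
  contact degree) is eigendecomposed, and mode $k$ contributes
  $\lambda_k^{-1}[u_k]_i[u_k]_j$ to residue covariance. The slowest
  non-rigid mode partitions the structure into dynamic domains; its
  minima are the hinges. Cross-correlations
  $C_{ij} = \langle \Delta R_i \cdot \Delta R_j\rangle /
  (\langle \Delta R_i^2\rangle \langle \Delta R_j^2\rangle)^{1/2}$
  over the slowest 40 modes map which domains move in or out of phase.
* **ANM** (anisotropic network model): the $3N \times 3N$ Hessian with
  blocks $h_{ij} = -\gamma\, d_{ij} d_{ij}^T / R_{ij}^2$ yields
  per-residue displacement *directions* (default cutoff 13 Å), exported
  in NMD format for normal-mode viewers.
* **Superposition**: determinant-corrected Kabsch fits (optionally
  anchored on a trimmed rigid core) compare two conformations, with
  per-residue deviations written into PDB B-factors, plus a helix
  bend-angle measure from split-half axis fits.

A synthetic-structure generator (chains, rings, ideal helices, helix
bundles, two-domain dumbbells, gapped chains) provides fixtures with
closed-form or constructed ground truth, so the whole pipeline is testable
offline. The package is aimed at structural bioinformaticians who want
scriptable, reproducible mode analysis rather than a viewer plugin.

## Worked example

```r
library(enmodes)

# two dense 20-node domains joined by a thin 4-node linker
nd  <- synthetic_structure("dumbbell")
ann <- attr(nd, "annotation")

spec <- gnm_decompose(build_kirchhoff(nd, enm_params(cutoff = 7.3)))
prof <- slow_mode_profile(spec, ann)
prof$segments
#>    label start end       mean        max
#>        A     0  19 0.02396535 0.02419881
#>   linker    20  23 0.01035736 0.01861717
#>        B    24  43 0.02396318 0.02419947

find_hinges(prof$profile)$hinges
#> [1] 21

round(block_correlation(cross_correlation(spec, count = 40), ann), 3)
#>             A linker      B
#> A       0.922 -0.022 -0.923
#> linker -0.022 -0.016 -0.022
#> B      -0.923 -0.022  0.924
```

The slowest mode gives the linker the lowest mean fluctuation (0.010 vs
0.024 for either domain) and the hinge detector places the hinge at node
21, inside the true linker (nodes 20–23). Over the first 40 non-rigid
modes each domain coheres internally (mean correlation +0.92) while the
two domains move anti-phase (−0.92) — the numeric restatement of a
two-domain hinge motion.

The numbered scripts under `analysis/` run the full workflow (simulate →
GNM slow modes → cross-correlations → ANM directions → superposition) and
write their tables under `results/`; each prints a short summary like the
output above. Real structures enter through `parse_structure()` /
`run_config(input = "file.pdb")`.

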