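---
title: "Elastic-network mode analysis: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network mode analysis: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enmodes)
```

## The models

`enmodes` analyses the collective motions of a protein from a single
structure, coarse-grained to one node per residue at the C&alpha; position.
Two harmonic models are implemented.

**Gaussian network model (GNM).** Every pair of nodes within a cutoff
distance $r_c$ is joined by an identical spring of constant $\gamma$. The
potential is $V = \tfrac{\gamma}{2}\,\Delta R^T (\Gamma \otimes E)\,\Delta R$,
where $\Gamma$ is the $N \times N$ Kirchhoff (contact Laplacian) matrix:
$\Gamma_{ij} = -1$ if $i \neq j$ and $R_{ij} \le r_c$, $0$ if beyond the
cutoff, and $\Gamma_{ii}$ equals the contact count of node $i$. Fluctuations
and correlations are read off the Moore–Penrose pseudo-inverse of $\Gamma$
through its eigendecomposition $\Gamma = U \Lambda U^T$: mode $k$
contributes $\lambda_k^{-1} [u_k]_i [u_k]_j$ to the covariance of residues
$i$ and $j$, and the slowest non-rigid modes (smallest nonzero
$\lambda_k$) dominate the large-amplitude, functionally relevant motion.
The model is isotropic: it predicts fluctuation magnitudes and their
correlations but no directions.

**Anisotropic network model (ANM).** The same contact network, but the
energy is expanded in the full $3N$ coordinate space. The Hessian is built
from $3\times3$ blocks
$h_{ij} = -\frac{\gamma}{R_{ij}^2}\, d_{ij} d_{ij}^T$ for contacting pairs
($d_{ij}$ the coordinate difference at the input geometry), with diagonal
blocks closing each block row to zero. Its non-rigid eigenvectors are
per-residue displacement 3-vector fields — the directional information the
scalar model lacks.

Assumptions shared by both: the crystal structure is the energy minimum;
springs are uniform (no residue-specific or distance-weighted constants);
solvent, side chains and anharmonicity are ignored. These models predict
the *topology-determined tendency* of motion, not trajectories.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `cutoff` (GNM) | 7.3 | Å | contact radius of the scalar network |
| `cutoff` (ANM) | 13 | Å | contact radius of the directional network |
| `gamma` | 1 | energy/Å² | uniform spring constant; scales all eigenvalues |
| `kT_scale` | 1 | — | the prefactor $3 k_B T/\gamma$ folded into one reporting scale |
| `zero_tol` | 1e-8 | relative | eigenvalue threshold for zero modes |
| `n_modes_correlation` | 40 | modes | slow-mode range of the correlation map |
| `hinge_window` | 5 | nodes | moving-average width before minima detection |
| `hinge_prominence` | 0.05 | fraction of max | minimum prominence of a hinge dip |

Notes on the less obvious choices:

* **ANM cutoff 13 Å.** A C&alpha; network at 7.3 Å is frequently
  under-constrained in three dimensions — nodes whose contacts are nearly
  collinear acquire zero-energy mechanisms and the rigid-body null space
  inflates past 6. 12–15 Å is standard practice for C&alpha; ANM; we default
  to 13 Å and leave the value configurable (`run_config(anm_cutoff = …)`).
  This is the single most consequential parameter that the scalar model
  does not pin down; the choice is echoed in every run's `config.yaml`.
* **Mode counting.** User-facing mode numbers are 1-based over *non-rigid*
  modes: "mode 1" is the slowest internal motion, never a rigid-body mode.
  The 40-mode default of the correlation map therefore means 40 non-rigid
  modes; the starting mode is exposed (`cross_correlation(first = …)`)
  because conventions in the literature differ on whether the zero mode is
  counted. On systems with fewer than 40 non-rigid modes the range is
  clipped with a warning.
* **`kT_scale`.** Physical units are never evaluated: every fluctuation
  output is either relative (normalized profiles, correlations in
  $[-1,1]$) or in $3k_BT/\gamma$ units, which is all the analyses need.

## What the synthetic generator emulates — and what it does not

`synthetic_structure()` produces C&alpha; traces whose elastic-network
behaviour is known by construction: straight chains, rings (circulant
Kirchhoff matrix, closed-form spectrum $2 - 2\cos(2\pi k/n)$), ideal
α-helices (rise 1.5 Å, twist 100°, radius 2.3 Å, giving the canonical
~3.8 Å C&alpha; spacing), antiparallel helix bundles, two-domain dumbbells
(compact FCC-packed 20-node blobs joined by a thin 4-node strand), and
chains with a residue-numbering gap emulating a disordered segment absent
from deposited coordinates. Gaussian coordinate noise (default sd 0 Å) can
be added; generation is deterministic given the seed.

These fixtures reproduce the *topological* features the analyses rely on —
dense domains, thin linkers, helical geometry, numbering gaps — but not
real protein features: no side-chain packing, no β-sheets, no heterogeneous
contact density, no crystallographic noise model. Passing tests on them
demonstrates that the machinery computes the model correctly and that the
hinge/domain logic responds to topology as designed; it does not by itself
validate biological conclusions about any particular protein, which also
depend on the input structure's quality.

## Numerical choices

* Contact comparison is inclusive ($R_{ij} \le r_c$); row sums of
  $\Gamma$ are exact zeros because contacts are counted, not accumulated
  in floating point. ANM diagonal blocks are computed as negated block-row
  sums, so translation invariance is exact rather than approximate.
* Dense symmetric eigendecomposition (`eigen(symmetric = TRUE)`),
  ascending eigenvalues. Intended problem sizes (N up to ~1200 nodes) are
  comfortably dense; the analyses shipped here run at N ≤ 50.
* Eigenvector sign is fixed by making each vector's largest-magnitude
  entry positive (first such entry on ties), so mode shapes are
  reproducible across solvers. Within a degenerate eigenvalue cluster the
  *individual* vectors remain solver-dependent; tests compare invariant
  quantities (eigenvalues, summed profiles of the degenerate pair,
  projectors) instead.
* Zero modes are counted against `zero_tol` × the largest eigenvalue; for
  the contact graph this count equals the number of connected components
  (GNM) or 6 per rigid connected component (ANM). Collinear geometries
  legitimately deviate (a two-node spring has 5 zero modes; a straight
  linker is a floppy mechanism) and are reported with a warning, not an
  error.
* Hinge detection operationalizes "read the minima off the slow-mode
  plot": moving-average smoothing (shrinking window at the edges), then
  interior local minima kept if their topographic prominence is at least
  `hinge_prominence` × the profile maximum. The relative threshold makes
  the result invariant under uniform scaling; plateau ties resolve to the
  lower node index, and profile endpoints are never hinges.
* Kabsch superposition corrects the SVD determinant so reflections are
  never returned; degenerate (collinear) fit selections and fits with
  fewer than 3 pairs are rejected. `rmsd²` equals the mean squared
  per-residue deviation over the fit selection by construction.
* Helix axes are estimated from the null principal direction of the
  second-difference vectors of the C&alpha; trace: for an ideal helix the
  constant rise cancels exactly in $p_{i+2} - 2p_{i+1} + p_i$, so the
  estimator is unbiased even on fragments covering partial turns, where a
  plain principal-component fit of the coordinates tilts by several
  degrees. Straight or planar traces (degenerate second differences) fall
  back to the dominant principal direction. Each half needs ≥ 4 residues.

## Design choices that were genuinely open

* **Fit selection for conformation comparison.** Which residues anchor a
  superposition is not dictated by the model. The default (`fit =
  "trimmed"`) fits all matched pairs once, drops the worst 10% by
  deviation, and refits once: anchoring on the rigid core lets genuine
  deformations stand out in the per-residue deviations instead of being
  averaged into the global fit. `fit = "all"` and explicit index
  selections are available.
* **Deviation colour classes.** Per-residue deviations are exported in
  the B-factor column of a PDB copy, so any viewer can colour by
  deviation; no fixed numeric thresholds for "high/moderate/low" are
  baked in — tertiles of the observed deviations are a sensible default
  at display time.
* **Residue pairing.** Structures are paired by (chain, resSeq, iCode)
  identity, never by sequence alignment: the intended comparisons are
  between conformations of the same protein with consistent numbering.
* **HETATM records are always excluded** when reading PDB files; only
  CA atoms of standard ATOM records become nodes, with the
  highest-occupancy alternate location kept (first-listed on ties) and
  residues lacking a CA skipped with a warning.

## Problem sizes and runtime

The shipped analyses and test suite run on fixtures of 20–50 nodes, where
every oracle (pseudo-inverse, finite-difference Hessian, graph traversal,
10,000-rotation Monte-Carlo bound) is exact or exhaustive within seconds.
The implementation itself is dense linear algebra and scales to the
N ≈ 1000 node range of full-length multi-domain proteins.

## Known limitations

* No distance-weighted or residue-specific spring constants, and no
  temperature-factor fitting of γ.
* No automatic dynamic-domain partitioning beyond minima of the slowest
  mode, and no spectral clustering of modes.
* No mmCIF input and no sequence alignment for pairing.
* ANM cone-length scaling in the NMD export is a convention, not a
  prediction: `1/sqrt(λ)` (thermal amplitude) by default, `1/λ` and raw
  eigenvector scaling available.
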