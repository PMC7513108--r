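---
title: "Methods: entropy estimation and free-energy ranking in confent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: entropy estimation and free-energy ranking in confent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(confent)
```

## Scope and model

`confent` answers one question: among competing conformations of a
protein sequence, which dominates at equilibrium once configurational
entropy is included? The free energy of the folded, solvated protein is
decomposed as

$$G \approx E_\mathrm{intra} + G_\mathrm{solv} - T S_\mathrm{conf} + \text{const},$$

where the constant is conformation-independent and therefore irrelevant
to state selection. $E_\mathrm{intra}$ and $G_\mathrm{solv}$ are
*inputs* (an `energy_table`); the package never computes force-field
terms. Its own contributions are (i) the entropy estimator that turns a
torsion-angle ensemble into per-residue partial entropies, and (ii) the
Boltzmann machinery that turns energies into weights, ranks, and
minimal contributing subsets.

Three cost functions are exposed: `Eintra`, `G0 = Eintra + Gsolv` and
`Ghat = G0 + (-T Sconf)`. Weights follow
$w_X(k) = e^{-\beta X(k)} / \sum_i e^{-\beta X(i)}$ with
$\beta = 1/(k_B T)$, $k_B = 0.0019872$ kcal/(mol·K), default
$T = 300$ K. Weights are invariant under adding any constant to a cost
column, which is why tables whose columns are each shifted to a zero
minimum are valid inputs, and why the implementation may subtract the
minimum cost before exponentiating (pure numerics, no approximation).

## Partial entropies from torsion ensembles

The configurational entropy of the chain is approximated from its
torsional degrees of freedom. For a `torsion_ensemble` (frames ×
labelled torsions, radians), residue $i$ receives

$$S_i = \sum_{t \in \mathcal{T}_i} \hat H(t)\; - \sum_{(a,b) \in \mathcal{A}_i} \hat I(a, b),$$

and the total $S_\mathrm{conf} + C = \sum_i S_i$, where $C$ is an
unknown constant for a fixed sequence. The package never estimates $C$;
every reported comparison is a difference, in which $C$ cancels.

$\mathcal{T}_i$ contains the $\phi$, $\psi$ and $\chi_1..\chi_4$
torsions of residue $i$ ($\omega$ is treated as rigid — its narrow
trans distribution carries negligible entropy). $\mathcal{A}_i$ are
the covalently adjacent torsion pairs *charged to* residue $i$:

* within residue $i$: $(\phi,\psi)$, $(\phi,\chi_1)$, $(\psi,\chi_1)$,
  $(\chi_k,\chi_{k+1})$ — owned by residue $i$;
* across the peptide bond: $(\psi_i, \phi_{i+1})$ — owned by residue
  $i+1$.

Subtracting *all* adjacent-pair mutual informations is a deliberate,
documented convention. A maximum-information spanning tree would
subtract only a cycle-free subset and can therefore never
over-subtract; the all-adjacent-pairs form can, slightly, when the
coupling graph has cycles. The convention here (including the ownership
of the cross-residue pair, which is arbitrary but must be fixed for
$\sum_i S_i$ to be well defined) is a stand-in for conventions that
exist in several variants in the literature; it is exact whenever
couplings are disjoint, which is also the regime the synthetic ground
truth covers. Chain ends simply omit the undefined torsions ($\phi$ of
the first residue, $\psi$ of the last); no special end correction is
applied.

### Estimators

Marginal entropies use a plug-in histogram on **30 equal circular
bins** over $[-\pi, \pi)$:
$\hat H = -\sum_b \hat p_b \ln \hat p_b + \ln(2\pi/30)$, in $k_B$
(nats). Thirty bins (12° resolution) balance discretization bias
against sampling noise in the regime the estimator is meant for,
$10^3$–$10^5$ frames; the count is a config parameter (`bins`). The
**Miller–Madow** correction $(m - 1)/(2F)$ ($m$ = occupied bins, $F$ =
frames) is on by default; it removes the leading small-sample bias at
negligible cost.

Mutual information uses the same grid in 2-D:
$\hat I = \hat H(x) + \hat H(y) - \hat H(x,y)$; the bin-width terms
cancel, leaving the discrete MI. After Miller–Madow correction
($(m_x-1)/2F + (m_y-1)/2F - (m_{xy}-1)/2F$), negative estimates are
clipped to zero. Clipping keeps every subtracted term nonnegative, which
guarantees the estimated total never exceeds the sum of marginals (the
spanning-tree-style upper-bound property) and protects sparse-data
profiles from spurious entropy gains.

Degenerate inputs behave predictably: a constant torsion occupies one
bin and yields exactly $\ln(2\pi/30)$; an ensemble below ~`bins`
frames triggers a warning; a single frame is rejected (entropy of one
microstate is meaningless); residues with no torsions get $S_i = 0$
with a warning.

### Validation against analytic ground truth

`sample_torsion_ensemble()` draws ensembles whose exact entropy is
known: uniform or von Mises marginals
($H = \ln(2\pi I_0(\kappa)) - \kappa I_1(\kappa)/I_0(\kappa)$), coupled
pairwise through a **Gaussian copula**. The copula was chosen because
its MI has a closed form, $-\tfrac12 \ln(1-\rho^2)$, *invariant under
the monotone marginal transforms* — so the planted MI is exact for any
marginals, giving the estimator an oracle with no simulation error.
Coupled pairs must be disjoint; otherwise the analytic total would need
the full copula covariance and would no longer decompose
pair-by-pair. The test suite checks recovery at $10^3$–$10^5$ frames
for $\kappa \in \{0.5, 2, 8\}$ and $\rho \in \{0.3, 0.5, 0.8\}$ over
three seeds; with 30 bins and $10^5$ frames, marginals recover to a few
$10^{-2}\,k_B$ (the $\kappa = 8$ case is the worst, since a ~20°-wide
peak spans few bins) and MI to ~$10^{-2}\,k_B$.

What the generator emulates: equilibrium torsion fluctuations with
known marginal shapes and controlled pairwise coupling, i.e. the
statistical substrate of the estimator. What it does not emulate:
multimodal rotamer hopping, excluded-volume coupling across distant
residues, correlated backbone waves, or anything kinetic. Passing tests
therefore demonstrate estimator correctness, not that 30 bins is
optimal for any particular molecular-dynamics trajectory.

## Ranking and the minimal subset

`evaluate_cost()` shifts each cost column to a zero minimum (display
convention; weights are shift-invariant). `rank_report()` ranks every
column with ties sharing the lower rank. `minimal_subset()` sorts
conformations by descending weight per cost function and keeps the
shortest prefix whose weight sum exceeds $1-\varepsilon$ (default
$\varepsilon = 10^{-7}$); for a single cost function the prefix is the
optimal subset of its size. The joint subset is the union of per-cost
prefixes. The true joint minimum could not be smaller for
prefix-optimal single-cost sets over a shared ground set; the test
suite nevertheless cross-checks against exhaustive enumeration of all
$2^6$ subsets on the bundled table.

## Structure characterization choices

* **Superposition RMSD**: Kabsch via SVD, with the reflection branch
  corrected (determinant +1) so mirror images are *not* treated as
  identical. Cross-checked in tests against `bio3d::rmsd(fit = TRUE)`
  and a brute-force rotation search.
* **Deduplication**: average-linkage (UPGMA) clustering of the pairwise
  CA-RMSD matrix via `stats::hclust`, cut so that only merges strictly
  below the 5 Å threshold happen; each cluster collapses to one
  representative drawn uniformly under a caller-supplied seed. CA
  atoms are the conventional choice for decoy comparison; the atom
  selection is a parameter. Merge-order ties are resolved by `hclust`'s
  deterministic agglomeration, so identical inputs give identical
  clusterings. Note RMSD after independent superpositions need not obey
  the triangle inequality; UPGMA does not require it.
* **SASA**: Shrake–Rupley point sampling with a deterministic golden-
  spiral point set, 960 points per atom (92 available for speed), probe
  1.4 Å, radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å. Unknown elements
  are an error unless a default radius is supplied. An isolated atom
  reproduces $4\pi(r+1.4)^2$ to <1%; a two-atom overlap matches the
  spherical-cap closed form.
* **Secondary structure**: a deliberately simplified three-state
  assignment for descriptive reports only — Kabsch–Sander H-bond energy
  $E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})$
  kcal/mol with a −0.5 cutoff, amide H placed 1 Å from N opposite the
  preceding carbonyl; two consecutive $i\!\to\!i{+}4$ turns mark H,
  reciprocal long-range bonds mark E, everything else C. It is not a
  DSSP replacement and is never used in any quantitative result.
* **Unfolded-model flag** in `run_dedup()`: structures with
  $R_g > c\,N^{0.38}$ (default $c = 3.3$ Å) are dropped. Folded
  globular proteins follow $R_g \approx 2.2\,N^{0.38}$ Å, so the
  default flags chains expanded ~50% beyond that. This is an explicit
  heuristic, exposed as `rg_coeff`.

## Geometry conventions

Dihedrals follow the IUPAC sign convention and are returned in
$(-\pi, \pi]$ by `dihedral()` (the planar-anti case is exactly $\pi$);
stored ensemble samples are wrapped into $[-\pi, \pi)$, mapping $\pi$
to $-\pi$, so histogram bins tile the circle without a seam. The chain
builder uses ideal geometry (N–CA 1.458, CA–C 1.525, C–N 1.329 Å,
standard angles, $\omega = 180°$) and round-trips through
`compute_torsions()` to $10^{-6}$ rad, which the suite asserts.
Alternate locations in PDB input resolve to the highest occupancy, ties
to the first record; hydrogens and HETATM records are ignored.

## Problem sizes in the test suite

The suite runs synthetic ensembles up to $10^5$ frames × 4 torsions for
estimator-recovery checks and 20–25-residue decoy sets for clustering;
these sizes give stable estimates at the stated tolerances while
keeping the full suite in seconds. Larger inputs are supported — cost
is linear in frames and quadratic in atoms only for SASA and RMSD
matrices.

## Known limitations

* Entropy from ensembles only: there is no single-structure entropy
  predictor in this package; one structure carries no fluctuation
  information.
* The adjacency/ownership convention and end treatment are fixed
  stand-ins (see above); alternative conventions shift $C$-like
  constants and per-residue attribution but not differences of totals
  between conformations of the same sequence, provided the same
  convention is used on both sides.
* The histogram estimator is biased for strongly concentrated torsions
  (bias $\sim h^2/(24\sigma^2)$); 30 bins keep this below
  $\sim 0.015\,k_B$ for $\kappa \le 8$.
* Ensembles must share labels exactly; no alignment or imputation of
  missing torsions is attempted.
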