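---
title: "Torsion-space backbone assembly from residual dipolar couplings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion-space backbone assembly from residual dipolar couplings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rdcfold)
```

## The model

A residual dipolar coupling (RDC) between two magnetically active backbone
nuclei reports the average orientation of their internuclear vector
relative to the magnetic field when the protein tumbles in a weakly
aligning medium. For a rigid structure the coupling is the quadratic form

$$D = D_{\max}\; v^{\mathsf T} S\, v,$$

where $v$ is the unit internuclear vector in the molecular frame, $S$ the
$3\times 3$ symmetric traceless Saupe order tensor of the alignment
medium, and $D_{\max} = -\mu_0\gamma_1\gamma_2 h/(2\pi r)^3$ the maximal
coupling fixed by the two gyromagnetic ratios and the internuclear
distance $r$ (assumed fixed for bonded backbone pairs; the supported
pairs and distances are in `vectorTypes()`). We evaluate $D_{\max}$ with
the full Planck constant, which puts the maximal N--H coupling at about
23 kHz -- the value the field routinely quotes. The constant is a pure
scale convention here: it is folded into every design-matrix row, so a
different choice would simply be absorbed by the fitted tensors, leaving
fitness scores and recovered structures unchanged for self-consistent
data.

Because each row of the linear system carries its own $D_{\max}$, RDCs of
*mixed* vector types (N--H together with C$\alpha$--H$\alpha$,
N--C$\alpha$, C$'$--N, ...) share a single dimensionless order tensor per
medium. That is what makes arbitrary backbone atom-pair restraints, as
NEF files express them, usable in one fit.

Given couplings $D'_{ij}$ in $M$ media and a candidate structure, each
medium's tensor is estimated by least squares in its five independent
components and the structure's fitness is the pooled root-mean-square
deviation

$$\mathrm{Fitness} = \sqrt{\frac{\sum_{j=1}^{M}\sum_{i=1}^{N}
 (D_{ij}-D'_{ij})^2}{M\times N}}\ \text{(Hz)},$$

with the denominator counted as the total number of pooled couplings, so
media of unequal size are handled naturally. Under-determined systems
(fewer than five independent rows, routine during the first elongation
steps) take the minimum-norm solution through a singular-value
pseudo-inverse with relative cutoff $10^{-10}$; uncertainties are stored
but not used for weighting by default (`weighted = TRUE` enables
$1/\sigma^2$ weighting of the fit).

## The search

The backbone is assembled in torsion space from rigid trans peptide
planes with fixed ideal bonded geometry (Engh--Huber-style values,
$\omega = 180^\circ$; only N, H, C$\alpha$, H$\alpha$, C$'$, O are
built). Junction $i$ -- the joint between adjoining peptide planes at
C$\alpha(i)$ -- is parameterized by residue $i$'s $(\phi,\psi)$.

**Stage I** enumerates a regular torsion grid per junction (default
$10^\circ$; the packaged evaluation uses $15^\circ$, see below), filters
it by generously inclusive Ramachandran polygons for four residue
classes (general, Gly, Pro, pre-Pro), and ranks the survivors by the
fitness of the two-plane fragment against the couplings whose *both*
atoms lie in those two planes. The region tables are deliberately loose
-- real targets sample atypical Ramachandran space, and an over-strict
filter would discard the true conformation before the data can vote --
and they are plain data (`ramaRegions()`), swappable by argument.

**Stage II** elongates fragments junction by junction: the beam of at
most $n$ fragments (search depth, default 1000) is crossed with the
junction's candidate list, every child is scored by the full fitness
over all couplings resolvable within it, and the pool is pruned by the
decimation policy. Elongation is append-only, so each fragment caches
the normal-equation blocks of its already-resolved couplings and a child
costs one small dense solve per medium (the `scorePoolCpp` kernel); the
reported score of every step's winner is audited against a from-scratch
recomputation (`$audit`).

Two decimation policies are provided:

* **static** (legacy behaviour, for comparison experiments): bucket the
  pool by the terminal $(\phi,\psi)$ rounded to a bucket width, keep the
  best representative per bucket, then apply an absolute score
  threshold. A fixed threshold cannot adapt: with sparse early data it
  admits nearly everything (exponential pool growth), with noisy data it
  can reject everything.
* **dynamic** (default): keep fragments scoring below
  $\max\!\big(s_0\,(1+n/100),\ \varepsilon_{\mathrm{abs}}\big)$, where
  $s_0$ is the current best score and $n$ the percentage tolerance
  (default 20). The absolute floor $\varepsilon_{\mathrm{abs}}$ (default
  0.01 Hz) governs the under-determined early steps: there $s_0$ is zero
  to machine precision, a pure percentage band would collapse to exact
  numerical ties, and the floor keeps every fragment consistent with the
  data, which is the honest answer while the tensor is unconstrained. A
  percentage of the best score could also be read additively
  ($s_0 + n/100$ Hz); both are implemented (`additive`), the
  multiplicative reading is the default because the tolerance is defined
  as a percentage.

All orderings break ties lexicographically on the torsion sequence, so
runs are bit-reproducible; the only randomness in the package is the
seeded uniform noise of the simulator.

### Terminal torsions

$\phi_1$ and $\psi_n$ are not defined as four-atom dihedrals. The
builder realizes them as proxy orientations -- $\phi_1$ orients the
N-terminal amide hydrogen, $\psi_n$ the C-terminal carbonyl oxygen (the
same placement formula used at every other residue) -- and
`extractTorsions()` inverts both. This keeps build/extract round-trips
exact at every residue and lets Stage II search all $n$ junctions
uniformly; couplings involving H(1) or O($n$) then constrain the proxies
exactly as interior couplings do.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `gridStep` | 10 deg | Stage-I torsion grid step (must divide 360) |
| `depth` | 1000 | beam width: fragments carried between steps |
| `tolerance` | 20 % | dynamic decimation band above the best score |
| `epsAbs` | 0.01 Hz | dynamic floor for near-zero best scores |
| `staticThreshold` | Inf Hz | static-mode absolute score cutoff |
| `bucketWidth` | 10 deg | static-mode representative bucket |
| `half_width` / `step` | 25 / 5 deg | dihedral-restraint expansion |
| mining `window` | 6 | rolling k-mer length |

The beam must be at least as wide as the set of data-consistent
candidates at the most ambiguous early junction -- RDCs carry inherent
orientational degeneracies that only resolve as data accumulate, so a
beam narrower than the first steps' tie set can silently drop the true
path. With the $15^\circ$ grid (240 Ramachandran-filtered candidates for
a general residue) a depth of 300 is a practical floor.

## Simulated data and fixtures

`simulateRdcs()` back-calculates one coupling per residue, vector type
and medium from a structure and adds seeded uniform noise
$U(-E, E)$ (so the added deltas have RMS $E/\sqrt 3$). The default
tensors (`defaultTensors()`) have principal order parameters in the
commonly observed $10^{-4}$--$10^{-3}$ range, the second rotated by
Euler angles $(40^\circ, 50^\circ, 60^\circ)$ so the two frames are
independent. `makeFixture()` ships four deterministic synthetic
targets -- `helix15`, `helix_turn_helix20`, `hairpin12` and the
40-residue two-helix stand-in `synthetic_helical40` -- with torsions on
a $15^\circ$ grid and datasets at $E \in \{0, 1, 2, 4\}$ Hz under fixed
seeds.

What the generator emulates: geometry-consistent couplings of arbitrary
backbone vector types, several media, uniform spectral noise, missing
prolines and chain-end vectors. What it does not: internal dynamics
(time-averaged couplings), per-residue variation of bonded geometry or
cis-prolines, systematic referencing errors, or realistic missing-data
patterns. Passing the synthetic suite therefore demonstrates the
correctness and robustness of the estimator and search, not performance
on experimental depositions.

## Evaluation protocol and problem sizes

The packaged evaluation (tests and `scripts/acceptance.R`) folds the
fixtures from six-type, two-medium data with grid step $15^\circ$ and
depth 300, using a 20% decimation band on clean data and a 50% band on
noisy data -- noise shuffles the early ranking of near-equivalent
fragments by more than 20% of the best score, and the band has to
exceed that churn for the true path to survive (this is precisely the
adaptivity argument for a percentage threshold): noise-free recovery of `helix15`/`helix_turn_helix20`
(sub-0.5 A), five $\pm 1$ Hz replicates (fitness bounded by the
$E/\sqrt3$ noise floor plus fit slack), a $\pm 4$ Hz fold of the first
20 residues of `synthetic_helical40`, the full 40-residue stand-in from
only the two newly supported vector types [H$\alpha$--C$\alpha$,
N--C$\alpha$], and a sparse single-medium N--H fold with and without
self-mined dihedral restraints. These sizes are the package's own
evaluation choices: they are large enough to exercise every code path
(turns, glycines, cross-residue vectors, under-determined openings) while
keeping the whole suite reproducible on a single CPU in minutes.

## Mined dihedral restraints

`mineFragments()` fragments every corpus chain with a rolling window
(k = 6 by default) and stores each k-mer's $(\phi,\psi)$ series;
`predictDihedrals()` pools, for every query residue, the observations of
all matching windows covering it and predicts the mode of a
$10^\circ$-binned 2-D histogram. The mode was chosen over a circular
mean deliberately: pooled Ramachandran distributions are multimodal and
a mean of helix and sheet observations would land in forbidden
territory. Ties break to the lexicographically lower bin; bin centers
are reported. Predictions expand to Stage-I candidate lists at
$\pm 25^\circ$ in $5^\circ$ steps (121 pairs), replacing the full grid
for restrained residues. Pooling is per position, not per amino-acid
type -- with small local corpora, position-specific windows are better
determined; against a very large heterogeneous corpus a per-type
aggregation could behave differently.

## File formats

NEF restraint lists are read and written as STAR documents restricted to
`nef_rdc_restraint_list` saveframes (one per alignment medium; media are
numbered in file, then frame order). The legacy fixed format is a
12-column whitespace table, one residue per row -- six couplings then six
errors, sentinel 999 for missing -- with the pinned column order
C$'$(i)--N(i+1), C$'$(i)--H(i+1), N--H, C$\alpha$--C$'$,
C$\alpha$--H$\alpha$, C$'$--O (row $i$ carries the couplings of residue
$i$'s peptide plane; the historical column layout is not normative, so
this convention is documented rather than inferred, and
`readLegacyRdc()`'s source is the reference). The C$'$--O pair is
treated as a $^{13}$C--$^{17}$O coupling for its $D_{\max}$. Run
configurations are INI files with `#`/`;` comments; Stage-II traces are
line-oriented `.out` files replayable by the `pdbgen` subcommand.

## Numerical choices

* Least squares via SVD pseudo-inverse, relative cutoff $10^{-10}$ on
  singular values; the C++ pool scorer uses the eigendecomposition of
  the $5\times5$ normal matrix with the matching cutoff
  ($10^{-20}$ relative on eigenvalues). The normal-equation residual
  identity cancels catastrophically near zero, so incremental and
  from-scratch scores agree to $\sim 10^{-7}$ Hz rather than machine
  precision (the audit asserts this); Stage-I ranking, where exact zeros
  matter for tie structure, evaluates residuals directly from the rows
  instead.
* Superposition for bb-rmsd (over N, C$\alpha$, C$'$) by the Kabsch
  closed form with the determinant correction, so reflections are never
  selected.
* Dihedrals follow the IUPAC sign convention, wrapped to
  $(-180^\circ, 180^\circ]$; collinear atom quadruples raise an error
  rather than returning an arbitrary angle.
* H$\alpha$ is placed on the L-amino-acid side of the N--C$\alpha$--C$'$
  plane; glycine gets that single H$\alpha$, proline no amide H (its
  N--H couplings are rejected at parse time).
* PDB coordinates carry three decimals, so structures round-tripped
  through PDB files agree to $\sim 10^{-3}$ A, not machine precision.

## Limitations

Static structures only: no time-averaging of the dipolar interaction, no
multi-conformer tensors. Single chain, backbone only, trans peptide
bonds. The search is guaranteed deterministic but not globally optimal:
with noise of the order of the signal (e.g. $\pm 4$ Hz on a 15-residue
helix whose weaker vector types carry couplings of only a few Hz) the
globally best-fitting structure can fall outside any practical beam, and
widening the beam is the only remedy the method offers. Experimental
reproduction of published per-protein numbers additionally depends on
the depositors' order tensors, which are not public; the packaged
evaluation therefore targets regimes, not digits, and all of its inputs
are generated by the package itself.
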