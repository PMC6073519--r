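---
title: "Elastic-network normal modes of finite-size DNA ring and buckyball assemblies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Elastic-network normal modes of finite-size DNA ring and buckyball assemblies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(dnanma)
```

## The model

`dnanma` computes low-frequency vibrational modes of coarse-grained DNA
nanostructure assemblies: 12-tile 2D rings (open and closed variants at two
diameters) and the 60-tile three-point-star (3PS) buckyball cage, plus
desk-scale fixtures built with the same machinery.

The mechanical model is a mass-weighted chemical elastic network.  Each
nucleotide is reduced to six or seven representative atoms — the backbone
P, C4' and C1' sites plus three base sites for pyrimidines or four for
purines (the glycosidic nitrogen and the Watson–Crick edge sites).  Every
non-representative atom's mass is lumped onto the nearest representative
bead of the same nucleotide, so nucleotide and total masses are conserved
exactly.  Beads are connected by springs whose constants depend on the
chemical bond class:

| bond class        | spring constant |
|-------------------|-----------------|
| van der Waals     | 7 N/m           |
| hydrogen (and ion)| 70 N/m          |
| covalent (and disulfide) | 700 N/m  |

Covalent springs run along each strand's backbone chain and across
designed strand linkages (junction crossovers); hydrogen springs join the
Watson–Crick bead sites of every paired base (including hybridized sticky
ends); van der Waals springs connect all remaining bead pairs within a
0.8 nm cutoff.  Each pair carries one spring — the strongest class wins.

About the equilibrium geometry, the potential of a spring between beads
$i$ and $j$ is $\tfrac12 k_{ij}(\lVert x_i - x_j\rVert - r_{ij})^2$, whose
Hessian contributes $k_{ij}\,\hat e\hat e^{\mathsf T}$ blocks with
$\hat e$ the unit inter-bead vector.  With the diagonal lumped-mass matrix
$M$ the equation of motion is $M\ddot\delta + K\delta = 0$ and the modes
solve the generalized eigenproblem $Kv = \omega^2 Mv$.  A unit
subtlety worth stating: with lengths in nm, masses in amu and spring
constants in N/m, the conversion 1 N/m = 602.2140857 amu/ps$^2$ makes the
eigenvalues come out as $\omega^2$ in (rad/ps)$^2$; reported wavenumbers
use $\tilde\nu = \omega / (2\pi c)$.

## Structure generation

The builders produce idealized, exactly symmetric coordinates:

* **Nucleotide templates.** Bases are regular fused polygons (bond
  0.139 nm) oriented so that all Watson–Crick H-bond site pairs span
  0.29 nm; backbone atoms sit at fiber-like cylindrical positions; implicit
  hydrogens are folded into their heavy atoms (united-atom masses, exact
  residue compositions).  The base-pair template is exactly twofold
  symmetric (dyad along its y axis), which the assembly constructions
  exploit.
* **Rings.** Inner and outer circles are built as circular arcs whose
  duplex axis follows the circle; per-tile twist is quantized to whole
  helical turns (34.3–36°/bp) so the ring closes with exact C12 symmetry.
  Base-pair counts per tile derive from the target diameters under
  0.34 nm/bp rise: the inner diameter fixes the inner arc directly; the
  outer diameter is measured over atoms, so the maximum template atom
  radius (1.04 nm) is subtracted first.  That yields 10 + 21 bp/tile for
  the 29/13 nm rings and 31 + 41 bp/tile for the 55/40 nm rings.  Radial
  bridges connect the circles; bridge ends sit 1.30 nm from the arc axes
  so van der Waals contacts couple each junction (links alone would leave
  the bridge free to spin about its own axis), and the two designed strand
  links per junction cross over ±2 bp along the arc like a
  double-crossover.  Sticky-end nicks (6 nt) interrupt both circles at
  every tile boundary; open-form tiles carry an additional 8-nt
  single-stranded domain in the outer circle.
* **Cages.** Tile centers are the orbit of one truncated-icosahedron
  (or truncated-tetrahedron, for the tetrahedral mini-ball fixture) vertex
  under the rotation group, generated programmatically from two
  generators.  Each tile-graph edge carries one continuous duplex along
  the chord between neighboring centers, built exactly dyad-symmetric
  about the radial axis through the edge midpoint (palindromic sequence,
  twist phase zero at the midpoint); the central sticky base pairs split
  strand ownership between the two tiles.  This construction makes copy
  $i$ exactly equal to rotation $i$ applied to copy 1 — the property the
  symmetry-reduced solver verifies and relies on.  Default cage
  dimensions come from the design scheme's ~80 nm diameter: 18 bp arms,
  2-nt sticky ends (three-point-star polyhedra use very short sticky
  ends) and 4-nt single-stranded T-loops at each vertex hub.  T-loops are
  placed on non-crossing azimuth-matched paths between arm strand
  termini, with templates re-centered on C1' and compressed toward the
  path (a single strand has no helix cross-section); each loop end links
  to both strand termini of its arm end, because single-point anchoring
  would leave edge duplexes free to spin.
* **Validation.** `validate_structure()` reports every base pair's H-bond
  site distances (in-band 0.25–0.35 nm by construction), per-interface
  sticky-end pairing counts, and steric clashes among atoms more than
  three steps apart in the backbone/pairing/junction connectivity graph
  (threshold 0.25 nm).  All shipped builders produce clash-free models.

## Solvers

Small systems (3N ≤ 3000) are diagonalized densely.  Larger ones use
shift-inverted Lanczos iterations (ARPACK) on the sparse mass-weighted
Hessian with a sparse Cholesky factorization; the six rigid-body modes are
deflated analytically (they are known exactly from the geometry), because
without deflation the rigid cluster at $1/\sigma$ swamps the soft elastic
modes.  Eigenvectors are returned mass-orthonormal with a deterministic
sign convention.  Rigid modes are detected at a relative eigenvalue
threshold of $10^{-8}$; more than six signals a disconnected or
mechanism-bearing network and raises a warning.

The symmetry-constrained path partitions a $q$-copy assembly into
congruent subunits (verified bead-by-bead, positions and masses), forms
the reduced stiffness $K_{\mathrm{red}} = K_{1,1} + \sum_{i\ge2}
K_{1,i} R_i$ from subunit-1 row blocks and the group rotations, and solves
the $3m$-dimensional problem with the subunit mass block.  Because the
printed reduced operator is not symmetric in general, the solver uses
$\tfrac12(K_{\mathrm{red}} + K_{\mathrm{red}}^{\mathsf T})$ and reports
the asymmetry residual, which vanishes (≈ $10^{-16}$) for exactly
symmetric networks.  Reduced modes expand through $\Delta_i = R_i\Delta_1$
— the totally symmetric representation, where the cage breathing and
torsional motions live — and every retained eigenpair is verified against
the full operator by its Rayleigh quotient and residual.  On C3/C4/C6 toy
rings the reduced spectrum matches the dense full spectrum to better than
$10^{-6}$ relative.  Rings are analyzed by full-model NMA by default:
their seesaw and zigzag modes live outside the symmetric subspace.

## Mode taxonomy

The classifier scores each non-rigid mode by squared mass-weighted
projection onto small template bases, normalized by mode energy; scores
are invariant to sign, scale and the assembly's symmetry group, and
numerically degenerate eigen-groups are scored jointly on their invariant
subspace (stable under solver-arbitrary remixing).  Ring categories:
out-of-plane translation (O-T) and rotation (O-R, the seesaw) of the inner
circle, in-plane translation (I-T), outer-circle zigzag (z-displacement at
angular wavenumber ≥ 2), and coherent (spiderlike) or angularly modulated
(mixed-spiderlike) bridge bending.  Cage categories: overall breathing
(uniform-sign radial coherence), local breathing (radial energy ×
spatial concentration, the "spiky" pattern), and torsional (per-arm
twisting about arm axes).  Tile categories: out-of-plane arm bending and
in-plane tweezer motion (linear and quadratic arm profiles, disjoint from
the sticky-end categories), and bending or twisting localized at sticky
ends.  A mode whose top two scores differ by less than 0.15 is labeled
"mixed".  These score formulas are this package's own quantitative
rendering of motion classes that were originally described pictorially;
there is no reference classifier to compare against.

## What the defaults reproduce, and what they do not

With default parameters the package reproduces, from scratch: the ring
diameters (29/13 and 55/40 nm after rounding), the full cage topology
(60 vertices, 90 edges, 12 pentagons + 20 hexagons, Euler characteristic
2), clash-free assembly with complete sticky-end hybridization, exactly
six rigid modes on every assembled structure, and the flat-tile taxonomy
(mode 1 bending, tweezer-like motion at mode 3).

The mode *ordering* of the assemblies matches the reported tables only
partially, and deliberately so.  The reported ring hierarchy — inner-circle
suspension modes first, outer-circle zigzag later — requires the
inner-circle suspension to be roughly an order of magnitude softer than
the rim's bending stiffness while staying torsionally constrained.  A
junction-stiffness sensitivity analysis (scaling the junction-crossing
springs) shows our architecture reaches the reported ordering only in a
regime that point-contact junctions between single duplexes cannot
provide: that compliance anisotropy comes from the tiles' internal
multi-helix crossover architecture, which is encoded in the base sequences
shown only as figure artwork.  Our single-duplex spoke-wheel reproduces
all six ring motion families with correct shapes but interleaves zigzag
below the seesaw pair for the closed designs (the open R1 design does
place O-T first).  Similarly, the cage places one tangential tile-shear
mode below the breathing pair.  A two-helix bundle-arm variant
(`star_design(bundle = 2)`, whose per-tile bead count incidentally matches
the reported 102,960/60) is included for exploration but does not close
the gap and costs twice as much to solve, so it is not the default.  The
absolute frequency values likewise depend on the unavailable sequences;
the package reports its own (in rad/ps and cm⁻¹) without claiming
correspondence.

## Numerical choices and degenerate inputs

* Zero-mode threshold: relative, $10^{-8}$ of the largest computed
  eigenvalue (overridable).
* Shift for the sparse factorization: $10^{-6}$ × mean diagonal of the
  mass-weighted Hessian; rigid-mode deflation makes the result insensitive
  to this choice.
* Degeneracy grouping for labeling: relative eigenvalue gap $10^{-4}$.
* Lumping ties (atoms exactly equidistant from two beads by symmetry)
  break by bead rank after rounding $d^2$ at $10^{-9}$, so symmetric
  copies lump identically.
* Zero-length springs, non-positive masses, unknown bases, inconsistent
  partitions and non-spherical tile graphs raise classed errors
  (`dnanma_*` conditions).
* Problem sizes: the test and acceptance workloads run the four rings
  (6–15 × 10³ beads, sparse path), the cage via symmetry reduction
  (79 × 10³ beads, reduced order ~4 × 10³), the flat tile densely, and
  dense-oracle cross-checks on ≤ 500-bead toy rings — all chosen so a
  complete run stays comfortably on one desktop core.

## Fixtures and what passing tests show

`generate_fixture()` provides a two-bead dimer (closed-form eigenvalue
$2k/m$), a deliberately floppy straight chain (exercises the
disconnection warning), C3/C4/C6 toy rings small enough for dense
full-spectrum oracles, and the tetrahedral 12-tile mini-ball (Euler check,
rigid-mode count, cage scorers).  These fixtures emulate the *structure*
of the real assemblies — symmetric tiling, sticky-end interfaces, mixed
bond classes — but not their sequences, solvent, or thermal amplitudes;
passing tests demonstrate internal correctness of geometry, reduction and
classification machinery, not agreement with experiment.
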