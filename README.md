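# dnanma

Normal mode analysis of finite-size DNA nanostructures with a
mass-weighted chemical elastic network and a symmetry-constrained
reduction.

## What it does

Self-assembled DNA nanostructures — tile rings tens of nanometers across,
polyhedral cages of dozens of tiles — are too large for routine all-atom
dynamics, yet their low-frequency collective motions (breathing, seesaw,
zigzag, bridge bending) are exactly what determines their mechanical
stability.  `dnanma` builds coarse 3D models of such assemblies and
computes those motions:

* **Structure generation.** Parameterized builders for the four 12-tile
  2D ring designs (open/closed, 29/13 nm and 55/40 nm diameters), the
  flat three-point-star (3PS) tile, and the 60-tile buckyball cage
  (truncated-icosahedron topology, tiles placed by the icosahedral
  rotation group generated programmatically).  Assemblies are exactly
  symmetric: copy *i* equals rotation *i* applied to copy 1.  Validation
  reports Watson–Crick H-bond lengths, sticky-end pairing per tile
  interface, and steric clashes.
* **Coarse-graining.** Six or seven representative atoms per nucleotide
  (P, C4', C1' plus base sites), lumped masses that conserve every
  nucleotide's mass exactly, and a typed spring network: covalent
  (700 N/m) along backbones and designed junction links, hydrogen
  (70 N/m) between paired bases, van der Waals (7 N/m) within a 0.8 nm
  cutoff — the 1:10:100 chemical-bond ratio.
* **Normal modes.** The generalized eigenproblem `K v = omega^2 M v`,
  solved densely for small systems and by shift-inverted Lanczos
  iterations with analytic rigid-mode deflation for large ones; mode
  vectors come back mass-orthonormal with six rigid-body modes accounted
  for.  For symmetric assemblies, a symmetry-constrained reduction solves
  a single-subunit problem (`K_red = K11 + sum K1i Ri`, order reduced by
  the group order q) and expands modes back to the full assembly, with
  every eigenpair verified against the full operator.
* **Mode taxonomy.** Quantitative classifiers label ring modes
  (out-of-plane translation/rotation of the inner circle, in-plane
  translation, zigzag, spiderlike and mixed-spiderlike bridge bending),
  cage modes (overall/local breathing, torsional) and tile modes
  (bending, tweezer-like, sticky-end bending/twisting).

## Worked example

```r
library(dnanma)

des  <- ring_design("r1c")        # closed-form R1 ring, 12 tiles
ring <- build_ring(des)
measure_ring_diameters(ring)
#> $outer
#> [1] 29.34883
#> $inner
#> [1] 12.77457

validate_structure(ring)
#> validation_report
#>   H-bond sites: 1260, range 0.290-0.290 nm (band 0.25-0.35)
#>   sticky interfaces: 12, base pairs per interface: 12
#>   min non-bonded distance: 0.436 nm; clashes (< 0.25 nm): 0

cg <- coarse_grain(ring)          # 6480 beads, ~88k springs
ms <- solve_modes(cg, n_modes = 16)
ms <- label_modes(ms, cg, "ring")
head(data.frame(label = ms$labels, freq_cm1 = ms$freq_cm1[-(1:6)][1:10]), 4)
```

The outer diameter is twice the maximum atom radius about the ring axis
(29.3 nm, i.e. the designed 29 nm), the inner diameter twice the minimum
radial distance of inner-circle duplex-axis points (12.8 ≈ 13 nm).  The
validation block confirms all Watson–Crick H-bond sites sit at 0.29 nm,
every tile interface hybridizes its full 12 sticky base pairs, and no two
non-bonded atoms approach within the 0.25 nm clash threshold.  The labeled
modes list the softest collective motions with their wavenumbers.

For the cage:

```r
ball <- build_buckyball()
tg   <- tile_graph(ball)
assembly_topology(tg$centers, tg$interfaces)
#> $vertices [1] 60   $edges [1] 90   $faces [1] 32
#> $faces_by_size   5: 12   6: 20

cgb <- coarse_grain(ball)         # ~79k beads
msb <- scenm_modes(cgb, icosahedral_group(), n_modes = 12)  # reduced order ~4k
msb$asymmetry                     # ~1e-16: the network is exactly symmetric
```

A thin command-line front-end ships in `inst/cli/dnanma`
(`build-ring`, `build-buckyball`, `validate`, `topology`, `coarse-grain`,
`nma`, `scenm`, `classify`, `run`).

## Scope notes

The exact tile base sequences exist only as figure artwork in the source
designs, so the builders are parameterized by per-segment base-pair
counts derived from the published dimensions; absolute frequencies and
the finer ordering of nearly degenerate mode families depend on those
sequences and are discussed honestly in the methods vignette
(`vignettes/dnanma-methods.Rmd`).
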