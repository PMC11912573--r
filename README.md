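# pentatube

Geometric analysis of pentamer-based protein cages and nanotubes.

Engineered cage-forming homopentamers (circularly permuted lumazine
synthase variants being the canonical example) assemble into dodecahedral
and expanded spherical cages, straight nanotubes made of helical strips of
pentamers, and twisted tubes of compacted helical threads. Because the
building block is one C5-symmetric pentamer, the polymorphism is a problem
in geometry. `pentatube` is for structural biologists and protein
engineers who want to quantify and rationalize such assemblies:

* **AngelaR-style angle measurement** — the bending angle between two
  capsomers is 180° minus the angle between their plane normals (180° =
  flat); the torsion angle is the signed rotation about the
  centre-to-centre axis separating one normal from the plane of the other
  normal and that axis (0 = untwisted). Works on synthetic assemblies or
  PDB files with chains grouped into capsomers
  (`bendingTorsion`, `detectContacts`, `measureStructure`).
* **Straight-tube lattice model** — pentagons with vertices at the fifth
  roots of unity tile the plane in strips (strip vector P⃗, strip-to-strip
  vector H⃗ = (a, b), b = 2.18 circumradius units for the biological
  tube). Four 2-fold edge-contact conditions plus the tube-closure
  equality n_p·P_y = n_h·b determine the tiling for each helicity n_h and
  periodicity n_p; tilings are screened for pentagon overlap, missing
  contacts and flip-requiring (mirror) patterns, scored by percentage edge
  contact, and wrapped onto a cylinder
  (`solveLattice`, `enumerateTilings`, `wrapToCylinder`).
* **Twisted-tube helix builder** — chains built by iterating one rigid
  bending/torsion step with a free attachment parameter; exact screw
  symmetry, exact angle round-trips, thread-gap metrics and the
  gap-vs-angle scan (`buildHelix`, `threadMetrics`, `gapAngleScan`).
* **Interaction-network rewiring** — capsomer contact networks with
  helical symmetry classes and pentagon-edge engagement constraints;
  exhaustive enumeration of alternative architectures
  (`networkFromAssembly`, `enumerateRewirings`).
* **Synthetic assemblies** — dodecahedra, spherical cage shells, noisy
  variants, and a pseudo-atom PDB writer/reader so everything above is
  testable without a structural database (`makeDodecahedron`,
  `makeSphereCage`, `addNoise`, `writeStructure`).

## Worked example

```r
library(pentatube)

sol <- solveLattice(latticeParams(b = 2.18, nh = 3, np = 4))
sol
#> LatticeSolution (b = 2.18, n_h = 3, n_p = 4): feasible
#>   a = 0.453484, H = (0.4535, 2.1800), P = (3.0528, 1.6350), theta = 50.08 deg
#>   mean contact 40.40% (per class: intra.ahead 81.8%, intra.behind 27.1%,
#>                        inter.up 40.6%, inter.down 52.6%)

tube <- wrapToCylinder(sol, nTurns = 2)
threadMetrics(tube)
#> TubeMetrics [helix]: 3 thread(s), rise/step 1.6350, rise/turn 6.54,
#>                      radius 1.727, thread gap 0.0142

ct <- detectContacts(tube)
sort(unique(round(ct$torsion_deg, 1)))
#> -29.7 -27.0  24.3  27.4
```

The solved (3,4) tiling is the experimentally observed straight tube: the
strip offset a and the strip angle θ follow from b = 2.18 alone, the
wrapped tube has three helical threads, and the four interface classes
split into intrathread contacts with positive torsions (+24.3°, +27.4°)
and interthread contacts with negative torsions (−29.7°, −27.0°) — the
sign pattern that distinguishes thread-forming from thread-docking
interactions, with every bending angle above the dodecahedral cage value
of 116.565°. `enumerateTilings(2.18, 1:6, 1:10)` shows that for each
helicity the contact-maximizing periodicity is the smallest feasible one,
that (3,4) is optimal for three threads (40.4% mean edge contact), and
that the n_h = n_p diagonal would require flipped pentagons, which
asymmetric protein interfaces cannot supply.

## Package layout

S4 classes (`CapsomerFrame`, `Assembly`, `LatticeSolution`,
`ContactNetwork`, `HelixSpec`, `TubeMetrics`, ...) with validity checks,
accessors and `show` methods; the methods vignette
(`vignettes/pentamer-tube-geometry.Rmd`) documents the model, its
conventions (torsion sign, flip criterion, engagement constraints) and its
numerical choices.
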