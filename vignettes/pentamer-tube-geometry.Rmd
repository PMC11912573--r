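---
title: "Geometry of pentamer-based cages and nanotubes"
author: "pentatube"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Geometry of pentamer-based cages and nanotubes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pentatube)
```

## The problem

Cage-forming homopentameric proteins such as engineered lumazine synthase
variants assemble into a spectrum of architectures: dodecahedral and larger
spherical cages, straight nanotubes built from helical strips of pentamers,
and twisted tubes of compacted helical threads. Because the building block
is always the same C5-symmetric pentamer, the whole spectrum can be studied
geometrically: a pentamer is reduced to a planar regular pentagon (its
`CapsomerFrame`), and architectures differ only in how neighbouring
pentagons are positioned relative to one another. `pentatube` implements
the four geometric tools needed for that analysis: pairwise bending/torsion
angle measurement, a planar lattice model of straight tubes, an iterative
helix builder for twisted tubes, and interaction-network rewiring, together
with synthetic assembly generators that make all of it testable without any
structural database.

Throughout the package the pentagon circumradius is the unit of length;
a `scale` factor converts to physical units (e.g. Å) only when structures
are written to file.

## Bending and torsion between two capsomers

For two frames with centres joined by the unit vector $d$ and plane normals
$n_a$, $n_b$ (co-oriented so their components perpendicular to $d$ agree):

* if $n_a$, $n_b$ and $d$ are coplanar, the **torsion** is zero and the
  **bending** angle is $180^\circ$ minus the angle between the normals, so
  that $180^\circ$ means a flat, coplanar contact;
* otherwise the torsion is the signed angle (right-hand rule about $d$) by
  which $n_b$ is rotated out of the plane spanned by $n_a$ and $d$, and the
  bending angle is evaluated after rotating $n_b$ back into that plane.

Two conventions deserve comment. First, the torsion sign is fixed by the
right-hand rule about $d$ and flips globally if the normal orientation
convention is reversed; only relative signs are therefore comparable
between implementations. Second, the signed torsion is *invariant* under
swapping the two frames: reversing the order reverses $d$ together with the
roles of the normals, exactly as the signed backbone torsion of a molecular
chain does not change when the chain is read backwards. (A 2-fold-related
pair makes this concrete: the symmetry exchanges the two frames, so any
order-antisymmetric definition would force all isologous torsions to zero,
while real 2-fold pairs can be visibly twisted.) Bending is symmetric in
the two frames.

```{r angles}
dod <- makeDodecahedron(1)
ct <- detectContacts(dod, threshold = 0.2)
nrow(ct)                      # 30 cage edges
range(ct$bending_deg)         # the dodecahedral bending angle
180 / pi * acos(-1 / sqrt(5)) # its analytic value
```

Contacts are detected by the minimum vertex-ring edge-to-edge distance,
with a default threshold of 0.15 edge lengths; the paper-scale structures
separate cleanly (true contacts sit at ring gaps below 0.12 edge lengths,
the next-nearest dockings at 0.40). The threshold is configurable for
noisy or re-measured structures, whose fitted rings are built from subunit
centroids and are therefore slightly smaller than vertex rings.

## The straight-tube lattice model

Straight tubes are modelled as a planar tiling rolled onto a cylinder. The
unit cell contains two pentagons: the reference pentagon (circumradius 1,
vertices at the fifth roots of unity) and a partner rotated by 180 degrees.
Pentagons of opposite orientation can share partial, collinear edges, and
each such contact places the 2-fold centre of the pair on the shared edge
line. The tiling is generated by the strip vector $P$ (along a helical
thread) and the strip-to-strip vector $H = (a, b)$; the axial offset
$b = 2.18$ circumradius units matches the biological tube.

Four contact classes define the pattern: intrathread ahead/behind contacts
on edges 1 and 3 (the pair of edges exchanged by the 144-degree pentagon
rotation, which also carries the contact point $R_1$ on edge $P_1P_2$ to
the point $T$ on edge $P_3P_4$ with $|P_4T| = |R_1P_2|$; see
`edgeContactConstruction()`), and interthread contacts on edges 2 and 5
with the strips above and below. Because a 2-fold contact on edge $e$ is
the linear condition $\hat n_e \cdot q = 2\,\mathrm{apothem}$ on the class
offset $q$, the four contact conditions plus the tube-closure equality
between the axial components, $n_p P_y = n_h b$, form a square linear
system: given $(b, n_h, n_p)$ the construction is fully determined, and
$a$ has a closed form. The test suite still cross-checks it against a
bracketed root scan of the closure residual, the numerically natural
alternative.

A solved combination is kept only if all four contacts have positive edge
overlap and no pentagon interiors intersect:

```{r lattice}
sol <- solveLattice(latticeParams(2.18, 3, 4))
sol
```

The contact percentage of an edge is the proportion of its length covered
by collinear neighbour edges; both per-edge values and their mean over the
five edges are reported, since an average over contacting edges only would
be the other defensible choice.

**Flipped pentagons.** A regular pentagon is achiral as a shape, so no
positional argument alone can demand mirrored tiles. What distinguishes
realizable patterns is interface usage: combinations on the
$n_h = n_p$ diagonal admit no tiling with four distinct contact edges, but
do admit one in which a single pentagon edge is re-used for two
inequivalent contacts (a mirror-symmetric arrangement with $a = 0$). A
protein pentamer binds through asymmetric interaction surfaces, so one
edge cannot engage in two different contact geometries unless part of the
lattice presents mirrored - flipped - faces. `solveLattice()` therefore
reports such combinations as `flip_required`, biologically forbidden:

```{r flip}
subset(enumerateTilings(2.18, 1:6, 1:10), n_h == n_p | feasible)[
  , c("n_h", "n_p", "feasible", "flip_required", "mean_contact_percent")]
```

Two enumeration results are the package's headline numbers: for every
helicity the contact-maximizing periodicity is the smallest feasible one,
and the maxima are $n_p = 4$ at $n_h = 3$ (the observed tube) and
$n_p = 5$ at $n_h = 4$. Note also that infeasibility can arise either from
interpenetrating pentagons (tight strip offsets, e.g. $b = 1.5$) or from
contacts that cannot form because closure spreads the strip out (e.g.
$n_p = 1$); both are reported as geometrically forbidden.

`wrapToCylinder()` rolls a feasible solution so that the identification
vector $C = n_p P - n_h H$ (horizontal by the closure equality) becomes one
circumference; pentagons are placed rigid and tangent, normals radial -
the model does not bend the pentagons, which is one reason measured 3D
ring gaps are larger than their planar counterparts. The wrapped (3,4)
tube reproduces the experimental angle signature without any tuning:
intrathread torsions positive, interthread torsions negative, and all
bending angles above the dodecahedral cage value:

```{r wrap}
tube <- wrapToCylinder(sol, nTurns = 2)
threadMetrics(tube)
ct <- detectContacts(tube)
summary(ct$bending_deg)
range(ct$torsion_deg)
```

## The twisted-tube helix builder

`buildHelix()` grows a chain by applying one fixed rigid step per pentamer:
place the incoming pentamer by a 180-degree in-plane rotation about the
attachment point (a 2-fold contact at a free position `attach` along the
interface edge, default the midpoint), fold about the shared edge line to
the requested bending, and twist about the centre-to-centre axis to the
requested torsion. Each pentamer receives its predecessor on interface
edge 1 and emits its successor from edge 3 - the same 144-degree edge pair
as in the straight-tube strips - so the step is one fixed rigid motion and
the chain has exact screw symmetry. For off-centre attachment the raw fold
and twist angles differ from the measured angles (the centre-to-centre
axis tilts out of the fold plane), so the two construction angles are
solved with a damped Newton iteration until `bendingTorsion()` returns the
requested pair to $10^{-10}$ degrees; targets outside the reachable window
(sharp bending far from the edge midpoint) raise an error rather than
silently approximating.

Zero torsion makes all rotation axes of the step concurrent, so the chain
closes into a ring with no helical rise - the geometric reason why
torsion-free pentamer interactions can only produce ring-like (cage)
arrangements, and why the tube-forming variants need a torsion-imparting
interface. In the flat limit (bending $180^\circ$) the constant-step chain
is a planar decagonal ring rather than an infinite straight strip; a
straight strip would need the alternating step of the lattice model, which
would break the single-operation screw symmetry this module is about.

```{r helix}
h <- buildHelix(helixSpec(bending = 140, torsion = 20, nSteps = 24))
threadMetrics(h)
```

`gapAngleScan()` sweeps a path of angle pairs and tabulates the thread gap
(closest ring-ring approach between successive helical turns). Along the
default path - bending 154 to 136 degrees against torsion 0.5 to 30,
spanning the compacted regime to widely spaced turns at a desk-scale 24
pentamers per helix - the gap grows monotonically as bending decreases and
torsion increases, the trend seen across the twisted-tube family:

```{r scan}
scan <- gapAngleScan(nSteps = 22)
scan[, c("bending", "torsion", "thread_gap", "rise_per_turn")]
```

## Interaction-network rewiring

`networkFromAssembly()` reduces an assembly to its capsomer interaction
network: nodes at pentamer centres, weight-1 edges for contacts, and
candidate weight-0 edges for next-nearest pairs within twice the contact
threshold (for the (3,4) tube, the two same-sublattice dockings along
$\pm H$ at ring gaps of 0.40 edge lengths; the network tests use a 0.25
edge-length threshold so the candidate band reaches them). Edges are
grouped into helical symmetry classes - orbits of the lattice translations
for wrapped tubes, geometric-signature clusters otherwise - and each class
records which pentagon edges it engages: contact classes their collinear
contact edge, docking classes every edge within a slack of the minimum
ring distance, so a corner docking engages both flanking edges.

`enumerateRewirings()` then searches all symmetry-respecting weight
assignments that a pentamer with five asymmetric interfaces could realize:
no two contact classes may engage the same pentagon edge, no node exceeds
five contacts, the contact graph must stay connected, and the contact set
must be maximal (assembly is adhesion-driven, so a contact that can form
does). Maximality is our sharpening of the qualitative "connectivity"
requirement; without it every sub-network of the input would count as an
architecture. For the (3,4) tube the result is unique: the intrathread
ahead and interthread-up classes (which the corner dockings collide with
on edges 1 and 2) are deleted and both docking classes are gained - two
deleted, two gained - and applying the same enumeration to the rewired
network returns the straight tube, so the transformation is reversible:

```{r network}
net <- networkFromAssembly(tube, threshold = 0.25 * 2 * sin(pi / 5))
net
length(enumerateRewirings(net))
```

In the unrolled drawing the contact network tiles the lattice with
quadrilaterals; adding one docking diagonal splits alternate
quadrilaterals into triangle pairs - the squashed-hexagon picture of two
triangles and one square - and adding both docking classes triangulates
the blueprint completely (`networkFaces()`). The rewired architecture
realizes those dockings as true contacts only after the threads compact,
which is a 3D deformation the network layer does not model; the
triangle-based blueprint therefore belongs to the twisted tube's own
geometry, not to the straight-tube embedding of the rewired graph.

## Synthetic assemblies and structure files

The fixture generators provide the study conditions for every test:
`makeDodecahedron()` (12 pentamers, 60 subunits, all 30 contacts at the
analytic bending angle $\arccos(-1/\sqrt 5) \approx 116.565^\circ$ with
zero torsion), `makeSphereCage()` (Fibonacci-spiral shells; n = 12 is
special-cased to the exact icosahedral arrangement), `addNoise()`
(isotropic Gaussian subunit displacements with frame refitting, bit
reproducible for a fixed seed) and `writeStructure()`/`measureStructure()`
(a pseudo-atom PDB dialect: residue number = capsomer, chain = subunit,
two carbon pseudo-atoms per subunit at its centroid and pentagon vertex).
In cage series whose pentamer count grows with the shell surface - as in
the 12/24/36-pentamer cages - the mean nearest-neighbour bending angle
increases with cage size; at fixed pentamer count the angular separations,
and hence the bending angles of tangent pentamers, are scale-invariant, so
the trend is a statement about area-scaled series.

What the fixtures deliberately do not emulate: atomic detail and side-chain
flexibility, the quasi-symmetric deformations of real capsomers, cryo-EM
noise structure (noise here is isotropic and independent), and partial
occupancy or broken lattices. Passing tests therefore validate the
geometric machinery, not the structure-determination pipeline that would
feed it real coordinates.

## Numerical choices

* Planarity/regularity tolerances: $10^{-6}$ model units for exact
  constructions; frame validity allows 25% ring irregularity so that
  frames fitted to noisy subunits remain usable.
* Coplanarity (torsion-zero) branch: normalized scalar triple product
  below $10^{-9}$.
* Collinear-contact accumulation: perpendicular line offset below
  $10^{-7}$; in 3D, edges are treated as parallel within 30 degrees
  (wrapping tilts contact edges by up to ~20 degrees at the observed
  torsions, while the next pentagon edge is 72 degrees away).
* Overlap screening: convex polygon intersection area above $10^{-7}$ on
  a local lattice patch of two rings of unit cells.
* Degeneracy thresholds: a chain is a ring when |rise per turn| is below
  $10^{-6}$ and a strip when the step is a pure translation or the fitted
  radius exceeds $10^6$.
* Desk-scale problem sizes: enumeration over $n_h \le 6$, $n_p \le 10$
  (configurable to the 8 x 12 default grid), wrapped tubes of 2 turns
  (48 pentamers), helices of ~24 pentamers, 100-draw noise studies.

## Known limitations

The lattice model fixes the contact-edge assignment of the biological
family (isolated in one internal function, so alternative assignments can
be explored without touching the solver); exotic tilings using other edge
patterns exist mathematically but are outside the enumeration. Pentagons
are never deformed when wrapping, so 3D ring gaps exceed their planar
values. Network classes for assemblies without lattice metadata rely on
geometric-signature clustering, which cannot split classes that are
congruent but symmetry-inequivalent. And the helix builder constructs
single-stranded chains only; multi-start twisted tubes are represented
through their network blueprint rather than built explicitly.
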