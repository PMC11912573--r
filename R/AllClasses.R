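#' @import methods
NULL

#' Planar regular pentagon
#'
#' Five ordered planar vertices with centre and orientation sign. The
#' circumradius is the model length unit throughout the package: lattice
#' lengths such as the strip offset `b = 2.18` are expressed in circumradius
#' units, and a scale factor converts to physical units only on export.
#'
#' @slot vertices 5 x 2 matrix of ordered vertices.
#' @slot center length-2 centre.
#' @slot orientation +1 (counterclockwise) or -1 (clockwise), equal to the
#'   sign of the signed area of the vertex ring.
#' @export
setClass("Pentagon2D",
  representation(vertices = "matrix", center = "numeric",
                 orientation = "numeric"))

setValidity("Pentagon2D", function(object) {
  v <- object@vertices
  if (!is.matrix(v) || nrow(v) != 5 || ncol(v) != 2)
    return("vertices must be a 5 x 2 matrix")
  if (length(object@center) != 2) return("center must have length 2")
  d <- as.matrix(dist(v))
  if (any(d[upper.tri(d)] < 1e-9)) return("vertices must be pairwise distinct")
  r <- sqrt(rowSums(sweep(v, 2, object@center)^2))
  if (diff(range(r)) > 1e-6 * mean(r))
    return("vertices must be equidistant from the center (regular pentagon)")
  sa <- .signedArea(v)
  if (abs(sa) < 1e-12) return("signed area must be nonzero")
  if (object@orientation != sign(sa))
    return("orientation must equal the sign of the signed area")
  TRUE
})

#' Capsomer reference frame
#'
#' A polygonal multimer reduced to its geometric essentials: centre, unit
#' normal, and an ordered (counterclockwise about the normal) vertex ring
#' lying in the frame plane. This is the unit between which bending and
#' torsion angles are measured.
#'
#' @slot center length-3 centre.
#' @slot normal length-3 unit normal (|n| = 1 within 1e-9).
#' @slot vertices 5 x 3 matrix of in-plane vertices.
#' @slot label character identifier.
#' @export
setClass("CapsomerFrame",
  representation(center = "numeric", normal = "numeric",
                 vertices = "matrix", label = "character"))

setValidity("CapsomerFrame", function(object) {
  if (length(object@center) != 3) return("center must have length 3")
  if (length(object@normal) != 3) return("normal must have length 3")
  if (abs(sqrt(sum(object@normal^2)) - 1) > 1e-9)
    return("normal must be a unit vector (within 1e-9)")
  v <- object@vertices
  if (!is.matrix(v) || nrow(v) < 3 || ncol(v) != 3)
    return("vertices must be an n x 3 matrix with n >= 3")
  r <- sqrt(rowSums(sweep(v, 2, object@center)^2))
  sc <- mean(r)
  offs <- sweep(v, 2, object@center) %*% object@normal
  if (max(abs(offs)) > 1e-6 * max(sc, 1))
    return("vertices must lie in the frame plane")
  # ring regularity: generous bound so frames fitted to noisy subunit
  # positions (projected into their plane) remain valid
  if (diff(range(r)) > 0.25 * sc)
    return("vertex ring deviates grossly from a regular polygon")
  TRUE
})

#' Bending/torsion angle pair
#'
#' Bending is 180 degrees minus the angle between the two capsomer plane
#' normals (180 = coplanar, flat); torsion is the signed rotation about the
#' centre-to-centre axis separating one normal from the plane spanned by the
#' other normal and that axis (0 = untwisted).
#'
#' @slot bending degrees in (0, 180].
#' @slot torsion degrees in (-180, 180].
#' @export
setClass("AnglePair", representation(bending = "numeric", torsion = "numeric"))

setValidity("AnglePair", function(object) {
  if (!(object@bending > 0 && object@bending <= 180 + 1e-9))
    return("bending must lie in (0, 180]")
  if (!(object@torsion > -180 - 1e-9 && object@torsion <= 180 + 1e-9))
    return("torsion must lie in (-180, 180]")
  TRUE
})

#' Assembly of capsomer frames
#'
#' @slot frames list of [CapsomerFrame-class] objects with unique labels.
#' @slot subunitCoords optional list (one 5 x 3 matrix per frame) of subunit
#'   centroid positions; empty list if absent.
#' @slot scale physical length per model unit (dimensionless default 1).
#' @slot metadata data.frame of per-frame annotations (may have zero columns);
#'   lattice-derived assemblies carry kind/thread/step and unrolled 2D
#'   coordinates here.
#' @export
setClass("Assembly",
  representation(frames = "list", subunitCoords = "list", scale = "numeric",
                 metadata = "data.frame"))

setValidity("Assembly", function(object) {
  if (!all(vapply(object@frames, is, logical(1), "CapsomerFrame")))
    return("frames must be a list of CapsomerFrame objects")
  labs <- vapply(object@frames, function(f) f@label, character(1))
  if (anyDuplicated(labs)) return("frame labels must be unique")
  if (length(object@subunitCoords)) {
    if (length(object@subunitCoords) != length(object@frames))
      return("subunitCoords must have one entry per frame")
    for (i in seq_along(object@frames)) {
      sc <- object@subunitCoords[[i]]
      if (!is.matrix(sc) || nrow(sc) != 5 || ncol(sc) != 3)
        return("each subunitCoords entry must be a 5 x 3 matrix")
      f <- object@frames[[i]]
      offs <- sweep(sc, 2, f@center) %*% f@normal
      if (max(abs(offs)) > 0.2 * object@scale)
        return("subunit coordinates disagree with the frame plane")
    }
  }
  if (nrow(object@metadata) && nrow(object@metadata) != length(object@frames))
    return("metadata must have one row per frame")
  TRUE
})

#' Straight-tube lattice parameters
#'
#' @slot b strip offset (the axial component of the strip-to-strip vector H),
#'   in pentagon circumradius units.
#' @slot nh helicity number: the number of distinct strips (threads).
#' @slot np periodicity number: translation steps along the strip vector P
#'   separating lattice-identified pentagons.
#' @export
setClass("LatticeParams",
  representation(b = "numeric", nh = "numeric", np = "numeric"))

setValidity("LatticeParams", function(object) {
  if (!(object@b > 0)) return("b must be positive")
  if (object@nh < 1 || object@nh != round(object@nh))
    return("nh must be a positive integer")
  if (object@np < 1 || object@np != round(object@np))
    return("np must be a positive integer")
  TRUE
})

#' Solved straight-tube tiling
#'
#' @slot params [LatticeParams-class].
#' @slot a solved first component of the strip-to-strip vector H = (a, b).
#' @slot H length-2 strip-to-strip translation vector.
#' @slot P length-2 within-strip translation vector.
#' @slot g length-2 offset of the 180-degree-rotated partner pentagon.
#' @slot theta angle between P and H, degrees.
#' @slot contactPerEdge named numeric(5), percent contact per pentagon edge.
#' @slot contactPerClass named numeric(4), percent contact per contact class
#'   (intra.ahead, intra.behind, inter.up, inter.down).
#' @slot meanContact mean percent contact over the five edges.
#' @slot flipRequired logical: constructible only with flipped pentagons.
#' @slot overlap logical: pentagon interiors overlap (geometrically forbidden).
#' @slot status one of "feasible", "flip_required", "geometrically_forbidden".
#' @export
setClass("LatticeSolution",
  representation(params = "LatticeParams", a = "numeric", H = "numeric",
                 P = "numeric", g = "numeric", theta = "numeric",
                 contactPerEdge = "numeric", contactPerClass = "numeric",
                 meanContact = "numeric", flipRequired = "logical",
                 overlap = "logical", status = "character"))

setValidity("LatticeSolution", function(object) {
  if (object@status == "feasible") {
    res <- object@params@np * object@P[2] - object@params@nh * object@params@b
    if (abs(res) > 1e-9) return("closure residual exceeds 1e-9")
    if (any(object@contactPerEdge < -1e-9 | object@contactPerEdge > 100 + 1e-9))
      return("contact percentages must lie in [0, 100]")
    if (!(object@theta > 0 && object@theta < 180))
      return("theta must lie in (0, 180) degrees")
  }
  TRUE
})

#' Edge-contact construction points
#'
#' The auxiliary construction on the reference pentagon (vertices at the
#' fifth roots of unity): R1 on the line of edge P1P2, its image T under the
#' counterclockwise 144-degree rotation about the origin (which maps edge
#' P1P2 onto edge P3P4), and the strip-translated point R3 = R1 + (P1 - P3).
#'
#' @slot R1 length-2 contact point on edge P1P2.
#' @slot T length-2 rotated image of R1 on edge P3P4.
#' @slot R3 length-2 translated contact point.
#' @slot rotationDeg magnitude of the edge-to-edge rotation (144).
#' @export
setClass("EdgeContactConstruction",
  representation(R1 = "numeric", T = "numeric", R3 = "numeric",
                 rotationDeg = "numeric"))

#' Capsomer contact network
#'
#' Nodes are capsomer centres; edges carry weight 1 (contact) or 0 (candidate
#' non-contact) and belong to (helical) symmetry-equivalence classes. Each
#' class is annotated with the pentagon edges it engages on each endpoint
#' kind, which drives the realizability constraints during rewiring.
#'
#' @slot nodes data.frame: label, x, y, z, kind, and (for lattice-derived
#'   networks) unrolled 2D coordinates u, v.
#' @slot edges data.frame: a, b (labels), weight (0/1), class.
#' @slot classes data.frame: class, weight, engages (comma-separated
#'   "kind:edge" slots).
#' @export
setClass("ContactNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 classes = "data.frame"))

setValidity("ContactNetwork", function(object) {
  if (!all(object@edges$class %in% object@classes$class))
    return("every edge must belong to a declared class")
  w <- merge(object@edges, object@classes, by = "class")
  if (any(w$weight.x != w$weight.y))
    return("all edges in a class must share the class weight")
  TRUE
})

#' Twisted-tube helix specification
#'
#' @slot bending degrees in (0, 180].
#' @slot torsion degrees in (-180, 180].
#' @slot attach free attachment parameter in [0, 1] locating the incoming
#'   pentamer along the interface edge.
#' @slot nSteps number of pentamers in the chain (>= 1).
#' @export
setClass("HelixSpec",
  representation(bending = "numeric", torsion = "numeric",
                 attach = "numeric", nSteps = "numeric"))

setValidity("HelixSpec", function(object) {
  if (!(object@bending > 0 && object@bending <= 180))
    return("bending must lie in (0, 180]")
  if (!(object@attach >= 0 && object@attach <= 1))
    return("attach must lie in [0, 1]")
  if (object@nSteps < 1 || object@nSteps != round(object@nSteps))
    return("nSteps must be a positive integer")
  TRUE
})

#' Tube metrics
#'
#' @slot nThreads number of helical threads.
#' @slot risePerStep axial rise per chain step (model units).
#' @slot risePerTurn axial rise per full helical turn.
#' @slot radius helix radius of the frame centres.
#' @slot threadGap closest approach between adjacent helical threads
#'   (0 when compacted; NA for rings).
#' @slot status "helix", "ring" (no rise) or "strip" (degenerate straight).
#' @export
setClass("TubeMetrics",
  representation(nThreads = "numeric", risePerStep = "numeric",
                 risePerTurn = "numeric", radius = "numeric",
                 threadGap = "numeric", status = "character"))
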