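#' Construct a regular pentagon
#'
#' Vertices are placed at angles `phase + k * 72` degrees (k = 0..4) on the
#' circle of the given circumradius, in counterclockwise (`orientation = +1`)
#' or clockwise (`-1`) order. With `circumradius = 1` and `phase = 0` the
#' vertices are the fifth roots of unity, the reference pentagon of the
#' lattice model.
#'
#' @param circumradius positive circumradius (model length unit).
#' @param phase angular phase of the first vertex, degrees.
#' @param orientation +1 (counterclockwise) or -1 (clockwise).
#' @param center length-2 centre (default origin).
#' @return A [Pentagon2D-class].
#' @examples
#' p <- regularPentagon(1, 90)
#' pentagonVertices(p)[1, ]  # (0, 1)
#' @export
regularPentagon <- function(circumradius, phase = 0, orientation = 1L,
                            center = c(0, 0)) {
  if (!is.numeric(circumradius) || circumradius <= 0)
    stop("circumradius must be positive")
  if (!orientation %in% c(-1, 1)) stop("orientation must be +1 or -1")
  ang <- .deg2rad(phase + orientation * 72 * (0:4))
  v <- cbind(center[1] + circumradius * cos(ang),
             center[2] + circumradius * sin(ang))
  new("Pentagon2D", vertices = v, center = as.numeric(center),
      orientation = as.numeric(orientation))
}

#' @rdname regularPentagon
#' @param x a `Pentagon2D`.
#' @export
pentagonVertices <- function(x) x@vertices

#' @rdname regularPentagon
#' @export
pentagonOrientation <- function(x) x@orientation

#' Fit a capsomer frame to 3D points
#'
#' Least-squares plane fit: the centre is the centroid, the normal is the
#' minor principal axis of the point scatter, and the vertices are the points
#' projected onto the plane, re-ordered counterclockwise about the normal
#' (the normal sign is chosen so that the projected ring is
#' counterclockwise; assembly-level re-orientation, e.g. outward from the
#' assembly centroid, is applied by the caller).
#'
#' @param points n x 3 matrix (n >= 3), not all collinear.
#' @param label frame label.
#' @return A [CapsomerFrame-class].
#' @examples
#' ring <- cbind(cos(2 * pi * 0:4 / 5), sin(2 * pi * 0:4 / 5), 0)
#' f <- fitPolygonFrame(ring)
#' frameNormal(f)
#' @export
fitPolygonFrame <- function(points, label = "frame") {
  points <- as.matrix(points)
  if (nrow(points) < 3 || ncol(points) != 3)
    stop("points must be an n x 3 matrix with n >= 3")
  ctr <- colMeans(points)
  x <- sweep(points, 2, ctr)
  sv <- svd(x)
  if (sv$d[2] < 1e-9 * max(sv$d[1], 1))
    stop("points are collinear or degenerate; no plane can be fitted")
  n <- sv$v[, 3]
  proj <- x - outer(as.vector(x %*% n), n)
  # in-plane axes
  e1 <- .unit(sv$v[, 1])
  e2v <- c(n[2] * e1[3] - n[3] * e1[2],
           n[3] * e1[1] - n[1] * e1[3],
           n[1] * e1[2] - n[2] * e1[1])
  ang <- atan2(proj %*% e2v, proj %*% e1)
  ord <- order(ang)
  v2 <- cbind((proj %*% e1)[ord], (proj %*% e2v)[ord])
  if (.signedArea(v2) < 0) {  # flip normal so ring is counterclockwise
    n <- -n
    ord <- rev(ord)
  }
  new("CapsomerFrame", center = as.numeric(ctr), normal = as.numeric(.unit(n)),
      vertices = sweep(proj[ord, , drop = FALSE], 2, ctr, "+"),
      label = as.character(label))
}

#' Rotate a point about an axis
#'
#' Right-handed rotation: counterclockwise when viewed from the tip of
#' `axisDir` looking back along the axis.
#'
#' @param point length-3 point (or n x 3 matrix of points).
#' @param axisOrigin point on the axis.
#' @param axisDir unit axis direction.
#' @param angleDeg rotation angle in degrees.
#' @return Rotated point(s), same shape as `point`.
#' @examples
#' rotateAboutAxis(c(1, 0, 0), c(0, 0, 0), c(0, 0, 1), 90)  # (0, 1, 0)
#' @export
rotateAboutAxis <- function(point, axisOrigin, axisDir, angleDeg) {
  if (abs(sqrt(sum(axisDir^2)) - 1) > 1e-9)
    stop("axisDir must be a unit vector")
  R <- .rotmat(axisDir, angleDeg)
  if (is.matrix(point)) {
    sweep(sweep(point, 2, axisOrigin) %*% t(R), 2, axisOrigin, "+")
  } else {
    as.vector(R %*% (point - axisOrigin)) + axisOrigin
  }
}

## ---- frame helpers -------------------------------------------------------

#' Accessors for capsomer frames and assemblies
#'
#' @param x a [CapsomerFrame-class] or [Assembly-class].
#' @name frame-accessors
NULL

#' @rdname frame-accessors
#' @export
frameCenter <- function(x) x@center

#' @rdname frame-accessors
#' @export
frameNormal <- function(x) x@normal

#' @rdname frame-accessors
#' @export
frameVertices <- function(x) x@vertices

#' @rdname frame-accessors
#' @export
frameLabel <- function(x) x@label

#' @rdname frame-accessors
#' @export
assemblyFrames <- function(x) x@frames

#' @rdname frame-accessors
#' @export
nFrames <- function(x) length(x@frames)

#' @rdname frame-accessors
#' @export
frameCenters <- function(x)
  do.call(rbind, lapply(x@frames, function(f) f@center))

#' @rdname frame-accessors
#' @export
frameLabels <- function(x)
  vapply(x@frames, function(f) f@label, character(1))

#' @rdname frame-accessors
#' @export
assemblyMetadata <- function(x) x@metadata

## Build a CapsomerFrame directly from centre/normal/in-plane ring.
.makeFrame <- function(center, normal, vertices, label) {
  new("CapsomerFrame", center = as.numeric(center),
      normal = as.numeric(.unit(normal)), vertices = vertices,
      label = as.character(label))
}

#' Assemble capsomer frames into an Assembly
#'
#' @param frames list of [CapsomerFrame-class].
#' @param subunitCoords optional list of 5 x 3 subunit centroid matrices.
#' @param scale physical length per model unit.
#' @param metadata optional per-frame data.frame.
#' @return An [Assembly-class].
#' @export
assembly <- function(frames, subunitCoords = list(), scale = 1,
                     metadata = NULL) {
  if (is.null(metadata)) metadata <- data.frame(row.names = seq_along(frames))
  new("Assembly", frames = frames, subunitCoords = subunitCoords,
      scale = scale, metadata = metadata)
}

## Apply a rigid transform (R, t) to an assembly (used by tests and metrics).

#' Rigidly transform an assembly
#'
#' @param x an [Assembly-class].
#' @param R 3 x 3 rotation matrix.
#' @param t length-3 translation.
#' @export
transformAssembly <- function(x, R = diag(3), t = c(0, 0, 0)) {
  fr <- lapply(x@frames, function(f) {
    .makeFrame(as.vector(R %*% f@center) + t,
               as.vector(R %*% f@normal),
               sweep(f@vertices %*% t(R), 2, t, "+"), f@label)
  })
  sc <- lapply(x@subunitCoords, function(m) sweep(m %*% t(R), 2, t, "+"))
  assembly(fr, sc, x@scale, x@metadata)
}

setMethod("show", "Pentagon2D", function(object) {
  cat("Pentagon2D: circumradius",
      format(mean(sqrt(rowSums(sweep(object@vertices, 2,
                                     object@center)^2))), digits = 6),
      "orientation", object@orientation, "\n")
})

setMethod("show", "CapsomerFrame", function(object) {
  cat("CapsomerFrame", object@label, ": center (",
      paste(format(object@center, digits = 4), collapse = ", "),
      "), normal (", paste(format(object@normal, digits = 4),
                           collapse = ", "), ")\n")
})

setMethod("show", "Assembly", function(object) {
  cat("Assembly of", length(object@frames), "capsomer frames",
      if (length(object@subunitCoords)) "(with subunit coordinates)" else "",
      "\n  scale:", object@scale, "physical units per model unit\n")
  if (ncol(object@metadata))
    cat("  metadata:", paste(names(object@metadata), collapse = ", "), "\n")
})

setMethod("show", "AnglePair", function(object) {
  cat(sprintf("AnglePair: bending %.3f deg, torsion %.3f deg\n",
              object@bending, object@torsion))
})
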