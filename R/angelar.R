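#' Bending and torsion angles between two capsomers ("AngelaR")
#'
#' Let d be the unit vector between the two frame centres and n_a, n_b the
#' plane normals, co-oriented so that their components perpendicular to d
#' agree in sign (n_b is flipped if needed). If n_a, n_b and d are coplanar
#' the torsion is zero and the bending angle is 180 degrees minus the angle
#' between the normals. Otherwise the torsion is the signed angle (right-hand
#' rule about d, from a to b) separating n_b from the plane spanned by n_a
#' and d, and the bending angle is computed after rotating n_b back into
#' that plane.
#'
#' The global torsion sign follows the right-hand rule about d and flips with
#' the normal orientation convention; signed torsions are swap-invariant
#' (the signed dihedral of a chain does not change when the chain is read
#' backwards), while bending is symmetric in the two frames.
#'
#' @param a,b [CapsomerFrame-class] objects with distinct centres.
#' @param coplanarTol tolerance on the normalized scalar triple product below
#'   which the configuration is treated as coplanar (torsion exactly 0).
#' @return An [AnglePair-class].
#' @examples
#' dod <- makeDodecahedron(1)
#' ct <- detectContacts(dod, threshold = 0.2)
#' range(ct$bending_deg)  # all 116.565 (the dodecahedral bending angle)
#' @export
bendingTorsion <- function(a, b, coplanarTol = 1e-9) {
  ca <- a@center; cb <- b@center
  dv <- cb - ca
  if (sqrt(sum(dv^2)) < 1e-12) stop("frame centres coincide")
  d <- .unit(dv)
  na <- .unit(a@normal); nb <- .unit(b@normal)
  u <- na - sum(na * d) * d
  w <- nb - sum(nb * d) * d
  if (sum(u * w) < 0) {  # co-orient n_b
    nb <- -nb
    w <- -w
  }
  trip <- sum(d * c(na[2] * nb[3] - na[3] * nb[2],
                    na[3] * nb[1] - na[1] * nb[3],
                    na[1] * nb[2] - na[2] * nb[1]))
  nu <- sqrt(sum(u^2)); nw <- sqrt(sum(w^2))
  if (abs(trip) < coplanarTol || nu < 1e-12 || nw < 1e-12) {
    tau <- 0
    nbr <- nb
  } else {
    cx <- c(u[2] * w[3] - u[3] * w[2],
            u[3] * w[1] - u[1] * w[3],
            u[1] * w[2] - u[2] * w[1])
    tau <- atan2(sum(d * cx), sum(u * w))
    nbr <- as.vector(.rotmat(d, -.rad2deg(tau)) %*% nb)
  }
  bend <- 180 - .rad2deg(acos(min(max(sum(na * nbr), -1), 1)))
  if (bend <= 0) bend <- .Machine$double.eps
  new("AnglePair", bending = bend, torsion = .rad2deg(tau))
}

#' Construct a coplanar-then-twisted pentamer pair with given angles
#'
#' Builds frame `a` in the z = 0 plane and attaches frame `b` across an
#' interface edge: the incoming pentamer is placed by a 180-degree in-plane
#' rotation about the attachment point (a 2-fold contact), folded out of
#' plane about the shared edge line to the requested bending angle, then
#' rotated about the centre-to-centre axis by the requested torsion. By
#' construction `bendingTorsion(a, b)` returns the requested pair exactly.
#'
#' @param bending degrees in (0, 180].
#' @param torsion degrees in (-180, 180].
#' @param attach attachment parameter in [0, 1] along the interface edge.
#' @param edge interface edge index of frame a (1..5; edge k runs from
#'   vertex k to vertex k + 1).
#' @param circumradius pentagon circumradius.
#' @return list with elements `a`, `b` ([CapsomerFrame-class]) and `step`
#'   (the 4 x 4 rigid step transform, used by the helix builder).
#' @export
pairFromAngles <- function(bending, torsion = 0, attach = 0.5, edge = 1,
                           circumradius = 1) {
  stopifnot(bending > 0, bending <= 180)
  ang <- .deg2rad(72 * (0:4))
  v <- cbind(circumradius * cos(ang), circumradius * sin(ang), 0)
  a <- .makeFrame(c(0, 0, 0), c(0, 0, 1), v, "p1")
  M <- .helixStep(a, bending, torsion, attach, edge)
  b <- .applyStep(a, M, "p2")
  list(a = a, b = b, step = M)
}

## 4x4 rigid step transform attaching the next pentamer to frame `f`:
## 2-fold in-plane placement about the attachment point, fold about the
## shared edge line, twist about the centre-to-centre axis. For off-centre
## attachment the raw fold/twist angles are not the measured angles, so the
## construction angles are solved so that bendingTorsion() returns the
## requested pair exactly.
.helixStep <- function(f, bending, torsion, attach, edge) {
  v <- f@vertices
  e2 <- if (edge == nrow(v)) 1 else edge + 1
  p <- v[edge, ] + attach * (v[e2, ] - v[edge, ])
  ehat <- .unit(v[e2, ] - v[edge, ])
  n <- f@normal
  T1 <- .rigid(.rotmat(n, 180), p)                 # in-plane 2-fold about p
  build <- function(phi, psi) {
    M <- .rigid(.rotmat(ehat, phi), p) %*% T1      # fold about edge line
    cb <- as.vector(M %*% c(f@center, 1))[1:3]
    d <- .unit(cb - f@center)
    .rigid(.rotmat(d, psi), f@center) %*% M        # twist about centre axis
  }
  wrap180 <- function(x) ((x + 180) %% 360) - 180
  err <- function(x) {
    ap <- bendingTorsion(f, .applyStep(f, build(x[1], x[2]), "tmp"))
    c(ap@bending - bending, wrap180(ap@torsion - torsion))
  }
  x <- c(-(180 - bending), torsion)
  Fx <- err(x)
  for (it in 1:100) {
    if (max(abs(Fx)) < 1e-10) break
    h <- 1e-6
    J <- cbind((err(x + c(h, 0)) - Fx) / h, (err(x + c(0, h)) - Fx) / h)
    step <- tryCatch(solve(J, Fx), error = function(e) Fx)
    nrm <- sqrt(sum(step^2))
    if (nrm > 20) step <- step * 20 / nrm   # damp large Newton steps
    x2 <- x - step
    F2 <- err(x2)
    # backtracking line search
    k <- 0
    while (sum(F2^2) > sum(Fx^2) && k < 8) {
      x2 <- x - step * 0.5^(k + 1)
      F2 <- err(x2)
      k <- k + 1
    }
    x <- x2; Fx <- F2
  }
  if (max(abs(Fx)) > 1e-8)
    stop("requested bending/torsion pair is not attainable at attachment ",
         "position ", attach, " (closest residual ",
         format(max(abs(Fx))), " deg)")
  build(x[1], x[2])
}

## 4x4 matrix for rotation R about fixed point p.
.rigid <- function(R, p) {
  M <- diag(4)
  M[1:3, 1:3] <- R
  M[1:3, 4] <- p - as.vector(R %*% p)
  M
}

.applyStep <- function(f, M, label) {
  R <- M[1:3, 1:3]; t <- M[1:3, 4]
  .makeFrame(as.vector(R %*% f@center) + t, as.vector(R %*% f@normal),
             sweep(f@vertices %*% t(R), 2, t, "+"), label)
}

#' Detect capsomer contacts in an assembly
#'
#' Reports every unordered frame pair whose minimum vertex-ring edge-to-edge
#' distance is below the threshold, with bending/torsion angles, centre
#' distance and the contact fraction (collinear edge overlap relative to
#' edge length; 0 for point-like contacts).
#'
#' @param assembly an [Assembly-class] with at least 2 frames.
#' @param threshold contact distance threshold in model units; the default
#'   is 0.15 times the median ring edge length.
#' @return data.frame with columns frame_a, frame_b, distance, bending_deg,
#'   torsion_deg, contact_fraction, ring_gap.
#' @export
detectContacts <- function(assembly, threshold = NULL) {
  fr <- assembly@frames
  if (length(fr) < 2) {
    if (length(fr) < 1) stop("assembly must contain at least one frame")
    return(.emptyContacts())
  }
  s <- .medianEdge(assembly)
  if (is.null(threshold)) threshold <- 0.15 * s
  if (threshold <= 0) stop("threshold must be positive")
  ctrs <- frameCenters(assembly)
  rmax <- max(vapply(fr, function(f)
    max(sqrt(rowSums(sweep(f@vertices, 2, f@center)^2))), numeric(1)))
  out <- list()
  n <- length(fr)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) > 2 * rmax + threshold) next
      gap <- .ringDist(fr[[i]]@vertices, fr[[j]]@vertices)
      if (gap >= threshold) next
      ap <- bendingTorsion(fr[[i]], fr[[j]])
      out[[length(out) + 1]] <- data.frame(
        frame_a = fr[[i]]@label, frame_b = fr[[j]]@label,
        distance = sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)),
        bending_deg = ap@bending, torsion_deg = ap@torsion,
        contact_fraction = .contactFraction(fr[[i]], fr[[j]], s),
        ring_gap = gap, stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(.emptyContacts())
  do.call(rbind, out)
}

.emptyContacts <- function() {
  data.frame(frame_a = character(0), frame_b = character(0),
             distance = numeric(0), bending_deg = numeric(0),
             torsion_deg = numeric(0), contact_fraction = numeric(0),
             ring_gap = numeric(0), stringsAsFactors = FALSE)
}

.medianEdge <- function(assembly) {
  ed <- vapply(assembly@frames, function(f) {
    v <- f@vertices
    i2 <- c(seq_len(nrow(v))[-1], 1)
    stats::median(sqrt(rowSums((v[i2, ] - v)^2)))
  }, numeric(1))
  stats::median(ed)
}

## Collinear overlap fraction of the contact: among all near-minimal edge
## pairs (several pairs tie at shared vertices), the largest near-parallel
## projected overlap relative to the edge length.
.contactFraction <- function(fa, fb, edgeLen) {
  va <- fa@vertices; vb <- fb@vertices
  na <- nrow(va); nb <- nrow(vb)
  d <- matrix(Inf, na, nb)
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1 else i + 1
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1 else j + 1
      d[i, j] <- .segSegDist(va[i, ], va[i2, ], vb[j, ], vb[j2, ])
    }
  }
  frac <- 0
  tol <- min(d) + 0.05 * edgeLen
  for (i in seq_len(na)) for (j in seq_len(nb)) {
    if (d[i, j] > tol) next
    i2 <- if (i == na) 1 else i + 1
    j2 <- if (j == nb) 1 else j + 1
    a1 <- va[i, ]; a2 <- va[i2, ]; b1 <- vb[j, ]; b2 <- vb[j2, ]
    u <- .unit(a2 - a1)
    w <- b2 - b1
    cosang <- abs(sum(u * w) / sqrt(sum(w^2)))
    if (cosang < cos(.deg2rad(30))) next  # edges not near-parallel
    t1 <- sum((b1 - a1) * u); t2 <- sum((b2 - a1) * u)
    lo <- max(0, min(t1, t2)); hi <- min(sqrt(sum((a2 - a1)^2)), max(t1, t2))
    frac <- max(frac, max(0, min(1, (hi - lo) / edgeLen)))
  }
  frac
}

#' Measure capsomer contacts in a structure file
#'
#' Reads a PDB (or, when bio3d provides `read.cif`, an mmCIF) file, groups
#' chains into capsomers, builds one [CapsomerFrame-class] per capsomer from
#' its subunit centroids (each subunit centroid is the mean of all atom
#' positions of the chain within the group), orients normals outward from
#' the assembly centroid, and reports all contacts.
#'
#' @param path structure file.
#' @param groups either NULL (default: the residue number identifies the
#'   capsomer and the chain identifies the subunit, the dialect written by
#'   [writeStructure()]), a data.frame with columns `chain` and `capsomer`,
#'   or the path to a TSV file with those columns.
#' @param threshold contact threshold in file units (default 0.15 x median
#'   ring edge length).
#' @return data.frame of contacts as in [detectContacts()].
#' @export
measureStructure <- function(path, groups = NULL, threshold = NULL) {
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext == "cif") {
    if (!exists("read.cif", where = asNamespace("bio3d")))
      stop("mmCIF reading requires bio3d::read.cif")
    bio3d::read.cif(path)
  } else bio3d::read.pdb(path)
  at <- pdb$atom
  if (is.character(groups) && length(groups) == 1)
    groups <- utils::read.table(groups, header = TRUE, sep = "\t",
                                stringsAsFactors = FALSE)
  if (is.null(groups)) {
    cap <- as.character(at$resno)
    sub <- paste(at$resno, at$chain, sep = "/")
  } else {
    idx <- match(at$chain, groups$chain)
    if (anyNA(idx)) stop("inconsistent grouping: unmapped chains ",
                         paste(unique(at$chain[is.na(idx)]), collapse = ", "))
    cap <- as.character(groups$capsomer[idx])
    sub <- at$chain
  }
  xyz <- cbind(at$x, at$y, at$z)
  frames <- list()
  for (g in unique(cap)) {
    sel <- cap == g
    subs <- unique(sub[sel])
    if (length(subs) < 3)
      stop("capsomer group '", g, "' has fewer than 3 subunits")
    cent <- t(vapply(subs, function(s) colMeans(xyz[sel & sub == s, ,
                                                    drop = FALSE]),
                     numeric(3)))
    frames[[length(frames) + 1]] <- fitPolygonFrame(cent, label = g)
  }
  asm <- assembly(frames)
  asm <- .orientOutward(asm)
  detectContacts(asm, threshold)
}

## Flip frame normals to point away from the assembly centroid.
.orientOutward <- function(asm) {
  ctr <- colMeans(frameCenters(asm))
  asm@frames <- lapply(asm@frames, function(f) {
    if (sum(f@normal * (f@center - ctr)) < 0) f@normal <- -f@normal
    f
  })
  asm
}
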