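## Planar lattice model of straight tubes.
##
## The model tiles the plane with two pentagons per unit cell: a reference
## pentagon U (circumradius 1, vertices at the fifth roots of unity) at the
## lattice points m*P + k*H, and a 180-degree-rotated partner D centred at
## g + m*P + k*H. Contacts between up- and down-pentagons are collinear
## partial edge-edge overlaps whose 2-fold centres lie on the shared edge
## line; each contact class therefore contributes one linear equation
## n_e . q = 2 * apothem in the unknowns (g, P, a), where q is the class
## offset and H = (a, b). Together with the tube-closure equality between
## the axial (second) components, n_p * P_y = n_h * b, the system is square
## and the construction is fully determined.

.pentaConsts <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    ang <- 2 * pi * (0:4) / 5
    V <- cbind(cos(ang), sin(ang))           # vertices P1..P5, counterclockwise
    S <- 2 * sin(pi / 5)                     # edge length
    APO <- cos(pi / 5)                       # apothem
    EHAT <- t(vapply(1:5, function(k) {
      k2 <- if (k == 5) 1 else k + 1
      (V[k2, ] - V[k, ]) / S
    }, numeric(2)))
    NHAT <- cbind(EHAT[, 2], -EHAT[, 1])
    for (k in 1:5) {
      mid <- (V[k, ] + V[if (k == 5) 1 else k + 1, ]) / 2
      if (sum(NHAT[k, ] * mid) < 0) NHAT[k, ] <- -NHAT[k, ]
    }
    cache <<- list(V = V, S = S, APO = APO, EHAT = EHAT, NHAT = NHAT)
    cache
  }
})

## The construction's contact-edge assignment (isolated here so it can be
## revised without touching the solver). Edges are 1-based; edge k runs from
## vertex k to vertex k+1. The two intrathread contact edges (1 and 3) are
## the 144-degree rotation pair of the edge-contact construction. Class
## offsets are q = g + m*P + k*H.
.contactAssignment <- function(flip = FALSE) {
  if (!flip) {
    data.frame(class = c("intra.ahead", "intra.behind", "inter.up",
                         "inter.down"),
               edge = c(1L, 3L, 2L, 5L),
               m = c(0L, -1L, -1L, 0L),
               k = c(0L, 0L, 1L, -1L),
               stringsAsFactors = FALSE)
  } else {
    # repeated-edge variant: the interthread-up contact re-uses edge 3
    data.frame(class = c("intra.ahead", "intra.behind", "inter.up",
                         "inter.down"),
               edge = c(1L, 3L, 3L, 5L),
               m = c(0L, -1L, -1L, 0L),
               k = c(0L, 0L, 1L, -1L),
               stringsAsFactors = FALSE)
  }
}

#' Create straight-tube lattice parameters
#'
#' @param b strip offset in circumradius units (2.18 matches the biological
#'   straight tube).
#' @param nh helicity number (number of strips), positive integer.
#' @param np periodicity number (steps along the strip vector), positive
#'   integer.
#' @return A [LatticeParams-class].
#' @export
latticeParams <- function(b, nh, np) new("LatticeParams", b = b, nh = nh,
                                         np = np)

## Solve the 5x5 linear system for one assignment. Returns NULL when the
## system is singular (numerical failure, distinct from infeasibility).
.latticeSolveRaw <- function(asg, b, nh, np) {
  pc <- .pentaConsts()
  A <- matrix(0, 5, 5)  # unknowns (g1, g2, p1, p2, a)
  rhs <- numeric(5)
  for (i in 1:4) {
    n <- pc$NHAT[asg$edge[i], ]
    A[i, ] <- c(n[1], n[2], asg$m[i] * n[1], asg$m[i] * n[2], asg$k[i] * n[1])
    rhs[i] <- 2 * pc$APO - asg$k[i] * n[2] * b
  }
  A[5, ] <- c(0, 0, 0, 1, 0)
  rhs[5] <- nh * b / np
  if (abs(det(A)) < 1e-9) return(NULL)
  x <- solve(A, rhs)
  list(g = x[1:2], P = x[3:4], H = c(x[5], b), a = x[5])
}

## Collinear overlap interval of the class contact on its U edge, in edge
## arc-length coordinates [0, S]; negative length means no contact.
.classInterval <- function(sol, edge, q) {
  pc <- .pentaConsts()
  e2 <- if (edge == 5) 1 else edge + 1
  t0 <- sum((q - pc$V[e2, ] - pc$V[edge, ]) * pc$EHAT[edge, ])
  t1 <- sum((q - pc$V[edge, ] - pc$V[edge, ]) * pc$EHAT[edge, ])
  c(max(0, min(t0, t1)), min(pc$S, max(t0, t1)))
}

.classOffsets <- function(sol, asg) {
  lapply(seq_len(4), function(i)
    sol$g + asg$m[i] * sol$P + asg$k[i] * sol$H)
}

## Pentagon interiors overlap anywhere in a local patch?
.latticeOverlaps <- function(sol, rng = 2) {
  pc <- .pentaConsts()
  polys <- list(); ctrs <- list()
  for (m in -rng:rng) for (k in -rng:rng) {
    t <- m * sol$P + k * sol$H
    polys[[length(polys) + 1]] <- sweep(pc$V, 2, t, "+")
    ctrs[[length(ctrs) + 1]] <- t
    polys[[length(polys) + 1]] <- sweep(-pc$V, 2, sol$g + t, "+")
    ctrs[[length(ctrs) + 1]] <- sol$g + t
  }
  ctrs <- do.call(rbind, ctrs)
  n <- length(polys)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sum((ctrs[i, ] - ctrs[j, ])^2) > 4.2) next
    if (.convexClipArea(polys[[i]], polys[[j]]) > 1e-7) return(TRUE)
  }
  FALSE
}

## Feasibility screen: all four class contacts have positive overlap,
## contacts sharing an edge occupy disjoint stretches, and no interiors
## overlap.
.latticeFeasible <- function(sol, asg) {
  if (is.null(sol)) return(FALSE)
  iv <- lapply(seq_len(4), function(i)
    .classInterval(sol, asg$edge[i], .classOffsets(sol, asg)[[i]]))
  if (any(vapply(iv, function(x) x[2] - x[1], numeric(1)) < 1e-9))
    return(FALSE)
  for (e in unique(asg$edge[duplicated(asg$edge)])) {
    segs <- iv[asg$edge == e]
    segs <- segs[order(vapply(segs, `[`, numeric(1), 1))]
    for (i in seq_len(length(segs) - 1))
      if (segs[[i]][2] > segs[[i + 1]][1] + 1e-9) return(FALSE)
  }
  !.latticeOverlaps(sol)
}

## Percent of each U edge covered by collinear partner-edge overlap,
## accumulated over nearby partner pentagons (collinearity tolerance:
## perpendicular line offset < 1e-7).
.contactPerEdge <- function(sol) {
  pc <- .pentaConsts()
  out <- numeric(5)
  for (e in 1:5) {
    tot <- 0
    e2 <- if (e == 5) 1 else e + 1
    for (m in -3:3) for (k in -2:2) {
      q <- sol$g + m * sol$P + k * sol$H
      if (abs(sum(pc$NHAT[e, ] * q) - 2 * pc$APO) > 1e-7) next
      t0 <- sum((q - pc$V[e2, ] - pc$V[e, ]) * pc$EHAT[e, ])
      t1 <- sum((q - pc$V[e, ] - pc$V[e, ]) * pc$EHAT[e, ])
      tot <- tot + max(0, min(pc$S, max(t0, t1)) - max(0, min(t0, t1)))
    }
    out[e] <- 100 * tot / pc$S
  }
  names(out) <- paste0("edge", 1:5)
  out
}

#' Solve the straight-tube lattice for given (b, n_h, n_p)
#'
#' Determines the strip-to-strip vector H = (a, b), the strip vector P and
#' the partner offset from the four edge-contact conditions plus the tube
#' closure equality between the axial components of n_p P and n_h H, then
#' screens the tiling: all four contacts must have positive edge overlap and
#' no pentagon interiors may intersect. Combinations that fail the canonical
#' construction but succeed when a pentagon edge is re-used for two contacts
#' are flagged `flip_required` (realizable only with mirrored pentagons,
#' which asymmetric protein interfaces cannot provide); combinations that
#' fail both are geometrically forbidden.
#'
#' @param params a [LatticeParams-class] (or b, nh, np given separately).
#' @param nh,np used when `params` is the numeric b.
#' @return A [LatticeSolution-class]; inspect `latticeStatus()`.
#' @examples
#' sol <- solveLattice(latticeParams(2.18, 3, 4))
#' latticeStatus(sol)
#' @export
solveLattice <- function(params, nh = NULL, np = NULL) {
  if (is.numeric(params) && !is.null(nh))
    params <- latticeParams(params, nh, np)
  b <- params@b; nh <- params@nh; np <- params@np
  asg <- .contactAssignment(flip = FALSE)
  sol <- .latticeSolveRaw(asg, b, nh, np)
  if (is.null(sol))
    stop("lattice system is singular for (b, nh, np) = (",
         b, ", ", nh, ", ", np, "): numerical failure")
  if (.latticeFeasible(sol, asg))
    return(.finishSolution(params, sol, asg, "feasible"))
  overlapped <- .latticeOverlaps(sol)
  fasg <- .contactAssignment(flip = TRUE)
  fsol <- .latticeSolveRaw(fasg, b, nh, np)
  if (!is.null(fsol) && .latticeFeasible(fsol, fasg))
    return(.finishSolution(params, fsol, fasg, "flip_required",
                           overlap = overlapped))
  .finishSolution(params, sol, asg, "geometrically_forbidden",
                  overlap = overlapped)
}

.finishSolution <- function(params, sol, asg, status, overlap = FALSE) {
  perEdge <- if (status == "feasible") .contactPerEdge(sol) else
    stats::setNames(rep(NA_real_, 5), paste0("edge", 1:5))
  perClass <- vapply(seq_len(4), function(i) {
    iv <- .classInterval(sol, asg$edge[i], .classOffsets(sol, asg)[[i]])
    100 * max(0, iv[2] - iv[1]) / .pentaConsts()$S
  }, numeric(1))
  names(perClass) <- asg$class
  th <- .rad2deg(acos(sum(.unit(sol$P) * .unit(sol$H))))
  new("LatticeSolution", params = params, a = sol$a, H = sol$H, P = sol$P,
      g = sol$g, theta = th, contactPerEdge = perEdge,
      contactPerClass = perClass,
      meanContact = if (status == "feasible") mean(perEdge) else NA_real_,
      flipRequired = status == "flip_required", overlap = overlap,
      status = status)
}

#' @rdname solveLattice
#' @param solution a [LatticeSolution-class].
#' @export
latticeStatus <- function(solution) solution@status

#' @rdname solveLattice
#' @export
isFeasible <- function(solution) solution@status == "feasible"

#' Contact percentage per pentagon edge
#'
#' The contact area of the model is the proportion of a pentagonal edge in
#' contact with the edge of a neighbouring pentamer, as a percentage. Both
#' the per-edge values and their mean over the five edges are reported.
#'
#' @param solution a feasible [LatticeSolution-class].
#' @return list with `perEdge` (named numeric(5)), `perClass` (named
#'   numeric(4)) and `mean`.
#' @export
contactPercentage <- function(solution) {
  if (solution@status != "feasible")
    stop("contact percentages are defined only for feasible tilings (status: ",
         solution@status, ")")
  list(perEdge = solution@contactPerEdge,
       perClass = solution@contactPerClass,
       mean = solution@meanContact)
}

#' Does the tiling require flipped pentagons?
#'
#' TRUE when the canonical four-distinct-edge construction is infeasible but
#' the tiling is constructible with a pentagon edge re-used for two
#' inequivalent contacts - a mirror-symmetric contact pattern that a protein
#' pentamer with asymmetric interaction surfaces can only realize with
#' mirrored (flipped) subunits.
#'
#' @param solution a [LatticeSolution-class].
#' @export
flipRequired <- function(solution) solution@flipRequired

#' Enumerate straight-tube tilings over a (n_h, n_p) grid
#'
#' @param b strip offset (circumradius units), default 2.18.
#' @param nhRange,npRange integer vectors (defaults 1:8 and 1:12).
#' @return data.frame with one row per combination: n_h, n_p, feasible,
#'   flip_required, a, theta_deg, mean_contact_percent, status.
#' @examples
#' \donttest{tab <- enumerateTilings(2.18, 1:6, 1:10)}
#' @export
enumerateTilings <- function(b = 2.18, nhRange = 1:8, npRange = 1:12) {
  if (!length(nhRange) || !length(npRange))
    return(data.frame(n_h = integer(0), n_p = integer(0),
                      feasible = logical(0), flip_required = logical(0),
                      a = numeric(0), theta_deg = numeric(0),
                      mean_contact_percent = numeric(0),
                      status = character(0)))
  rows <- list()
  for (nh in nhRange) for (np in npRange) {
    s <- solveLattice(latticeParams(b, nh, np))
    rows[[length(rows) + 1]] <- data.frame(
      n_h = nh, n_p = np, feasible = s@status == "feasible",
      flip_required = s@flipRequired,
      a = if (s@status == "feasible") s@a else NA_real_,
      theta_deg = if (s@status == "feasible") s@theta else NA_real_,
      mean_contact_percent = s@meanContact,
      status = s@status, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Edge-contact construction points
#'
#' Returns the construction points of the solved tiling on the reference
#' pentagon: R1, the intrathread contact point on edge P1P2; T, its image
#' under the counterclockwise 144-degree rotation about the origin (the
#' pentagon symmetry that maps edge P1P2 onto edge P3P4, so that
#' |P4 T| = |R1 P2|); and R3 = R1 + (P1 - P3), the contact point translated
#' by the pentagon diagonal.
#'
#' @param solution a feasible [LatticeSolution-class].
#' @return An [EdgeContactConstruction-class].
#' @export
edgeContactConstruction <- function(solution) {
  if (solution@status != "feasible")
    stop("construction points require a feasible solution")
  pc <- .pentaConsts()
  R1 <- solution@g / 2
  T <- as.vector(.rot2(144) %*% R1)
  R3 <- R1 + (pc$V[1, ] - pc$V[3, ])
  new("EdgeContactConstruction", R1 = R1, T = T, R3 = R3, rotationDeg = 144)
}

#' Wrap a solved planar tiling onto a cylinder
#'
#' Rolls the lattice so that the identification vector C = n_p P - n_h H
#' (horizontal by the closure equality) becomes one full circumference;
#' lattice-equivalent pentagons map onto the same 3D pentamer and the
#' assembly has exactly n_h distinct helical threads. Pentagons are placed
#' rigid, tangent to the cylinder at their centres, normals radial.
#'
#' @param solution a feasible, non-flip [LatticeSolution-class].
#' @param nTurns number of helical turns to generate (axial extent).
#' @return An [Assembly-class] with kind/thread/step/u/v metadata.
#' @export
wrapToCylinder <- function(solution, nTurns = 2) {
  if (solution@status != "feasible")
    stop("only feasible tilings can be wrapped (status: ", solution@status,
         ")")
  pc <- .pentaConsts()
  nh <- solution@params@nh; np <- solution@params@np
  C <- np * solution@P - nh * solution@H
  r <- C[1] / (2 * pi)
  if (r < 0) stop("internal error: negative circumference")
  frames <- list(); subs <- list(); meta <- list()
  for (k in 0:(nh - 1)) for (m in 0:(np * nTurns - 1)) {
    for (kind in c("U", "D")) {
      uv <- m * solution@P + k * solution@H
      if (kind == "D") uv <- uv + solution@g
      v2 <- if (kind == "U") pc$V else -pc$V
      fr <- .wrapFrame(uv, v2, r,
                       sprintf("%s_m%d_k%d", kind, m, k))
      frames[[length(frames) + 1]] <- fr$frame
      subs[[length(subs) + 1]] <- fr$subunits
      meta[[length(meta) + 1]] <- data.frame(
        kind = kind, thread = k, step = m, u = uv[1], v = uv[2],
        stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, meta)
  attr(md, "radius") <- r
  attr(md, "solution") <- solution
  assembly(frames, subs, scale = 1, metadata = md)
}

## Place one pentagon tangent to the cylinder of radius r at unrolled
## coordinates uv; returns the frame and scaled subunit centroid ring.
.wrapFrame <- function(uv, v2, r, label) {
  phi <- uv[1] / r
  c3 <- c(r * cos(phi), r * sin(phi), uv[2])
  n3 <- c(cos(phi), sin(phi), 0)
  t3 <- c(-sin(phi), cos(phi), 0)
  z3 <- c(0, 0, 1)
  verts <- sweep(outer(v2[, 1], t3) + outer(v2[, 2], z3), 2, c3, "+")
  list(frame = .makeFrame(c3, n3, verts, label),
       subunits = sweep(0.8 * (outer(v2[, 1], t3) + outer(v2[, 2], z3)),
                        2, c3, "+"))
}

setMethod("show", "LatticeParams", function(object) {
  cat(sprintf("LatticeParams: b = %g, n_h = %d, n_p = %d\n",
              object@b, object@nh, object@np))
})

setMethod("show", "LatticeSolution", function(object) {
  cat(sprintf("LatticeSolution (b = %g, n_h = %d, n_p = %d): %s\n",
              object@params@b, object@params@nh, object@params@np,
              object@status))
  if (object@status == "feasible") {
    cat(sprintf("  a = %.6f, H = (%.4f, %.4f), P = (%.4f, %.4f), theta = %.2f deg\n",
                object@a, object@H[1], object@H[2], object@P[1], object@P[2],
                object@theta))
    cat(sprintf("  mean contact %.2f%% (per class: %s)\n", object@meanContact,
                paste(sprintf("%s %.1f%%", names(object@contactPerClass),
                              object@contactPerClass), collapse = ", ")))
  }
})

setMethod("show", "EdgeContactConstruction", function(object) {
  cat(sprintf("EdgeContactConstruction: R1 = (%.4f, %.4f), T = (%.4f, %.4f), R3 = (%.4f, %.4f), rotation %g deg\n",
              object@R1[1], object@R1[2], object@T[1], object@T[2],
              object@R3[1], object@R3[2], object@rotationDeg))
})
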