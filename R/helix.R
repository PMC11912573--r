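#' Create a twisted-tube helix specification
#'
#' @param bending bending angle, degrees in (0, 180].
#' @param torsion torsion angle, degrees in (-180, 180].
#' @param attach free attachment parameter in [0, 1] locating the incoming
#'   pentamer along the interface edge (default 0.5, edge midpoint).
#' @param nSteps number of pentamers in the chain.
#' @return A [HelixSpec-class].
#' @export
helixSpec <- function(bending, torsion = 0, attach = 0.5, nSteps = 10) {
  new("HelixSpec", bending = bending, torsion = torsion, attach = attach,
      nSteps = nSteps)
}

#' Build a single-stranded pentamer helix
#'
#' Constructs a deterministic chain of pentamer frames by applying the
#' bending and torsion angles iteratively, starting from a reference
#' pentamer in the z = 0 plane: each incoming pentamer is placed across the
#' same local interface edge at the attachment position, so the step
#' transform is one fixed rigid motion and the chain has exact screw
#' symmetry. Consecutive frames measured with [bendingTorsion()] return the
#' specified angles.
#'
#' @param spec a [HelixSpec-class].
#' @return An [Assembly-class] with step metadata (frames in chain order).
#' @examples
#' h <- buildHelix(helixSpec(bending = 140, torsion = 20, nSteps = 8))
#' threadMetrics(h)
#' @export
buildHelix <- function(spec) {
  ang <- 2 * pi * (0:4) / 5
  v <- cbind(cos(ang), sin(ang), 0)
  f <- .makeFrame(c(0, 0, 0), c(0, 0, 1), v, "h1")
  ## Each pentamer receives the previous one on interface edge 1 and emits
  ## the next from interface edge 3 (the 144-degree pair, as in the
  ## straight-tube strips): the step is the fixed rigid motion
  ## (placement across edge 3) o (C5 relabeling by 144 degrees).
  A <- .rigid(.rotmat(f@normal, 144), f@center)
  fR <- .applyStep(f, A, "relabel")
  M <- .helixStep(fR, spec@bending, spec@torsion, spec@attach,
                  edge = 1L) %*% A
  frames <- vector("list", spec@nSteps)
  subs <- vector("list", spec@nSteps)
  frames[[1]] <- f
  cur <- diag(4)
  for (i in seq_len(spec@nSteps - 1)) {
    cur <- M %*% cur
    frames[[i + 1]] <- .applyStep(f, cur, sprintf("h%d", i + 1))
  }
  for (i in seq_len(spec@nSteps)) {
    fr <- frames[[i]]
    subs[[i]] <- sweep(0.8 * sweep(fr@vertices, 2, fr@center), 2,
                       fr@center, "+")
  }
  md <- data.frame(kind = "H", thread = 0L,
                   step = seq_len(spec@nSteps) - 1L,
                   stringsAsFactors = FALSE)
  attr(md, "helixStep") <- M
  attr(md, "helixSpec") <- spec
  assembly(frames, subs, scale = 1, metadata = md)
}

## Screw decomposition of a 4x4 rigid transform: rotation angle (deg), unit
## axis, a point on the axis, and translation along the axis.
.screwDecompose <- function(M) {
  R <- M[1:3, 1:3]; t <- M[1:3, 4]
  tr <- (sum(diag(R)) - 1) / 2
  theta <- acos(min(max(tr, -1), 1))
  if (theta < 1e-9) {
    return(list(angleDeg = 0, axis = if (sqrt(sum(t^2)) > 0) .unit(t)
                else c(0, 0, 1), point = c(0, 0, 0),
                rise = sqrt(sum(t^2))))
  }
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (sqrt(sum(ax^2)) < 1e-9) {  # theta = pi
    E <- (R + diag(3)) / 2
    ax <- E[, which.max(diag(E))]
  }
  u <- .unit(ax)
  h <- sum(t * u)                       # rise along the axis
  tp <- t - h * u                       # in-plane translation
  # point p on axis satisfies (I - R) p = tp
  A <- diag(3) - R
  # solve in the plane perpendicular to u
  b1 <- .unit(if (abs(u[1]) < 0.9) c(1, 0, 0) - u[1] * u else
    c(0, 1, 0) - u[2] * u)
  b2 <- c(u[2] * b1[3] - u[3] * b1[2], u[3] * b1[1] - u[1] * b1[3],
          u[1] * b1[2] - u[2] * b1[1])
  B <- cbind(b1, b2)
  coef <- solve(t(B) %*% A %*% B, as.vector(t(B) %*% tp))
  p <- as.vector(B %*% coef)
  list(angleDeg = .rad2deg(theta) * sign(sum(u * ax)), axis = u, point = p,
       rise = h)
}

#' Measure helical metrics of a tubular assembly
#'
#' For chains built by [buildHelix()] the exact screw transform between
#' consecutive frames gives axis, rise and angular step; for wrapped-lattice
#' assemblies the thread metadata and cylinder radius are used. The thread
#' gap is the closest vertex-ring approach between frames that are not chain
#' neighbours (adjacent helical threads/turns); it is 0-like when the
#' threads are compacted and undefined (NA) for planar rings.
#'
#' @param assembly an [Assembly-class] with at least 3 frames.
#' @return A [TubeMetrics-class].
#' @export
threadMetrics <- function(assembly) {
  if (nFrames(assembly) < 3)
    stop("thread metrics require at least 3 frames")
  md <- assembly@metadata
  M <- attr(md, "helixStep")
  if (!is.null(M)) return(.chainMetrics(assembly, M))
  sol <- attr(md, "solution")
  if (!is.null(sol)) return(.wrappedMetrics(assembly))
  # generic fall-back: fit a screw transform from the first two frames,
  # assuming chain order
  M <- .frameTransform(assembly@frames[[1]], assembly@frames[[2]])
  .chainMetrics(assembly, M)
}

.frameTransform <- function(fa, fb) {
  kb <- .kabsch(fa@vertices, fb@vertices)
  M <- diag(4); M[1:3, 1:3] <- kb$R; M[1:3, 4] <- kb$t
  M
}

.chainMetrics <- function(assembly, M) {
  sc <- .screwDecompose(M)
  ctrs <- frameCenters(assembly)
  if (abs(sc$angleDeg) < 1e-7) {
    # pure translation: straight strip, infinite radius
    return(new("TubeMetrics", nThreads = 1, risePerStep = sc$rise,
               risePerTurn = Inf, radius = Inf, threadGap = NA_real_,
               status = "strip"))
  }
  rad <- mean(sqrt(rowSums((sweep(ctrs, 2, sc$point) -
    outer(as.vector(sweep(ctrs, 2, sc$point) %*% sc$axis), sc$axis))^2)))
  if (rad > 1e6) {
    return(new("TubeMetrics", nThreads = 1, risePerStep = abs(sc$rise),
               risePerTurn = Inf, radius = Inf, threadGap = NA_real_,
               status = "strip"))
  }
  risePerTurn <- sc$rise * 360 / sc$angleDeg
  isRing <- abs(risePerTurn) < 1e-6
  gap <- .threadGap(assembly)
  new("TubeMetrics", nThreads = 1, risePerStep = abs(sc$rise),
      risePerTurn = if (isRing) 0 else abs(risePerTurn), radius = rad,
      threadGap = if (isRing) NA_real_ else gap,
      status = if (isRing) "ring" else "helix")
}

.wrappedMetrics <- function(assembly) {
  md <- assembly@metadata
  r <- attr(md, "radius")
  sol <- attr(md, "solution")
  nThreads <- length(unique(md$thread))
  risePerStep <- abs(sol@P[2])                  # axial rise per strip step
  # one full turn along a thread spans n_p steps (closure equality)
  risePerTurn <- abs(sol@params@np * sol@P[2])
  gap <- .threadGap(assembly)
  new("TubeMetrics", nThreads = nThreads, risePerStep = risePerStep,
      risePerTurn = risePerTurn, radius = r, threadGap = gap,
      status = "helix")
}

## Closest ring-ring approach between adjacent threads: across threads when
## the assembly has several, between non-consecutive chain members (turns of
## the single helix) otherwise.
.threadGap <- function(assembly) {
  fr <- assembly@frames
  n <- length(fr)
  md <- assembly@metadata
  threads <- if (!is.null(md$thread) && nrow(md) == n) md$thread else
    rep(0L, n)
  steps <- if (!is.null(md$step) && nrow(md) == n) md$step else seq_len(n)
  multi <- length(unique(threads)) > 1
  best <- Inf
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (multi) {
      if (threads[i] == threads[j]) next
    } else {
      if (abs(steps[i] - steps[j]) <= 1) next
    }
    d <- .ringDist(fr[[i]]@vertices, fr[[j]]@vertices)
    if (d < best) best <- d
  }
  if (!is.finite(best)) NA_real_ else best
}

#' Scan thread gap against bending/torsion angles
#'
#' Builds one helix per (bending, torsion) pair and tabulates the thread
#' gap, rise and radius. When `bending` and `torsion` have equal length
#' they are paired as a path (the default mirrors the twisted-tube trend:
#' decreasing bending with increasing torsion); otherwise the full grid is
#' scanned.
#'
#' @param bending,torsion numeric vectors (degrees).
#' @param attach attachment parameter.
#' @param nSteps pentamers per helix.
#' @return data.frame: bending, torsion, thread_gap, rise_per_step,
#'   rise_per_turn, radius, status.
#' @export
gapAngleScan <- function(bending = seq(154, 136, length.out = 10),
                         torsion = seq(0.5, 30, length.out = 10),
                         attach = 0.5, nSteps = 24) {
  if (!length(bending) || !length(torsion))
    stop("bending and torsion ranges must be nonempty")
  if (length(bending) == length(torsion)) {
    grid <- data.frame(bending = bending, torsion = torsion)
  } else {
    grid <- expand.grid(bending = bending, torsion = torsion)
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    h <- buildHelix(helixSpec(grid$bending[i], grid$torsion[i], attach,
                              nSteps))
    m <- threadMetrics(h)
    data.frame(bending = grid$bending[i], torsion = grid$torsion[i],
               thread_gap = m@threadGap, rise_per_step = m@risePerStep,
               rise_per_turn = m@risePerTurn, radius = m@radius,
               status = m@status, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

setMethod("show", "HelixSpec", function(object) {
  cat(sprintf("HelixSpec: bending %.2f deg, torsion %.2f deg, attach %.2f, %d steps\n",
              object@bending, object@torsion, object@attach, object@nSteps))
})

setMethod("show", "TubeMetrics", function(object) {
  cat(sprintf("TubeMetrics [%s]: %d thread(s), rise/step %.4f, rise/turn %s, radius %s, thread gap %s\n",
              object@status, object@nThreads, object@risePerStep,
              format(object@risePerTurn, digits = 4),
              format(object@radius, digits = 4),
              format(object@threadGap, digits = 4)))
})
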