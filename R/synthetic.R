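## Synthetic assembly generators: parameterized pentameric fixtures so that
## angle measurement and network analysis are testable with no structural
## database.

#' Dodecahedral cage fixture
#'
#' Twelve pentamer frames on the faces of a regular dodecahedron, normals
#' outward, with five subunit centroids per frame (60 subunits in total, as
#' in a T = 1 pentameric cage). Every pair of adjacent faces meets at the
#' dodecahedral bending angle acos(-1/sqrt(5)) ~ 116.565 degrees with zero
#' torsion.
#'
#' @param circumradius circumradius of each pentagon face (model unit).
#' @return An [Assembly-class] of 12 frames.
#' @export
makeDodecahedron <- function(circumradius = 1) {
  if (circumradius <= 0) stop("circumradius must be positive")
  phi <- (1 + sqrt(5)) / 2
  vs <- rbind(
    expand.grid(x = c(-1, 1), y = c(-1, 1), z = c(-1, 1)),
    do.call(rbind, lapply(list(c(0, 1 / phi, phi), c(1 / phi, phi, 0),
                               c(phi, 0, 1 / phi)), function(p) {
      expand.grid(x = if (p[1] == 0) 0 else c(-p[1], p[1]),
                  y = if (p[2] == 0) 0 else c(-p[2], p[2]),
                  z = if (p[3] == 0) 0 else c(-p[3], p[3]))
    })))
  vs <- unique(as.matrix(vs))
  dirs <- rbind(
    do.call(rbind, lapply(list(c(0, phi, 1), c(phi, 1, 0), c(1, 0, phi)),
                          function(p) {
      expand.grid(x = if (p[1] == 0) 0 else c(-p[1], p[1]),
                  y = if (p[2] == 0) 0 else c(-p[2], p[2]),
                  z = if (p[3] == 0) 0 else c(-p[3], p[3]))
    })))
  dirs <- unique(as.matrix(dirs))
  dirs <- dirs / sqrt(rowSums(dirs^2))
  frames <- list()
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    sel <- order(vs %*% u, decreasing = TRUE)[1:5]
    face <- vs[sel, , drop = FALSE]
    frames[[i]] <- fitPolygonFrame(face, label = sprintf("pent%02d", i))
  }
  # rescale so each face pentagon has the requested circumradius
  sc <- circumradius /
    mean(sqrt(rowSums(sweep(frames[[1]]@vertices, 2,
                            frames[[1]]@center)^2)))
  frames <- lapply(frames, function(f)
    .makeFrame(f@center * sc, f@normal, f@vertices * sc, f@label))
  asm <- assembly(frames, scale = 1)
  asm <- .orientOutward(asm)
  asm@subunitCoords <- lapply(asm@frames, function(f)
    sweep(0.8 * sweep(f@vertices, 2, f@center), 2, f@center, "+"))
  validObject(asm)
  asm
}

#' Spherical cage shell fixture
#'
#' Pentamers (circumradius 1) tangent to a sphere at approximately
#' equidistributed points (deterministic Fibonacci spiral; the seed sets a
#' reproducible global rotation), normals radial. `n = 12` is special-cased
#' to the exact icosahedrally symmetric arrangement. In cage series whose
#' pentamer count grows with the shell surface (as in the 12/24/36-pentamer
#' cages), larger shells give larger nearest-neighbour bending angles.
#'
#' @param nPentamers number of pentamers (>= 4).
#' @param radius sphere radius in circumradius units.
#' @param seed integer seed (orientation only; output is bit-reproducible).
#' @return An [Assembly-class].
#' @export
makeSphereCage <- function(nPentamers, radius, seed = 1) {
  if (nPentamers < 4 || nPentamers != round(nPentamers))
    stop("nPentamers must be an integer >= 4")
  if (radius <= 0) stop("radius must be positive")
  if (nPentamers == 12) {
    dod <- makeDodecahedron(1)
    dirs <- t(vapply(dod@frames, function(f) .unit(f@center), numeric(3)))
  } else {
    i <- seq_len(nPentamers) - 0.5
    z <- 1 - 2 * i / nPentamers
    th <- pi * (1 + sqrt(5)) * i
    r2 <- sqrt(pmax(0, 1 - z^2))
    dirs <- cbind(r2 * cos(th), r2 * sin(th), z)
  }
  set.seed(seed)
  ax <- .unit(stats::rnorm(3))
  R <- .rotmat(ax, stats::runif(1, 0, 360))
  dirs <- dirs %*% t(R)
  frames <- list()
  for (i in seq_len(nrow(dirs))) {
    u <- dirs[i, ]
    b1 <- .unit(if (abs(u[1]) < 0.9) c(1, 0, 0) - u[1] * u else
      c(0, 1, 0) - u[2] * u)
    b2 <- c(u[2] * b1[3] - u[3] * b1[2], u[3] * b1[1] - u[1] * b1[3],
            u[1] * b1[2] - u[2] * b1[1])
    ang <- 2 * pi * (0:4) / 5
    verts <- sweep(outer(cos(ang), b1) + outer(sin(ang), b2), 2,
                   radius * u, "+")
    frames[[i]] <- .makeFrame(radius * u, u, verts, sprintf("pent%02d", i))
  }
  asm <- assembly(frames, scale = 1)
  asm@subunitCoords <- lapply(asm@frames, function(f)
    sweep(0.8 * sweep(f@vertices, 2, f@center), 2, f@center, "+"))
  asm
}

#' Add Gaussian positional noise to an assembly
#'
#' Applies isotropic Gaussian displacements to the subunit coordinates and
#' refits every frame from its noisy subunits ([fitPolygonFrame()]); the
#' refitted normal keeps the hemisphere of the original.
#'
#' @param assembly an [Assembly-class] (subunit coordinates are generated
#'   from the vertex rings if absent).
#' @param sigma displacement standard deviation (model units), >= 0.
#' @param seed integer seed; output is bit-reproducible.
#' @return An [Assembly-class] with refitted frames.
#' @export
addNoise <- function(assembly, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (!length(assembly@subunitCoords))
    assembly@subunitCoords <- lapply(assembly@frames, function(f)
      sweep(0.8 * sweep(f@vertices, 2, f@center), 2, f@center, "+"))
  if (sigma == 0) return(assembly)
  set.seed(seed)
  frames <- assembly@frames
  subs <- assembly@subunitCoords
  for (i in seq_along(frames)) {
    noisy <- subs[[i]] + matrix(stats::rnorm(15, 0, sigma), 5, 3)
    f <- fitPolygonFrame(noisy, label = frames[[i]]@label)
    if (sum(f@normal * frames[[i]]@normal) < 0) f@normal <- -f@normal
    frames[[i]] <- f
    subs[[i]] <- noisy
  }
  # refitted frames may not match noisy subunits' plane exactly at high
  # sigma; subunit coordinates are the noisy ones by construction
  asm <- assembly
  asm@frames <- frames
  asm@subunitCoords <- subs
  asm
}

#' Write an assembly to a structure file
#'
#' Writes a pseudo-atom PDB: one chain per subunit (chain IDs cycle through
#' A-Z, a-z, 0-9 when more than 62 subunits are present), the residue number
#' identifies the capsomer, and each subunit carries two carbon pseudo-atoms
#' (occupancy 1.00): its centroid and its pentagon vertex. Re-reading the
#' file with [measureStructure()] reproduces all frames and pairwise angles
#' within tolerance.
#'
#' @param assembly a non-empty [Assembly-class].
#' @param path output file.
#' @param format only "pdb" is supported.
#' @param scale physical length per model unit applied on export
#'   (default: the assembly's scale slot).
#' @return `path`, invisibly.
#' @export
writeStructure <- function(assembly, path, format = "pdb", scale = NULL) {
  if (!nFrames(assembly)) stop("assembly is empty")
  format <- tolower(format)
  if (format != "pdb")
    stop("unsupported format '", format, "': only PDB output is supported")
  if (is.null(scale)) scale <- assembly@scale
  if (!length(assembly@subunitCoords))
    assembly@subunitCoords <- lapply(assembly@frames, function(f)
      sweep(0.8 * sweep(f@vertices, 2, f@center), 2, f@center, "+"))
  chains <- c(LETTERS, letters, 0:9)
  xyz <- list(); chain <- character(0); resno <- integer(0)
  elety <- character(0)
  sub <- 0L
  for (j in seq_along(assembly@frames)) {
    f <- assembly@frames[[j]]
    sc <- assembly@subunitCoords[[j]]
    for (s in 1:5) {
      sub <- sub + 1L
      ch <- chains[((sub - 1L) %% length(chains)) + 1L]
      xyz[[length(xyz) + 1]] <- sc[s, ] * scale
      xyz[[length(xyz) + 1]] <- f@vertices[s, ] * scale
      chain <- c(chain, ch, ch)
      resno <- c(resno, j, j)
      elety <- c(elety, "CEN", "VRT")
    }
  }
  co <- do.call(rbind, xyz)
  n <- nrow(co)
  bio3d::write.pdb(file = path, xyz = as.vector(t(co)),
                   resno = resno, chain = chain, resid = rep("SUB", n),
                   elety = elety, eleno = seq_len(n),
                   o = rep(1, n), b = rep(0, n), elesy = rep("C", n))
  invisible(path)
}
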