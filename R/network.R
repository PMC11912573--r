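## Capsomer interaction networks and symmetry-respecting rewiring.

#' Build the capsomer interaction network of an assembly
#'
#' Nodes are pentamer centres. Weight-1 edges are the detected contacts;
#' candidate weight-0 edges are next-nearest pairs within twice the contact
#' threshold. Edges are partitioned into (helical) symmetry-equivalence
#' classes: for lattice-derived assemblies (from [wrapToCylinder()]) the
#' classes are exact orbits of the lattice translations, otherwise pairs are
#' clustered by their geometric signature (distance, bending, torsion). Each
#' class records which pentagon edges it engages on each endpoint; contact
#' classes engage their collinear contact edge, candidate docking classes
#' engage every edge within a slack of the minimum ring distance (a corner
#' docking engages both flanking edges). Engagements drive the realizability
#' constraints of [enumerateRewirings()].
#'
#' @param assembly an [Assembly-class] with >= 2 frames.
#' @param threshold contact threshold (model units); default 0.15 x median
#'   ring edge length.
#' @return A [ContactNetwork-class].
#' @export
networkFromAssembly <- function(assembly, threshold = NULL) {
  if (nFrames(assembly) < 2) stop("assembly must contain at least 2 frames")
  s <- .medianEdge(assembly)
  if (is.null(threshold)) threshold <- 0.15 * s
  pairs <- .allNearPairs(assembly, 2 * threshold)
  pairs$weight <- as.integer(pairs$ring_gap < threshold)
  if (!any(pairs$weight == 1))
    stop("no contacts detected at threshold ", format(threshold))
  md <- assembly@metadata
  lattice <- all(c("kind", "u", "v") %in% names(md)) &&
    nrow(md) == nFrames(assembly)
  labs <- frameLabels(assembly)
  circumference <- if (!is.null(attr(md, "radius")))
    2 * pi * attr(md, "radius") else NULL
  if (lattice) {
    ia <- match(pairs$frame_a, labs); ib <- match(pairs$frame_b, labs)
    key <- character(nrow(pairs))
    for (r in seq_len(nrow(pairs))) {
      i <- ia[r]; j <- ib[r]
      ki <- md$kind[i]; kj <- md$kind[j]
      duv <- c(md$u[j] - md$u[i], md$v[j] - md$v[i])
      if (!is.null(circumference))  # reduce across the rolling seam
        duv[1] <- duv[1] - circumference * round(duv[1] / circumference)
      if (ki == kj) {
        if (duv[2] < 0 || (abs(duv[2]) < 1e-9 && duv[1] < 0)) duv <- -duv
      } else if (ki > kj) {  # order U before D
        tmp <- ki; ki <- kj; kj <- tmp
        duv <- -duv
      }
      key[r] <- sprintf("%s-%s:%+.3f,%+.3f", ki, kj, duv[1], duv[2])
    }
  } else {
    key <- sprintf("d%.2f/b%.1f/t%.1f", round(pairs$distance, 2),
                   round(pairs$bending_deg, 1),
                   round(abs(pairs$torsion_deg), 1))
  }
  pairs$class <- key
  # class table with engaged pentagon-edge slots
  cls <- unique(pairs[, c("class", "weight")])
  if (anyDuplicated(cls$class))
    cls <- cls[!duplicated(cls$class), , drop = FALSE]
  cls$engages <- vapply(cls$class, function(cl) {
    rows <- which(pairs$class == cl)
    slots <- character(0)
    for (r in rows[seq_len(min(2, length(rows)))]) {
      i <- match(pairs$frame_a[r], labs); j <- match(pairs$frame_b[r], labs)
      ki <- if (lattice) md$kind[i] else "X"
      kj <- if (lattice) md$kind[j] else "X"
      isContact <- pairs$weight[r] == 1
      slots <- c(slots,
                 paste0(ki, ":", .engagedEdges(assembly@frames[[i]],
                                               assembly@frames[[j]], s,
                                               contact = isContact)),
                 paste0(kj, ":", .engagedEdges(assembly@frames[[j]],
                                               assembly@frames[[i]], s,
                                               contact = isContact)))
    }
    paste(sort(unique(slots)), collapse = ",")
  }, character(1))
  nodes <- data.frame(label = labs,
                      x = frameCenters(assembly)[, 1],
                      y = frameCenters(assembly)[, 2],
                      z = frameCenters(assembly)[, 3],
                      kind = if (lattice) md$kind else "X",
                      u = if (lattice) md$u else NA_real_,
                      v = if (lattice) md$v else NA_real_,
                      stringsAsFactors = FALSE)
  edges <- data.frame(a = pairs$frame_a, b = pairs$frame_b,
                      weight = pairs$weight, class = pairs$class,
                      stringsAsFactors = FALSE)
  new("ContactNetwork", nodes = nodes, edges = edges,
      classes = data.frame(class = cls$class, weight = cls$weight,
                           engages = cls$engages, stringsAsFactors = FALSE))
}

## All frame pairs with ring gap below maxGap, with angles.
.allNearPairs <- function(assembly, maxGap) {
  fr <- assembly@frames
  ctrs <- frameCenters(assembly)
  rmax <- max(vapply(fr, function(f)
    max(sqrt(rowSums(sweep(f@vertices, 2, f@center)^2))), numeric(1)))
  out <- list()
  n <- length(fr)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)) > 2 * rmax + maxGap) next
    gap <- .ringDist(fr[[i]]@vertices, fr[[j]]@vertices)
    if (gap >= maxGap) next
    ap <- bendingTorsion(fr[[i]], fr[[j]])
    out[[length(out) + 1]] <- data.frame(
      frame_a = fr[[i]]@label, frame_b = fr[[j]]@label,
      distance = sqrt(sum((ctrs[i, ] - ctrs[j, ])^2)),
      bending_deg = ap@bending, torsion_deg = ap@torsion,
      ring_gap = gap, stringsAsFactors = FALSE)
  }
  if (!length(out)) stop("no near pairs within ", format(maxGap))
  do.call(rbind, out)
}

## Pentagon edges of frame `fa` engaged by the interaction with `fb`.
## For contacts the engaged edge is the one carrying near-parallel collinear
## overlap with a partner edge; for candidate (non-contact) dockings it is
## every edge within a slack of the minimum ring distance, so that a corner
## docking engages both flanking edges.
.engagedEdges <- function(fa, fb, edgeLen, contact = TRUE, slack = 0.08) {
  va <- fa@vertices; vb <- fb@vertices
  na <- nrow(va); nb <- nrow(vb)
  if (contact) {
    eng <- integer(0)
    for (i in seq_len(na)) {
      i2 <- if (i == na) 1 else i + 1
      u <- .unit(va[i2, ] - va[i, ])
      for (j in seq_len(nb)) {
        j2 <- if (j == nb) 1 else j + 1
        w <- vb[j2, ] - vb[j, ]
        if (abs(sum(u * w) / sqrt(sum(w^2))) < cos(.deg2rad(30))) next
        if (.segSegDist(va[i, ], va[i2, ], vb[j, ], vb[j2, ]) >
              0.25 * edgeLen) next
        t1 <- sum((vb[j, ] - va[i, ]) * u)
        t2 <- sum((vb[j2, ] - va[i, ]) * u)
        ov <- min(sqrt(sum((va[i2, ] - va[i, ])^2)), max(t1, t2)) -
          max(0, min(t1, t2))
        if (ov > 0.05 * edgeLen) eng <- c(eng, i)
      }
    }
    if (length(eng)) return(sort(unique(eng)))
    # fall through to the proximity rule for point-like contacts
  }
  d <- vapply(seq_len(na), function(i) {
    i2 <- if (i == na) 1 else i + 1
    best <- Inf
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1 else j + 1
      dd <- .segSegDist(va[i, ], va[i2, ], vb[j, ], vb[j2, ])
      if (dd < best) best <- dd
    }
    best
  }, numeric(1))
  which(d <= min(d) + slack * edgeLen)
}

#' Enumerate admissible rewirings of a contact network
#'
#' Exhaustively re-assigns weights over the symmetry classes, keeping
#' architectures that are realizable by one pentamer with five asymmetric
#' interaction surfaces: no two weight-1 classes may engage the same
#' pentagon edge of the same node kind, every node keeps at most 5 contacts,
#' the weight-1 subgraph must connect all capsomers, and the contact set
#' must be maximal (assembly is adhesion-driven, so any contact that can
#' form does). The input architecture is excluded from the result.
#'
#' @param network a [ContactNetwork-class].
#' @return list of [ContactNetwork-class] alternatives (possibly empty).
#' @examples
#' \donttest{
#' tube <- wrapToCylinder(solveLattice(latticeParams(2.18, 3, 4)), 2)
#' net <- networkFromAssembly(tube, threshold = 0.25 * 2 * sin(pi / 5))
#' alts <- enumerateRewirings(net)  # exactly one: the twisted-tube network
#' }
#' @export
enumerateRewirings <- function(network) {
  cls <- network@classes
  k <- nrow(cls)
  if (k > 16) stop("too many edge classes for exhaustive enumeration")
  slots <- strsplit(cls$engages, ",")
  conflict <- matrix(FALSE, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j && length(intersect(slots[[i]], slots[[j]])))
      conflict[i, j] <- TRUE
  }
  input <- cls$weight
  admissible <- function(w) {
    on <- which(w == 1)
    if (!length(on)) return(FALSE)
    for (i in on) if (any(conflict[i, on])) return(FALSE)
    .networkRealizable(network, cls$class[on])
  }
  maximal <- function(w) {
    for (i in which(w == 0)) {
      w2 <- w; w2[i] <- 1
      if (admissible(w2)) return(FALSE)
    }
    TRUE
  }
  out <- list()
  for (code in seq_len(2^k) - 1) {
    w <- as.integer(intToBits(code)[seq_len(k)] == 1)
    if (identical(w, as.integer(input))) next
    if (!admissible(w) || !maximal(w)) next
    net2 <- network
    net2@classes$weight <- w
    net2@edges$weight <- w[match(net2@edges$class, cls$class)]
    out[[length(out) + 1]] <- net2
  }
  out
}

## Degree cap and connectivity of the weight-1 subgraph.
.networkRealizable <- function(network, onClasses) {
  ed <- network@edges[network@edges$class %in% onClasses, , drop = FALSE]
  if (!nrow(ed)) return(FALSE)
  g <- igraph::graph_from_data_frame(ed[, c("a", "b")], directed = FALSE,
                                     vertices = network@nodes$label)
  if (max(igraph::degree(g)) > 5) return(FALSE)
  igraph::is_connected(g)
}

#' Face sizes of the planar (unrolled) interaction network
#'
#' Traces the faces of the network drawn at the unrolled lattice
#' coordinates and returns the sizes of its bounded faces. Available for
#' lattice-derived networks only.
#'
#' @param network a [ContactNetwork-class] with lattice coordinates.
#' @param classes which classes to draw (default: the weight-1 classes).
#' @return integer vector of bounded-face sizes.
#' @export
networkFaces <- function(network, classes = NULL) {
  nd <- network@nodes
  if (all(is.na(nd$u))) stop("faces require unrolled lattice coordinates")
  if (is.null(classes))
    classes <- network@classes$class[network@classes$weight == 1]
  ed <- network@edges[network@edges$class %in% classes, , drop = FALSE]
  pos <- cbind(nd$u, nd$v)
  rownames(pos) <- nd$label
  # drop edges crossing the rolling seam: they are not planar in the
  # unrolled drawing
  span <- diff(range(nd$u))
  du <- abs(pos[ed$a, 1] - pos[ed$b, 1])
  ed <- ed[du < span / 2, , drop = FALSE]
  adj <- split(c(ed$b, ed$a), c(ed$a, ed$b))
  # rotation system: neighbours sorted counterclockwise
  rot <- lapply(names(adj), function(a) {
    nb <- unique(adj[[a]])
    ang <- atan2(pos[nb, 2] - pos[a, 2], pos[nb, 1] - pos[a, 1])
    nb[order(ang)]
  })
  names(rot) <- names(adj)
  visited <- new.env(hash = TRUE)
  sizes <- integer(0)
  for (r in seq_len(nrow(ed))) {
    for (de in list(c(ed$a[r], ed$b[r]), c(ed$b[r], ed$a[r]))) {
      keyStart <- paste(de, collapse = ">")
      if (!is.null(visited[[keyStart]])) next
      face <- character(0)
      cur <- de
      area2 <- 0
      repeat {
        key <- paste(cur, collapse = ">")
        if (!is.null(visited[[key]])) break
        visited[[key]] <- TRUE
        face <- c(face, cur[1])
        a <- cur[1]; b <- cur[2]
        area2 <- area2 + pos[a, 1] * pos[b, 2] - pos[b, 1] * pos[a, 2]
        nb <- rot[[b]]
        idx <- match(a, nb)
        nxt <- nb[if (idx == 1) length(nb) else idx - 1]  # clockwise turn
        cur <- c(b, nxt)
        if (identical(cur, de)) {
          if (area2 > 1e-9) sizes <- c(sizes, length(face))
          break
        }
      }
    }
  }
  sort(sizes)
}

setMethod("show", "ContactNetwork", function(object) {
  cat("ContactNetwork:", nrow(object@nodes), "capsomers,",
      sum(object@edges$weight == 1), "contacts and",
      sum(object@edges$weight == 0), "candidate edges in",
      nrow(object@classes), "symmetry classes\n")
  for (i in seq_len(nrow(object@classes)))
    cat(sprintf("  [w=%d] %s  engages {%s}\n", object@classes$weight[i],
                object@classes$class[i], object@classes$engages[i]))
})
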