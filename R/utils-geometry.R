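# Small internal geometry helpers shared across modules.

.unit <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("zero-length vector cannot be normalized")
  v / n
}

.deg2rad <- function(x) x * pi / 180
.rad2deg <- function(x) x * 180 / pi

## Rodrigues rotation matrix for unit axis u, angle in degrees.
.rotmat <- function(u, angleDeg) {
  th <- .deg2rad(angleDeg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

## 2D rotation matrix, angle in degrees.
.rot2 <- function(angleDeg) {
  th <- .deg2rad(angleDeg)
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

## Signed area of a 2D polygon (rows = vertices).
.signedArea <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  i2 <- c(seq_len(nrow(v))[-1], 1)
  sum(x * y[i2] - x[i2] * y) / 2
}

## Area of the intersection of two convex 2D polygons
## (Sutherland-Hodgman clipping; no polygon-clipping package is installed).
.convexClipArea <- function(subj, clip) {
  if (.signedArea(clip) < 0) clip <- clip[nrow(clip):1, , drop = FALSE]
  out <- subj
  nc <- nrow(clip)
  for (i in seq_len(nc)) {
    if (nrow(out) == 0) return(0)
    a <- clip[i, ]; b <- clip[if (i == nc) 1 else i + 1, ]
    e <- b - a
    side <- function(p) e[1] * (p[2] - a[2]) - e[2] * (p[1] - a[1])
    inp <- out
    out <- matrix(numeric(0), 0, 2)
    n <- nrow(inp)
    for (j in seq_len(n)) {
      p <- inp[j, ]; q <- inp[if (j == n) 1 else j + 1, ]
      sp <- side(p); sq <- side(q)
      if (sp >= 0) out <- rbind(out, p)
      if ((sp > 0 && sq < 0) || (sp < 0 && sq > 0)) {
        t <- sp / (sp - sq)
        out <- rbind(out, p + t * (q - p))
      }
    }
  }
  if (nrow(out) < 3) return(0)
  abs(.signedArea(out))
}

## Minimum distance between two 3D segments (a1-a2, b1-b2).
.segSegDist <- function(a1, a2, b1, b2) {
  d1 <- a2 - a1; d2 <- b2 - b1; r <- a1 - b1
  a <- sum(d1 * d1); e <- sum(d2 * d2); f <- sum(d2 * r)
  if (a < 1e-14 && e < 1e-14) return(sqrt(sum(r * r)))
  if (a < 1e-14) {
    s <- 0; t <- min(max(f / e, 0), 1)
  } else {
    c1 <- sum(d1 * r)
    if (e < 1e-14) {
      t <- 0; s <- min(max(-c1 / a, 0), 1)
    } else {
      b <- sum(d1 * d2)
      den <- a * e - b * b
      s <- if (den > 1e-14) min(max((b * f - c1 * e) / den, 0), 1) else 0
      t <- (b * s + f) / e
      if (t < 0) { t <- 0; s <- min(max(-c1 / a, 0), 1) }
      else if (t > 1) { t <- 1; s <- min(max((b - c1) / a, 0), 1) }
    }
  }
  sqrt(sum((a1 + s * d1 - (b1 + t * d2))^2))
}

## Minimum distance between two closed vertex rings (5x3 matrices),
## exact over all edge pairs.
.ringDist <- function(va, vb) {
  na <- nrow(va); nb <- nrow(vb)
  best <- Inf
  for (i in seq_len(na)) {
    i2 <- if (i == na) 1 else i + 1
    for (j in seq_len(nb)) {
      j2 <- if (j == nb) 1 else j + 1
      d <- .segSegDist(va[i, ], va[i2, ], vb[j, ], vb[j2, ])
      if (d < best) best <- d
    }
  }
  best
}

## Best rigid transform (rotation R, translation t) mapping x onto y
## (Kabsch); returns list(R, t) with y ~ x %*% t(R) + t.
.kabsch <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  H <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = cy - as.vector(R %*% cx))
}
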