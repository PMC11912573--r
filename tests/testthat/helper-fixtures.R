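# Shared fixtures, built once per test run.

.fx <- new.env()

fxDodeca <- function() {
  if (is.null(.fx$dodeca)) .fx$dodeca <- makeDodecahedron(1)
  .fx$dodeca
}

fxSol34 <- function() {
  if (is.null(.fx$sol34)) .fx$sol34 <- solveLattice(latticeParams(2.18, 3, 4))
  .fx$sol34
}

fxTube34 <- function() {
  if (is.null(.fx$tube34)) .fx$tube34 <- wrapToCylinder(fxSol34(), 2)
  .fx$tube34
}

fxNet34 <- function() {
  if (is.null(.fx$net34))
    .fx$net34 <- networkFromAssembly(fxTube34(),
                                     threshold = 0.25 * 2 * sin(pi / 5))
  .fx$net34
}

dodecaBending <- function() 180 / pi * acos(-1 / sqrt(5))

# Independent bracketed root-scan oracle for the lattice closure: for each
# trial `a` the four contact conditions are solved for (g, P) and the
# closure residual n_p * P_y - n_h * b is evaluated; the root is bracketed
# on a grid and refined with uniroot.
rootScanA <- function(b, nh, np, lo = -5, hi = 5, nGrid = 1000) {
  ang <- 2 * pi * (0:4) / 5
  V <- cbind(cos(ang), sin(ang))
  S <- 2 * sin(pi / 5); APO <- cos(pi / 5)
  nhat <- t(sapply(1:5, function(k) {
    k2 <- if (k == 5) 1 else k + 1
    e <- (V[k2, ] - V[k, ]) / S
    n <- c(e[2], -e[1])
    if (sum(n * (V[k, ] + V[k2, ]) / 2) < 0) n <- -n
    n
  }))
  # canonical assignment: classes on edges 1,3,2,5 at offsets
  # g, g-P, g-P+H, g-H
  edges <- c(1, 3, 2, 5); ms <- c(0, -1, -1, 0); ks <- c(0, 0, 1, -1)
  resid <- function(a) {
    H <- c(a, b)
    A <- matrix(0, 4, 4); rhs <- numeric(4)
    for (i in 1:4) {
      n <- nhat[edges[i], ]
      A[i, ] <- c(n[1], n[2], ms[i] * n[1], ms[i] * n[2])
      rhs[i] <- 2 * APO - ks[i] * sum(n * H)
    }
    x <- solve(A, rhs)
    np * x[4] - nh * b
  }
  grid <- seq(lo, hi, length.out = nGrid)
  vals <- vapply(grid, resid, numeric(1))
  sgn <- which(diff(sign(vals)) != 0)
  if (!length(sgn)) return(NA_real_)
  stats::uniroot(resid, c(grid[sgn[1]], grid[sgn[1] + 1]),
                 tol = 1e-12)$root
}
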