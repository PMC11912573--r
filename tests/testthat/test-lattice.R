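test_that("the biological (3,4) tiling solves and is feasible", {
  sol <- fxSol34()
  expect_equal(latticeStatus(sol), "feasible")
  expect_false(flipRequired(sol))
  expect_gt(sol@a, 0)
  expect_lt(sol@a, 5)
  expect_equal(sol@H[2], 2.18)
  # closure equality between the axial components
  expect_lt(abs(4 * sol@P[2] - 3 * 2.18), 1e-9)
  expect_gt(sol@theta, 0)
  expect_lt(sol@theta, 180)
  cp <- contactPercentage(sol)
  expect_true(all(cp$perEdge >= 0 & cp$perEdge <= 100))
  expect_true(all(cp$perClass > 0))
})

test_that("the solver agrees with a bracketed root-scan oracle", {
  for (nh in 1:6) for (np in 1:10) {
    sol <- solveLattice(latticeParams(2.18, nh, np))
    if (latticeStatus(sol) != "feasible") next
    aOracle <- rootScanA(2.18, nh, np)
    expect_false(is.na(aOracle))
    expect_equal(sol@a, aOracle, tolerance = 1e-9)
  }
})

test_that("forbidden combinations are screened correctly", {
  expect_error(latticeParams(2.18, 0, 4), "positive integer")
  s31 <- solveLattice(latticeParams(2.18, 3, 1))
  expect_equal(latticeStatus(s31), "geometrically_forbidden")
  expect_error(contactPercentage(s31), "feasible")
  # interior-overlap screening fires for strip offsets that are too tight
  tight <- solveLattice(latticeParams(1.5, 3, 4))
  expect_equal(latticeStatus(tight), "geometrically_forbidden")
  expect_true(tight@overlap)
  expect_error(wrapToCylinder(s31), "feasible")
  s44 <- solveLattice(latticeParams(2.18, 4, 4))
  expect_equal(latticeStatus(s44), "flip_required")
  expect_true(flipRequired(s44))
  expect_false(flipRequired(solveLattice(latticeParams(2.18, 4, 5))))
})

test_that("contact percentage handles full-edge and isolated cases", {
  pc <- pentatube:::.pentaConsts()
  mid1 <- (pc$V[1, ] + pc$V[2, ]) / 2
  shared <- list(g = 2 * mid1, P = c(50, 0), H = c(0, 50))
  pe <- pentatube:::.contactPerEdge(shared)
  expect_equal(unname(pe[1]), 100, tolerance = 1e-9)
  expect_equal(unname(pe[2:5]), rep(0, 4))
  isolated <- list(g = c(30, 30), P = c(50, 0), H = c(0, 50))
  expect_equal(unname(pentatube:::.contactPerEdge(isolated)), rep(0, 5))
})

test_that("mean contact matches a Monte-Carlo edge-sampling oracle", {
  sol <- fxSol34()
  pc <- pentatube:::.pentaConsts()
  set.seed(99)
  nPer <- 2e5
  covered <- numeric(5)
  for (e in 1:5) {
    e2 <- if (e == 5) 1 else e + 1
    ts <- runif(nPer, 0, pc$S)
    inside <- rep(FALSE, nPer)
    for (m in -3:3) for (k in -2:2) {
      q <- sol@g + m * sol@P + k * sol@H
      if (abs(sum(pc$NHAT[e, ] * q) - 2 * cos(pi / 5)) > 1e-7) next
      t0 <- sum((q - pc$V[e2, ] - pc$V[e, ]) * pc$EHAT[e, ])
      t1 <- sum((q - pc$V[e, ] - pc$V[e, ]) * pc$EHAT[e, ])
      inside <- inside | (ts >= min(t0, t1) & ts <= max(t0, t1))
    }
    covered[e] <- 100 * mean(inside)
  }
  expect_equal(mean(covered), contactPercentage(sol)$mean, tolerance = 0.1)
})

test_that("enumeration reproduces the published feasibility pattern", {
  tab <- enumerateTilings(2.18, 1:6, 1:10)
  expect_equal(nrow(tab), 60)
  for (nh in 1:6) {
    sub <- tab[tab$n_h == nh & tab$feasible, ]
    expect_gt(nrow(sub), 0)
    best <- sub$n_p[which.max(sub$mean_contact_percent)]
    expect_equal(best, min(sub$n_p))
  }
  # the diagonal needs flipped pentagons, unrealizable for proteins
  expect_true(tab$flip_required[tab$n_h == 4 & tab$n_p == 4])
  expect_false(tab$feasible[tab$n_h == 4 & tab$n_p == 4])
  expect_true(tab$feasible[tab$n_h == 3 & tab$n_p == 4])
  expect_true(tab$feasible[tab$n_h == 4 & tab$n_p == 5])
  expect_equal(nrow(enumerateTilings(2.18, integer(0), 1:3)), 0)
})

test_that("edge-contact construction points obey the 144-degree rotation", {
  ecc <- edgeContactConstruction(fxSol34())
  pc <- pentatube:::.pentaConsts()
  expect_equal(ecc@rotationDeg, 144)
  expect_equal(ecc@R3 - ecc@R1, pc$V[1, ] - pc$V[3, ], tolerance = 1e-12)
  # T is the counterclockwise 144-degree image of R1 about the origin
  Tpt <- ecc@T
  rot <- pentatube:::.rot2(144)
  expect_equal(Tpt, as.vector(rot %*% ecc@R1), tolerance = 1e-12)
  measured <- atan2(ecc@R1[1] * Tpt[2] - ecc@R1[2] * Tpt[1],
                    sum(ecc@R1 * Tpt)) * 180 / pi
  expect_equal(measured, 144, tolerance = 1e-9)
  # the rotation maps edge P1P2 onto edge P3P4, carrying R1 to a point of
  # that edge with |P4 T| = |P2 R1|
  expect_equal(as.vector(rot %*% pc$V[1, ]), pc$V[3, ], tolerance = 1e-12)
  expect_equal(as.vector(rot %*% pc$V[2, ]), pc$V[4, ], tolerance = 1e-12)
  tcoord <- sum((Tpt - pc$V[3, ]) * pc$EHAT[3, ])
  expect_gte(tcoord, 0)
  expect_lte(tcoord, pc$S)
  expect_equal(sqrt(sum((Tpt - pc$V[4, ])^2)),
               sqrt(sum((ecc@R1 - pc$V[2, ])^2)), tolerance = 1e-12)
})

test_that("wrapping yields the three-thread tube with the paper's angle signs", {
  tube <- fxTube34()
  md <- assemblyMetadata(tube)
  expect_equal(length(unique(md$thread)), 3)
  m <- threadMetrics(tube)
  expect_equal(m@nThreads, 3)
  # lattice-identified pentagons land on the same 3D position
  sol <- fxSol34()
  C <- 4 * sol@P - 3 * sol@H
  r <- attr(md, "radius")
  pc <- pentatube:::.pentaConsts()
  uv <- c(1.3, 2.1)
  f1 <- pentatube:::.wrapFrame(uv, pc$V, r, "a")$frame
  f2 <- pentatube:::.wrapFrame(uv + C, pc$V, r, "b")$frame
  expect_equal(frameCenter(f1), frameCenter(f2), tolerance = 1e-6)
  expect_equal(frameVertices(f1), frameVertices(f2), tolerance = 1e-6)
  # intrathread torsions positive, interthread negative, bending above the
  # dodecahedral cage value
  ct <- detectContacts(tube)
  labs <- frameLabels(tube)
  ia <- match(ct$frame_a, labs); ib <- match(ct$frame_b, labs)
  intra <- md$thread[ia] == md$thread[ib] & md$kind[ia] != md$kind[ib]
  inter <- md$thread[ia] != md$thread[ib]
  expect_true(all(ct$torsion_deg[intra] > 0))
  expect_true(any(ct$torsion_deg[inter] < 0))
  expect_gt(mean(ct$bending_deg), dodecaBending())
})
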