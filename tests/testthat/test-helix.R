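test_that("consecutive helix frames return the specified angles exactly", {
  for (beta in c(120, 140, 155)) {
    for (tau in c(-25, 0, 12, 30)) {
      h <- buildHelix(helixSpec(beta, tau, 0.5, 6))
      fr <- assemblyFrames(h)
      for (i in 1:5) {
        ap <- bendingTorsion(fr[[i]], fr[[i + 1]])
        expect_equal(ap@bending, beta, tolerance = 1e-6)
        expect_equal(ap@torsion, tau, tolerance = 1e-6)
      }
    }
  }
  # off-centre attachment keeps the contract
  h <- buildHelix(helixSpec(145, 18, 0.25, 4))
  ap <- bendingTorsion(assemblyFrames(h)[[2]], assemblyFrames(h)[[3]])
  expect_equal(ap@bending, 145, tolerance = 1e-6)
  expect_equal(ap@torsion, 18, tolerance = 1e-6)
})

test_that("helix construction is deterministic with exact screw symmetry", {
  h1 <- buildHelix(helixSpec(142, 17, 0.4, 8))
  h2 <- buildHelix(helixSpec(142, 17, 0.4, 8))
  expect_identical(frameCenters(h1), frameCenters(h2))
  fr <- assemblyFrames(h1)
  M1 <- pentatube:::.frameTransform(fr[[1]], fr[[2]])
  for (i in 2:7) {
    Mi <- pentatube:::.frameTransform(fr[[i]], fr[[i + 1]])
    expect_equal(Mi, M1, tolerance = 1e-9)
  }
})

test_that("zero torsion closes rings with no helical rise", {
  # solve the bending angle whose step rotation is 360/k (ring of k)
  stepAngle <- function(beta) {
    h <- buildHelix(helixSpec(beta, 0, 0.5, 2))
    M <- attr(assemblyMetadata(h), "helixStep")
    abs(pentatube:::.screwDecompose(M)$angleDeg)
  }
  betaClose <- uniroot(function(b) stepAngle(b) - 360 / 6,
                       c(100, 150), tol = 1e-10)$root
  h <- buildHelix(helixSpec(betaClose, 0, 0.5, 7))
  m <- threadMetrics(h)
  expect_equal(m@status, "ring")
  expect_equal(m@risePerStep, 0, tolerance = 1e-8)
  expect_equal(m@risePerTurn, 0)
  # frame 7 closes onto frame 1
  expect_equal(frameCenter(assemblyFrames(h)[[7]]),
               frameCenter(assemblyFrames(h)[[1]]), tolerance = 1e-6)
  # any zero-torsion chain stays rise-free (ring-shaped arrangement)
  for (beta in c(120, 140, 160, 180)) {
    m <- threadMetrics(buildHelix(helixSpec(beta, 0, 0.5, 6)))
    expect_equal(m@status, "ring")
    expect_lt(m@risePerStep, 1e-8)
  }
})

test_that("metrics recover a known rise from an independent construction", {
  # frames placed analytically on a helix (no builder involved)
  hRise <- 0.37; dphi <- 2 * pi / 7.3; rad <- 1.9
  ang <- 2 * pi * (0:4) / 5
  frames <- lapply(0:9, function(i) {
    phi <- i * dphi
    ctr <- c(rad * cos(phi), rad * sin(phi), i * hRise)
    n <- c(cos(phi), sin(phi), 0)
    t <- c(-sin(phi), cos(phi), 0)
    verts <- sweep(outer(cos(ang), t) + outer(sin(ang), c(0, 0, 1)), 2,
                   ctr, "+")
    pentatube:::.makeFrame(ctr, n, verts, sprintf("f%d", i))
  })
  m <- threadMetrics(assembly(frames))
  expect_equal(m@risePerStep, hRise, tolerance = 1e-6)
  expect_equal(m@radius, rad, tolerance = 1e-6)
  expect_equal(m@risePerTurn, hRise * 2 * pi / dphi, tolerance = 1e-6)
  # metrics are invariant under rigid motion
  R <- pentatube:::.rotmat(c(1, 0, 0) / 1, 63)
  m2 <- threadMetrics(transformAssembly(assembly(frames), R, c(5, -1, 2)))
  expect_equal(m2@risePerStep, m@risePerStep, tolerance = 1e-6)
  expect_equal(m2@radius, m@radius, tolerance = 1e-6)
})

test_that("the gap scan shows the twisted-tube trend", {
  tab <- gapAngleScan(nSteps = 22)
  expect_true(all(diff(tab$bending) < 0))
  expect_true(all(diff(tab$torsion) > 0))
  expect_true(all(diff(tab$thread_gap) > 0))
  # compacted dual-thread geometry at the low-torsion end
  expect_lt(tab$thread_gap[1], 0.1)
  one <- gapAngleScan(bending = 140, torsion = 20, nSteps = 12)
  expect_equal(nrow(one), 1)
  expect_error(gapAngleScan(numeric(0), numeric(0)), "nonempty")
})

test_that("helix specs are validated", {
  expect_error(helixSpec(0, 0), "bending")
  expect_error(helixSpec(120, 0, attach = 1.5), "attach")
  expect_error(helixSpec(120, 0, nSteps = 0), "nSteps")
})
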