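test_that("dodecahedron contacts show the analytic bending angle", {
  ct <- detectContacts(fxDodeca(), threshold = 0.2)
  expect_equal(nrow(ct), 30)
  expect_equal(ct$bending_deg, rep(dodecaBending(), 30), tolerance = 1e-9)
  expect_equal(ct$torsion_deg, rep(0, 30), tolerance = 1e-9)
  expect_equal(ct$contact_fraction, rep(1, 30), tolerance = 1e-6)
})

test_that("coplanar pairs are flat and twisting sets the torsion", {
  pr <- pairFromAngles(bending = 180, torsion = 0)
  ap <- bendingTorsion(pr$a, pr$b)
  expect_equal(ap@bending, 180, tolerance = 1e-9)
  expect_equal(ap@torsion, 0, tolerance = 1e-9)
  # rotating pentamer b about the centre-to-centre axis by +10 degrees
  # yields torsion +10 with the bending unchanged
  pr2 <- pairFromAngles(bending = 150, torsion = 0)
  d <- pentatube:::.unit(frameCenter(pr2$b) - frameCenter(pr2$a))
  b2 <- pr2$b
  b2@normal <- as.vector(pentatube:::.rotmat(d, 10) %*% b2@normal)
  b2@vertices <- rotateAboutAxis(b2@vertices, frameCenter(b2), d, 10)
  ap2 <- bendingTorsion(pr2$a, b2)
  expect_equal(ap2@torsion, 10, tolerance = 1e-9)
  expect_equal(ap2@bending, 150, tolerance = 1e-9)
})

test_that("constructed pairs round-trip their angles exactly", {
  # mid-edge attachment covers the full angle window
  for (beta in c(95, 120, 150, 175)) {
    for (tau in c(-35, -10, 0, 10, 35)) {
      pr <- pairFromAngles(beta, tau, attach = 0.5)
      ap <- bendingTorsion(pr$a, pr$b)
      expect_equal(ap@bending, beta, tolerance = 1e-6)
      expect_equal(ap@torsion, tau, tolerance = 1e-6)
    }
  }
  # off-centre attachment in the tube-relevant bending range
  for (beta in c(125, 150, 175)) {
    for (tau in c(-35, 0, 35)) {
      for (att in c(0.2, 0.8)) {
        pr <- pairFromAngles(beta, tau, attach = att)
        ap <- bendingTorsion(pr$a, pr$b)
        expect_equal(ap@bending, beta, tolerance = 1e-6)
        expect_equal(ap@torsion, tau, tolerance = 1e-6)
      }
    }
  }
  # sharp bending is geometrically unreachable far off the edge midpoint
  expect_error(pairFromAngles(95, 0, attach = 0.05), "not attainable")
})

test_that("bending is symmetric and signed torsion is swap-invariant", {
  # The signed dihedral about the centre-to-centre axis does not change
  # when the pair is read in the opposite order (the axis reverses together
  # with the order), exactly as for backbone torsion angles.
  set.seed(11)
  ang <- 2 * pi * (0:4) / 5
  ring <- cbind(cos(ang), sin(ang), 0)
  for (rep in 1:20) {
    mk <- function() {
      ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
      R <- pentatube:::.rotmat(ax, runif(1, 0, 360))
      ctr <- rnorm(3, sd = 2)
      fitPolygonFrame(sweep(ring %*% t(R), 2, ctr, "+"))
    }
    fa <- mk(); fb <- mk()
    ab <- bendingTorsion(fa, fb)
    ba <- bendingTorsion(fb, fa)
    expect_equal(ab@bending, ba@bending, tolerance = 1e-9)
    expect_equal(ab@torsion, ba@torsion, tolerance = 1e-9)
  }
})

test_that("angles are invariant under rigid transformation of the assembly", {
  set.seed(5)
  ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
  R <- pentatube:::.rotmat(ax, 77)
  moved <- transformAssembly(fxDodeca(), R, c(3, -2, 11))
  ct0 <- detectContacts(fxDodeca(), 0.2)
  ct1 <- detectContacts(moved, 0.2)
  expect_equal(nrow(ct1), nrow(ct0))
  expect_equal(sort(ct1$bending_deg), sort(ct0$bending_deg),
               tolerance = 1e-9)
  expect_equal(sort(ct1$torsion_deg), sort(ct0$torsion_deg),
               tolerance = 1e-9)
})

test_that("contact detection handles edge cases", {
  one <- assembly(list(assemblyFrames(fxDodeca())[[1]]))
  expect_equal(nrow(detectContacts(one, 0.2)), 0)
  expect_error(detectContacts(fxDodeca(), -0.1), "positive")
  # interior pentamers of the (3,4) straight tube have four contacts
  ct <- detectContacts(fxTube34())
  counts <- table(c(ct$frame_a, ct$frame_b))
  expect_equal(max(counts), 4)
  expect_gt(sum(counts == 4), nFrames(fxTube34()) / 2)
})

test_that("structure files round-trip through write and measure", {
  path <- tempfile(fileext = ".pdb")
  writeStructure(fxDodeca(), path, scale = 10)
  ct <- measureStructure(path)
  expect_equal(nrow(ct), 30)
  expect_equal(ct$bending_deg, rep(dodecaBending(), 30), tolerance = 1e-4)
  expect_lt(max(abs(ct$torsion_deg)), 0.01)
  unlink(path)
})

test_that("capsomer groups with fewer than 3 subunits are rejected", {
  path <- tempfile(fileext = ".pdb")
  writeStructure(fxDodeca(), path)
  pdb <- bio3d::read.pdb(path)
  chains <- unique(pdb$atom$chain[pdb$atom$resno == 1])
  groups <- data.frame(chain = unique(pdb$atom$chain),
                       capsomer = "all", stringsAsFactors = FALSE)
  groups$capsomer[groups$chain %in% chains[1:2]] <- "tiny"
  expect_error(measureStructure(path, groups = groups), "fewer than 3")
  expect_error(measureStructure(tempfile(), NULL), "cannot read")
  unlink(path)
})

test_that("bending grows with cage size in area-scaled sphere-cage series", {
  sizes <- c(12, 24, 36)
  meanBend <- vapply(sizes, function(n) {
    cage <- makeSphereCage(n, sqrt(n / 12) * 1.4, seed = 7)
    ctr <- frameCenters(cage)
    fr <- assemblyFrames(cage)
    nn <- vapply(seq_len(n), function(i) {
      d <- sqrt(rowSums(sweep(ctr, 2, ctr[i, ])^2))
      order(d)[2]
    }, integer(1))
    mean(vapply(seq_len(n), function(i)
      bendingTorsion(fr[[i]], fr[[nn[i]]])@bending, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(meanBend) > 0))
})
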