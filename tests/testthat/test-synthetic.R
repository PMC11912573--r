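test_that("the dodecahedron fixture has 12 pentamers and 60 subunits", {
  dod <- fxDodeca()
  expect_equal(nFrames(dod), 12)
  expect_equal(sum(vapply(dod@subunitCoords, nrow, integer(1))), 60)
  r <- vapply(assemblyFrames(dod), function(f)
    mean(sqrt(rowSums(sweep(frameVertices(f), 2, frameCenter(f))^2))),
    numeric(1))
  expect_equal(r, rep(1, 12), tolerance = 1e-9)
  # normals point outward
  out <- vapply(assemblyFrames(dod), function(f)
    sum(frameNormal(f) * frameCenter(f)) > 0, logical(1))
  expect_true(all(out))
  expect_error(makeDodecahedron(0), "positive")
})

test_that("sphere cages are deterministic and special-case n = 12", {
  c1 <- makeSphereCage(20, 1.8, seed = 4)
  c2 <- makeSphereCage(20, 1.8, seed = 4)
  expect_identical(frameCenters(c1), frameCenters(c2))
  c3 <- makeSphereCage(20, 1.8, seed = 5)
  expect_false(identical(frameCenters(c1), frameCenters(c3)))
  # n = 12 reproduces the icosahedrally symmetric direction set: all
  # nearest-neighbour angular separations equal the icosahedral value
  cage <- makeSphereCage(12, 2, seed = 1)
  dirs <- frameCenters(cage) / 2
  cosnn <- vapply(1:12, function(i) {
    d <- dirs %*% dirs[i, ]
    max(d[-i])
  }, numeric(1))
  expect_equal(cosnn, rep(1 / sqrt(5), 12), tolerance = 1e-9)
  expect_error(makeSphereCage(3, 1), ">= 4")
})

test_that("noise perturbs frames reproducibly and mildly at sigma 0.01", {
  dod <- fxDodeca()
  expect_identical(frameCenters(addNoise(dod, 0, seed = 1)),
                   frameCenters(dod))
  n1 <- addNoise(dod, 0.01, seed = 3)
  n2 <- addNoise(dod, 0.01, seed = 3)
  expect_identical(frameCenters(n1), frameCenters(n2))
  # adjacency from the clean cage; bending within 2 degrees of the
  # analytic value for at least 95% of edges across 100 noise draws
  ct <- detectContacts(dod, 0.2)
  labs <- frameLabels(dod)
  ia <- match(ct$frame_a, labs); ib <- match(ct$frame_b, labs)
  nOk <- 0; nTot <- 0
  for (seed in 1:100) {
    nz <- addNoise(dod, 0.01, seed = seed)
    fr <- assemblyFrames(nz)
    for (r in seq_len(nrow(ct))) {
      b <- bendingTorsion(fr[[ia[r]]], fr[[ib[r]]])@bending
      nTot <- nTot + 1
      if (abs(b - dodecaBending()) < 2) nOk <- nOk + 1
    }
  }
  expect_gte(nOk / nTot, 0.95)
  expect_error(addNoise(dod, -1), "non-negative")
})

test_that("structure writing validates inputs and applies the scale", {
  dod <- fxDodeca()
  expect_error(writeStructure(assembly(list()), tempfile()), "empty")
  expect_error(writeStructure(dod, tempfile(), format = "cif"),
               "unsupported")
  p1 <- tempfile(fileext = ".pdb"); p10 <- tempfile(fileext = ".pdb")
  writeStructure(dod, p1, scale = 1)
  writeStructure(dod, p10, scale = 10)
  a1 <- bio3d::read.pdb(p1)$atom
  a10 <- bio3d::read.pdb(p10)$atom
  expect_equal(a10$x, 10 * a1$x, tolerance = 1e-2)
  expect_equal(a10$y, 10 * a1$y, tolerance = 1e-2)
  unlink(c(p1, p10))
})

test_that("written tubes re-measure with the same angle pattern", {
  tube <- fxTube34()
  path <- tempfile(fileext = ".pdb")
  writeStructure(tube, path, scale = 100)
  # fitted frames carry subunit-centroid rings (10% smaller than the
  # vertex rings), so a wider threshold recovers the same contact set
  ct <- measureStructure(path, threshold = 35)
  ct0 <- detectContacts(tube)
  expect_equal(nrow(ct), nrow(ct0))
  expect_equal(sort(ct$bending_deg), sort(ct0$bending_deg),
               tolerance = 5e-3)
  expect_equal(sort(ct$torsion_deg), sort(ct0$torsion_deg),
               tolerance = 5e-3)
  unlink(path)
})
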