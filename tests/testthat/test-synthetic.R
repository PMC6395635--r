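test_that("phantom rasterization matches a per-pixel membership oracle", {
  g <- imagingGrid(32, 32)
  ## empty ellipse list -> zero image
  expect_true(all(makePhantom(g, sheppLoganEllipses()[0, ]) == 0))
  ## single centered disc: interior 1, exterior 0, background exactly zero
  disc <- data.frame(x = 0, y = 0, a = 0.5, b = 0.5, angle = 0, intensity = 1)
  img <- makePhantom(g, disc)
  u <- 2 * centeredCoords(32) / 32
  inside <- outer(u, u, function(a, b) a^2 + b^2 <= 0.25)
  expect_equal(Re(img[, , 1]), inside + 0)
  expect_true(all(img[!inside] == 0))
  ## overlapping ellipses add signed intensities, per-pixel oracle
  two <- data.frame(x = c(0, 0.1), y = c(0, 0), a = c(0.5, 0.3), b = c(0.5, 0.2),
                    angle = c(0, 30), intensity = c(1, -0.4))
  img2 <- makePhantom(g, two)
  U <- matrix(2 * centeredCoords(32) / 32, 32, 32)
  V <- t(U)
  oracle <- matrix(0, 32, 32)
  for (r in 1:2) {
    th <- two$angle[r] * pi / 180
    du <- U - two$x[r]; dv <- V - two$y[r]
    ru <- du * cos(th) + dv * sin(th); rv <- -du * sin(th) + dv * cos(th)
    oracle <- oracle + two$intensity[r] * ((ru / two$a[r])^2 + (rv / two$b[r])^2 <= 1)
  }
  expect_equal(Re(img2[, , 1]), oracle)
  ## determinism
  expect_identical(makePhantom(g), makePhantom(g))
})

test_that("simulated coils are smooth with nowhere-zero sum of squares", {
  g <- imagingGrid(64, 64)
  coils <- makeCoils(g, 8)
  d <- gridDims(g)
  ## single coil, constant profile: the identity case
  cid <- array(1 + 0i, dim = c(d, 1))
  expect_equal(dim(cid)[4], 1L)
  ## spectral smoothness audit: <= 1% energy outside the low-k ball
  ## (lowest 25% of the k-space radius)
  kr <- sqrt(outer(centeredCoords(64)^2, centeredCoords(64)^2, `+`))
  lowk <- kr <= 0.25 * 32
  for (j in 1:8) {
    K <- Mod(fftc(array(coils[, , , j], dim = d)))^2
    expect_lt(sum(K[!lowk]) / sum(K), 0.01)
  }
  ## recoverability: RSS strictly positive over the FOV
  ssq <- array(0, d)
  for (j in 1:8) ssq <- ssq + Mod(array(coils[, , , j], dim = d))^2
  expect_gt(min(ssq), 0)
})

test_that("k-space simulation coincides with the k = 1 forward model", {
  set.seed(81)
  g <- imagingGrid(16, 16)
  d <- gridDims(g)
  truth <- makePhantom(g)
  coils <- makeCoils(g, 3)
  ## zero image -> zero data
  z <- simulateKspace(array(0 + 0i, dim = d), coils)
  expect_true(all(z@kspace == 0))
  ## constant image and constant coil: single nonzero DC sample
  cc <- array(1 + 0i, dim = c(d, 1))
  k1 <- simulateKspace(array(2 + 0i, dim = d), cc)
  ks <- array(k1@kspace[, , , 1], dim = d)
  expect_equal(Mod(ks[9, 9, 1]), 2 * 16, tolerance = 1e-10)  # 2 * sqrt(N)
  ks[9, 9, 1] <- 0
  expect_lt(max(Mod(ks)), 1e-10)
  ## agreement with the estimate-based forward operator
  w <- weightValues(coilWeighting(), g)
  wc <- array(0 + 0i, dim = c(d, 3, 1))
  for (j in 1:3) wc[, , , j, 1] <- applyWeighting(array(coils[, , , j], dim = d),
                                                  coilWeighting(), g, w)
  x <- multisetEstimate(g, array(truth, dim = c(d, 1)), wc)
  data <- simulateKspace(truth, coils)
  expect_lt(relErr(enliveForward(x, data), data@kspace), 1e-10)
  ## masked and radial paths
  pat <- regularPattern(g, accel = 2L)
  dm <- simulateKspace(truth, coils, pat)
  expect_true(all(dm@kspace[!dm@mask] == 0))
  traj <- radialTrajectory(8, 24, g)
  dn <- simulateKspace(truth, coils, traj)
  expect_equal(nrow(dn@samples), 8L * 24L)
})

test_that("noise injection is calibrated as percent of the DC magnitude", {
  g <- imagingGrid(24, 24)
  truth <- makePhantom(g)
  coils <- makeCoils(g, 2)
  data <- simulateKspace(truth, coils)
  dc <- dcMagnitude(data)
  expect_gt(dc, 0)
  ## level 0 leaves data untouched
  expect_identical(addNoise(data, 0, seed = 3)@kspace, data@kspace)
  ## Monte-Carlo check: sample std over ~1e5 draws within 2% of level% * |DC|
  noisy <- addNoise(data, 5, seed = 3)
  dev <- noisy@kspace - data@kspace
  draws <- c(Re(dev), Im(dev))
  expect_equal(sd(draws), 0.05 * dc, tolerance = 0.02)
  ## determinism per seed; different seeds differ
  expect_identical(addNoise(data, 5, seed = 3)@kspace, noisy@kspace)
  expect_false(identical(addNoise(data, 5, seed = 4)@kspace, noisy@kspace))
  ## non-Cartesian: DC reference is the maximum-magnitude sample
  traj <- radialTrajectory(6, 24, g)
  dn <- simulateKspace(truth, coils, traj)
  expect_equal(dcMagnitude(dn), max(Mod(dn@samples)))
})

test_that("limited-FOV scenario reproduces the spatial aliasing identity", {
  g <- imagingGrid(32, 32)
  d <- gridDims(g)
  sc <- limitedFovScenario(g, margin = 6, nc = 4)
  ## folding oracle: the wrapped coil images equal the explicit sum of
  ## FOV-shifted copies of the extended-grid products
  dE <- gridDims(imagingGrid(32, 64))
  for (j in 1:4) {
    prod_ <- array(sc$coilsExt[, , , j], dim = dE) * array(sc$imageExt, dim = dE)
    manual <- array(0 + 0i, dim = c(32, 32))
    for (yf in 1:32) {
      e1 <- ((yf - 1 - 16 + 32) %% 64) + 1
      e2 <- ((yf - 1 - 16 + 32 + 32) %% 64) + 1
      manual[, yf] <- prod_[, e1, 1] + prod_[, e2, 1]
    }
    expect_lt(relErr(array(sc$foldedCoilImages[, , , j], dim = d[1:2]), manual), 1e-10)
  }
  ## k-space route: subsampling every 2nd extended line matches the folded
  ## transform up to the sqrt(2) aliasing scale
  j <- 1
  prod_ <- array(sc$coilsExt[, , , j], dim = dE) * array(sc$imageExt, dim = dE)
  Kext <- fftc(array(prod_, dim = c(32, 64, 1)))
  Ksub <- Kext[, seq(1, 64, by = 2), 1]           # even centered k indices
  Kfov <- fftc(array(sc$foldedCoilImages[, , , j], dim = d))
  expect_lt(relErr(sqrt(2) * Ksub, array(Kfov, dim = c(32, 32))), 1e-10)
  ## reference equals the RSS of the folded products
  expect_lt(relErr(sc$reference, rssReference(
    array(1 + 0i, dim = d), sc$foldedCoilImages)), 1e-12)
})

test_that("virtual conjugate coils implement the point-reflected conjugate", {
  g <- imagingGrid(16, 16)
  d <- gridDims(g)
  ## single nonzero sample v at k0 -> conj(v) at -k0 in the virtual channel
  ks <- array(0 + 0i, dim = c(d, 1))
  ks[11, 6, 1, 1] <- 2 + 3i                      # k = (2, -3)
  v <- vccExtend(kspaceCartesian(g, ks))
  expect_equal(nChannels(v), 2L)
  expect_equal(v@kspace[7, 12, 1, 2], 2 - 3i)    # k = (-2, 3)
  ## real image, real coils, full sampling: virtual channels equal originals
  img <- makePhantom(g)
  rc <- Mod(makeCoils(g, 3)) + 0i                 # strip coil phase
  data <- simulateKspace(img, rc)
  vd <- vccExtend(data)
  for (j in 1:3) {
    expect_lt(relErr(vd@kspace[, , , 3 + j], vd@kspace[, , , j]), 1e-10)
  }
  ## mask popcounts preserved per channel, reflected for virtual channels
  pat <- partialFourierMask(g, 5 / 8, axis = 2)
  du <- vccExtend(simulateKspace(img, rc, pat))
  cnt <- sampleCounts(du)
  expect_equal(cnt[1:3], cnt[4:6])
  expect_false(identical(du@mask[, , , 1], du@mask[, , , 4]))
  ## non-Cartesian input is rejected
  traj <- radialTrajectory(4, 16, g)
  expect_error(vccExtend(simulateKspace(img, rc, traj)), "Cartesian")
})

test_that("phase singularities carry the prescribed winding number", {
  g <- imagingGrid(64, 64)
  f1 <- phaseSingularityImage(g, charge = 1L)
  expect_equal(windingNumber(f1, 33, 33, 10), 1)
  ## charge 0: constant phase
  f0 <- phaseSingularityImage(g, charge = 0L)
  expect_lt(max(abs(Arg(f0) - Arg(f0[1, 1, 1]))), 1e-12)
  ## conjugate field has winding -1
  expect_equal(windingNumber(Conj(f1), 33, 33, 10), -1)
  ## charge 2
  expect_equal(windingNumber(phaseSingularityImage(g, charge = 2L), 33, 33, 10), 2)
  ## magnitude is 1 everywhere
  expect_lt(max(abs(Mod(f1) - 1)), 1e-12)
  ## initial guess container: all images singular, coils zero
  x0 <- singularInitialGuess(g, k = 2, nc = 4)
  expect_equal(nSets(x0), 2L)
  expect_true(all(x0@wcoils == 0))
  expect_equal(array(x0@images[, , , 1], dim = gridDims(g)), f1)
})
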