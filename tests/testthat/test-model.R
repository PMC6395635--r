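test_that("k-space penalty matches its closed form and basic properties", {
  g <- imagingGrid(8, 8)
  ## literal integer-coordinate normalization: direct evaluation of the formula
  w <- weightValues(coilWeighting(a = 240, b = 40, normalization = "grid"), g)
  ctr <- c(5, 5, 1)
  expect_identical(w[5, 5, 1], 1)
  expect_equal(w[6, 5, 1], 241^20)          # ||k||^2 = 1
  expect_equal(w[5, 6, 1], 241^20)
  expect_true(all(w > 0))
  ## zero exponent: unit weight everywhere
  w0 <- weightValues(coilWeighting(a = 240, b = 0), g)
  expect_true(all(w0 == 1))
  ## radially nondecreasing along an axis from the center outward
  wu <- weightValues(coilWeighting(), imagingGrid(16, 1))
  expect_true(all(diff(as.vector(wu)[9:16]) >= 0))
  expect_true(all(diff(as.vector(wu)[8:1]) >= 0))
})

test_that("coil weighting transform inverts exactly and matches a dense DFT oracle", {
  set.seed(11)
  g <- imagingGrid(8, 8)
  spec <- coilWeighting()
  d <- gridDims(g)
  c0 <- array(randc(64), dim = d)
  expect_lt(relErr(applyWeightingInverse(applyWeighting(c0, spec, g), spec, g), c0), 1e-12)
  ## zero maps to zero
  expect_true(all(applyWeightingInverse(array(0 + 0i, dim = d), spec, g) == 0))
  ## delta at the k-space center with weight 1 there -> constant image v/sqrt(N)
  del <- array(0 + 0i, dim = d)
  del[5, 5, 1] <- 3 + 2i
  img <- applyWeightingInverse(del, spec, g)
  Fd <- denseDftMatrix(d)
  oracle <- Conj(t(Fd)) %*% (as.vector(del) / as.vector(weightValues(spec, g)))
  expect_lt(relErr(as.vector(img), as.vector(oracle)), 1e-12)
  expect_lt(max(Mod(img - (3 + 2i) / sqrt(64))), 1e-12)
})

test_that("forward operator matches the dense-matrix oracle and is additive over sets", {
  set.seed(21)
  g <- imagingGrid(8, 8)
  d <- gridDims(g)
  x <- randEstimate(g, k = 2, nc = 2)
  data <- kspaceCartesian(g, array(randc(prod(d) * 2), dim = c(d, 2)))
  fwd <- enliveForward(x, data)
  expect_lt(relErr(fwd, denseForward(x)), 1e-10)

  ## zero images -> zero samples
  x0 <- x; x0@images[] <- 0 + 0i
  expect_equal(max(Mod(enliveForward(x0, data))), 0)

  ## a k = 2 estimate with set 2 zeroed equals the k = 1 forward on set 1
  x2 <- x
  x2@images[, , , 2] <- 0 + 0i
  x2@wcoils[, , , , 2] <- 0 + 0i
  x1 <- multisetEstimate(g, x@images[, , , 1, drop = FALSE],
                         x@wcoils[, , , , 1, drop = FALSE], x@weighting)
  expect_lt(relErr(enliveForward(x2, data), enliveForward(x1, data)), 1e-12)

  ## additivity: sum of single-set forwards equals the multiset forward
  x2b <- multisetEstimate(g, x@images[, , , 2, drop = FALSE],
                          x@wcoils[, , , , 2, drop = FALSE], x@weighting)
  expect_lt(relErr(enliveForward(x1, data) + enliveForward(x2b, data),
                   enliveForward(x, data)), 1e-12)

  ## masked path agrees with the masked dense oracle
  mask <- array(runif(prod(d)) > 0.4, dim = d)
  mask[5, 5, 1] <- TRUE
  dataM <- kspaceCartesian(g, array(randc(prod(d) * 2), dim = c(d, 2)), mask)
  expect_lt(relErr(enliveForward(x, dataM), denseForward(x, mask)), 1e-10)

  ## grid mismatch errors
  dataBad <- kspaceCartesian(imagingGrid(4, 4), array(randc(32), dim = c(4, 4, 1, 2)))
  expect_error(enliveForward(x, dataBad), "grid")
})

test_that("derivative is the first-order expansion and linear in the perturbation", {
  set.seed(31)
  g <- imagingGrid(8, 8)
  d <- gridDims(g)
  x <- randEstimate(g, k = 2, nc = 2)
  data <- kspaceCartesian(g, array(randc(prod(d) * 2), dim = c(d, 2)))
  dx <- list(images = array(randc(prod(d) * 2), dim = c(d, 2)),
             wcoils = array(randc(prod(d) * 4), dim = c(d, 2, 2)))

  ## dx = 0 -> 0
  z <- list(images = 0 * dx$images, wcoils = 0 * dx$wcoils)
  expect_equal(max(Mod(enliveDerivative(x, z, data))), 0)

  ## at the standard initialization both bilinear factors of the cross terms
  ## vanish when the perturbation hits the zero blocks only
  xInit <- initializeEstimate(g, 2, 2)
  dImgOnly <- list(images = dx$images, wcoils = 0 * dx$wcoils)
  ## m-perturbation weighted by zero coils -> zero output
  expect_equal(max(Mod(enliveDerivative(xInit, dImgOnly, data))), 0)

  ## finite differences: halving epsilon divides the error by ~4 (O(eps^2))
  f0 <- enliveForward(x, data)
  dv <- enliveDerivative(x, dx, data)
  errAt <- function(eps) {
    xp <- x
    xp@images <- x@images + eps * dx$images
    xp@wcoils <- x@wcoils + eps * dx$wcoils
    sqrt(sum(Mod(enliveForward(xp, data) - f0 - eps * dv)^2))
  }
  e1 <- errAt(1e-2); e2 <- errAt(5e-3)
  expect_lt(e2 / e1, 0.3)

  ## linearity in dx
  dv2 <- enliveDerivative(x, list(images = 2 * dx$images, wcoils = 2 * dx$wcoils), data)
  expect_lt(relErr(dv2, 2 * dv), 1e-12)

  ## shape mismatch errors
  expect_error(enliveDerivative(x, list(images = dx$images[, , , 1, drop = FALSE],
                                        wcoils = dx$wcoils), data), "shape")
})

test_that("adjoint satisfies the inner-product identity and matches the dense transpose", {
  set.seed(41)
  g <- imagingGrid(8, 8)
  d <- gridDims(g)
  for (maskFrac in c(1, 0.5)) {
    mask <- array(runif(prod(d)) <= maskFrac, dim = d)
    mask[5, 5, 1] <- TRUE
    data <- kspaceCartesian(g, array(randc(prod(d) * 2), dim = c(d, 2)), mask)
    x <- randEstimate(g, k = 2, nc = 2)
    dx <- list(images = array(randc(prod(d) * 2), dim = c(d, 2)),
               wcoils = array(randc(prod(d) * 4), dim = c(d, 2, 2)))
    dy <- array(randc(prod(d) * 2), dim = c(d, 2))
    dy[!data@mask] <- 0 + 0i
    lhs <- sum(Conj(enliveDerivative(x, dx, data)) * dy)
    adj <- enliveAdjointDerivative(x, dy, data)
    rhs <- sum(Conj(dx$images) * adj$images) + sum(Conj(dx$wcoils) * adj$wcoils)
    expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
    ## zero data perturbation -> zero increment
    adj0 <- enliveAdjointDerivative(x, 0 * dy, data)
    expect_equal(max(Mod(adj0$images)), 0)
    expect_equal(max(Mod(adj0$wcoils)), 0)
  }

  ## single nonzero sample back-projection vs dense conjugate-transpose oracle
  x <- randEstimate(g, k = 1, nc = 1)
  data <- kspaceCartesian(g, array(randc(prod(d)), dim = c(d, 1)))
  ## dense derivative matrix via basis vectors of the (linear) perturbation
  nb <- 2 * prod(d)
  D <- matrix(0 + 0i, prod(d), nb)
  for (jb in seq_len(nb)) {
    v <- complex(nb); v[jb] <- 1
    dxb <- list(images = array(v[seq_len(prod(d))], dim = c(d, 1)),
                wcoils = array(v[-seq_len(prod(d))], dim = c(d, 1, 1)))
    D[, jb] <- as.vector(enliveDerivative(x, dxb, data))
  }
  dy <- array(0 + 0i, dim = c(d, 1))
  dy[3, 7, 1, 1] <- 2 - 1i
  adj <- enliveAdjointDerivative(x, dy, data)
  oracle <- Conj(t(D)) %*% as.vector(dy)
  expect_lt(relErr(c(as.vector(adj$images), as.vector(adj$wcoils)),
                   as.vector(oracle)), 1e-10)
})

test_that("grid-aligned non-Cartesian trajectory reproduces the Cartesian transform", {
  set.seed(51)
  d <- c(8L, 8L, 1L)
  g <- imagingGrid(8, 8)
  ## trajectory visiting every Cartesian k-space point
  ks <- expand.grid(kx = centeredCoords(8), ky = centeredCoords(8))
  x <- randEstimate(g, k = 1, nc = 2)
  dataC <- kspaceCartesian(g, array(randc(prod(d) * 2), dim = c(d, 2)))
  dataN <- kspaceNonCartesian(g, matrix(randc(64 * 2), 64, 2), cbind(ks$kx, ks$ky))
  fwdC <- enliveForward(x, dataC)
  fwdN <- enliveForward(x, dataN)
  for (j in 1:2) {
    expect_lt(relErr(array(fwdN[, j], dim = d[1:2]),
                     array(fwdC[, , , j], dim = d[1:2])), 1e-6)
  }
  ## non-Cartesian adjoint identity
  dx <- list(images = array(randc(64), dim = c(d, 1)),
             wcoils = array(randc(128), dim = c(d, 2, 1)))
  dy <- matrix(randc(128), 64, 2)
  lhs <- sum(Conj(enliveDerivative(x, dx, dataN)) * dy)
  adj <- enliveAdjointDerivative(x, dy, dataN)
  rhs <- sum(Conj(dx$images) * adj$images) + sum(Conj(dx$wcoils) * adj$wcoils)
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})

test_that("gridding non-uniform transform agrees with the exact direct path", {
  set.seed(61)
  g <- imagingGrid(32, 32)
  traj <- radialTrajectory(17, 48, g)
  img <- array(randc(1024), dim = gridDims(g))
  ## smooth test image: taper high frequencies so interpolation error is visible
  K <- fftc(img)
  kr <- sqrt(outer(centeredCoords(32)^2, centeredCoords(32)^2, `+`))
  K <- K * array(exp(-(kr / 10)^2), dim = dim(K))
  img <- ifftc(K)
  pd <- nufftPlan(trajCoords(traj), g, method = "direct")
  pg <- nufftPlan(trajCoords(traj), g, method = "gridding")
  sd_ <- nufftApply(pd, img)
  sg <- nufftApply(pg, img)
  expect_lt(relErr(sg, sd_), 1e-3)
  ## gridding adjoint is the exact transpose of the gridding forward
  y <- randc(nrow(trajCoords(traj)))
  lhs <- sum(Conj(nufftApply(pg, img)) * y)
  rhs <- sum(Conj(img) * nufftAdjoint(pg, y))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-10)
})
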