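test_that("initialization is all-ones images with zero coils, and forward of it is zero", {
  g <- imagingGrid(16, 16)
  x <- initializeEstimate(g, k = 1, nc = 4)
  expect_true(all(x@images == 1 + 0i))
  expect_true(all(x@wcoils == 0))
  expect_equal(dim(x@wcoils)[4:5], c(4L, 1L))
  ## symmetric multi-set initialization: identical all-ones images per set
  x3 <- initializeEstimate(g, k = 3, nc = 2)
  for (i in 2:3) expect_identical(x3@images[, , , i], x3@images[, , , 1])
  ## all coils zero -> the bilinear forward vanishes
  data <- kspaceCartesian(g, array(0.1 + 0i, dim = c(gridDims(g), 4)))
  expect_equal(max(Mod(enliveForward(x, data))), 0)
})

test_that("Gram-Schmidt removes projections in set order without renormalizing", {
  set.seed(91)
  g <- imagingGrid(8, 8)
  d <- gridDims(g)
  ## k = 1: unchanged
  x1 <- randEstimate(g, 1, 2)
  expect_identical(gramSchmidtCoils(x1)@wcoils, x1@wcoils)
  ## identical coil stacks: second set becomes exactly zero
  x <- randEstimate(g, 2, 2)
  x@wcoils[, , , , 2] <- x@wcoils[, , , , 1]
  xo <- gramSchmidtCoils(x)
  expect_lt(max(Mod(xo@wcoils[, , , , 2])), 1e-12 * max(Mod(x@wcoils)))
  expect_identical(xo@wcoils[, , , , 1], x@wcoils[, , , , 1])
  ## already-orthogonal sets are unchanged
  y <- randEstimate(g, 2, 1)
  v1 <- as.vector(y@wcoils[, , , , 1])
  v2 <- as.vector(y@wcoils[, , , , 2])
  v2 <- v2 - sum(Conj(v1) * v2) / sum(Mod(v1)^2) * v1
  y@wcoils[, , , , 2] <- array(v2, dim = d)
  yo <- gramSchmidtCoils(y)
  expect_lt(max(Mod(yo@wcoils - y@wcoils)), 1e-12 * max(Mod(y@wcoils)))
  ## a zero set stays zero (no division by zero)
  z <- randEstimate(g, 3, 2)
  z@wcoils[, , , , 2] <- 0 + 0i
  expect_no_error(zo <- gramSchmidtCoils(z))
  expect_true(all(zo@wcoils[, , , , 2] == 0))
  ## pairwise orthogonality after the sweep, k = 4
  q <- gramSchmidtCoils(randEstimate(g, 4, 3))
  V <- matrix(q@wcoils, ncol = 4)
  for (i in 1:3) for (j in (i + 1):4) {
    expect_lt(Mod(sum(Conj(V[, i]) * V[, j])),
              1e-10 * sqrt(sum(Mod(V[, i])^2) * sum(Mod(V[, j])^2)))
  }
})

test_that("a Newton step solves the regularized normal equations", {
  set.seed(101)
  g <- imagingGrid(8, 8)
  d <- gridDims(g)
  ## frozen known coil, single channel: the step is a linear Tikhonov solve,
  ## compared against a dense direct solution of the normal equations
  coil <- makeCoils(g, 1, sigma = 0.6)
  w <- weightValues(coilWeighting(), g)
  wc <- array(applyWeighting(array(coil[, , , 1], dim = d), coilWeighting(), g, w),
              dim = c(d, 1, 1))
  truth <- array(randc(64), dim = d)
  data <- simulateKspace(truth, coil)
  x <- multisetEstimate(g, array(1 + 0i, dim = c(d, 1)), wc)
  alpha <- 0.01
  cfg <- solverConfig(k = 1, cgTol = 1e-12, cgMaxIter = 500)
  st <- newtonStep(x, data, alpha, cfg, xref = x, freezeCoils = TRUE)
  ## dense oracle: A = F diag(c); (A^H A + alpha I) dm = A^H (y - A 1)
  Fd <- denseDftMatrix(d)
  A <- Fd %*% diag(as.vector(coil[, , , 1]))
  rhs <- Conj(t(A)) %*% (as.vector(data@kspace) - A %*% rep(1 + 0i, 64))
  H <- Conj(t(A)) %*% A + alpha * diag(64)
  mOracle <- 1 + solve(H, rhs)
  expect_lt(relErr(as.vector(st$estimate@images), as.vector(mOracle)), 1e-8)

  ## alpha -> infinity: the step collapses toward the reference
  xa <- randEstimate(g, 1, 1)
  xr <- randEstimate(g, 1, 1)
  dataR <- kspaceCartesian(g, array(randc(64), dim = c(d, 1)))
  stBig <- newtonStep(xa, dataR, 1e12, cfg, xref = xr)
  expect_lt(relErr(as.vector(stBig$estimate@images), as.vector(xr@images)), 1e-4)
  expect_lt(relErr(as.vector(stBig$estimate@wcoils), as.vector(xr@wcoils)), 1e-4)
})

test_that("the reconstruction applies the geometric schedule and stays deterministic", {
  g <- imagingGrid(24, 24)
  truth <- makePhantom(g)
  coils <- makeCoils(g, 4)
  data <- simulateKspace(truth, coils)
  cfg <- solverConfig(k = 2, nNewton = 5, weighting = coilWeighting(a = 24))
  fit <- enliveReconstruct(data, cfg)
  ## alpha_n = alpha0 q^(n-1), exactly
  expect_identical(fit@report@alpha, 1 * 0.5^(0:4))
  ## orthogonality after every step
  expect_true(all(fit@report@gramOffdiag <= 1e-8))
  ## determinism: identical inputs give identical outputs
  fit2 <- enliveReconstruct(data, cfg)
  expect_identical(fit@estimate@images, fit2@estimate@images)
  expect_identical(fit@estimate@wcoils, fit2@estimate@wcoils)
  ## residual nonincreasing on the noiseless single-set fixture (for k >= 2
  ## the orthogonalization is a non-descent projection, so only the overall
  ## decrease is guaranteed)
  fit1 <- enliveReconstruct(data, solverConfig(k = 1, nNewton = 5,
                                               weighting = coilWeighting(a = 24)))
  expect_true(all(diff(fit1@report@residual) <= 1e-8))
  expect_lt(fit@report@residual[5], fit@report@residual[1])
  ## error conditions
  bad <- data
  bad@kspace[1] <- NaN + 0i
  expect_error(enliveReconstruct(bad, cfg), class = "enlivr_data_error")
})

test_that("the k = 1 path is the same code path as any other k", {
  ## single function, k parameter only: reconstructing with k = 1 equals
  ## reconstructing with k = 2 whose second set is removed from the estimate
  ## only through the configuration, not a separate routine
  g <- imagingGrid(16, 16)
  truth <- makePhantom(g)
  coils <- makeCoils(g, 3)
  data <- simulateKspace(truth, coils)
  f1 <- enliveReconstruct(data, solverConfig(k = 1, nNewton = 4,
                                             weighting = coilWeighting(a = 24)))
  expect_equal(nSets(f1@estimate), 1L)
  expect_s4_class(f1, "EnliveFit")
  ## identical call again is bit-identical (pure function of inputs)
  f1b <- enliveReconstruct(data, solverConfig(k = 1, nNewton = 4,
                                              weighting = coilWeighting(a = 24)))
  expect_identical(f1@estimate@images, f1b@estimate@images)
})
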