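## Shared small fixtures and independent oracles.

randc <- function(n) complex(real = rnorm(n), imaginary = rnorm(n))

randEstimate <- function(grid, k, nc, weighting = coilWeighting()) {
  d <- gridDims(grid)
  multisetEstimate(grid,
                   array(randc(prod(d) * k), dim = c(d, k)),
                   array(randc(prod(d) * nc * k), dim = c(d, nc, k)),
                   weighting)
}

## dense unitary DC-centered DFT matrix, built from the exponential formula
## (independent of the package's fft-based path); voxels column-major, x fastest
denseDftMatrix <- function(d) {
  N <- prod(d)
  vox <- function(i) {
    rep(rep(seq_len(d[i]), each = prod(d[seq_len(i - 1)])),
        times = prod(d[seq(i + 1, length.out = 3 - i)]))
  }
  ph <- 0
  for (i in 1:3) {
    if (d[i] == 1) next
    ax <- (seq_len(d[i]) - (floor(d[i] / 2) + 1))[vox(i)]
    ph <- ph + outer(ax, ax) / d[i]
  }
  exp(-2i * pi * ph) / sqrt(N)
}

## dense evaluation of the multiset forward model through explicit matrices
denseForward <- function(x, mask = NULL) {
  d <- gridDims(x@grid)
  N <- prod(d)
  k <- nSets(x); nc <- nCoils(x)
  Fd <- denseDftMatrix(d)
  w <- as.vector(weightValues(x@weighting, x@grid))
  Winv <- Conj(t(Fd)) %*% diag(1 / w, N)
  out <- array(0 + 0i, dim = c(d, nc))
  for (j in seq_len(nc)) {
    z <- complex(N)
    for (i in seq_len(k)) {
      cj <- as.vector(Winv %*% as.vector(x@wcoils[, , , j, i]))
      z <- z + cj * as.vector(x@images[, , , i])
    }
    K <- as.vector(Fd %*% z)
    if (!is.null(mask)) K[!as.vector(mask)] <- 0 + 0i
    out[, , , j] <- array(K, dim = d)
  }
  out
}

relErr <- function(a, b) {
  sqrt(sum(Mod(a - b)^2)) / max(sqrt(sum(Mod(b)^2)), .Machine$double.eps)
}

## scale-matched normalized RMSE between a magnitude image and a reference
nrmse <- function(M, ref) {
  s <- sum(M * ref) / sum(M^2)
  sqrt(sum((s * M - ref)^2) / sum(ref^2))
}

## root-sum-of-squares coil combination of a true image and coil set: the
## fully-sampled reference that magnitude reconstructions are compared against
rssReference <- function(image, coils) {
  d <- dim(coils)[1:3]
  acc <- array(0, dim = d)
  nc <- dim(coils)[4]
  for (j in seq_len(nc)) {
    acc <- acc + Mod(array(coils[, , , j], dim = d) * array(image, dim = d))^2
  }
  sqrt(acc)
}

## discrete winding number of a complex field around a pixel loop
windingNumber <- function(field, cx, cy, radius) {
  th <- seq(0, 2 * pi, length.out = 200)
  xs <- round(cx + radius * cos(th)); ys <- round(cy + radius * sin(th))
  ph <- Arg(field[cbind(xs, ys, 1)])
  dph <- diff(ph)
  dph <- (dph + pi) %% (2 * pi) - pi
  round(sum(dph) / (2 * pi))
}
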