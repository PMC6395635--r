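## Non-uniform Fourier transforms between a centered image grid and an
## arbitrary list of k-space coordinates (centered integer units, axis i
## spanning [-n_i/2, n_i/2]).
##
## Two evaluation paths share one normalization (matching the unitary
## Cartesian transform on grid-aligned coordinates):
##   direct   - exact summed DFT through a dense [M, N_I] matrix; used by
##              default on small grids and as the oracle path.
##   gridding - Kaiser-Bessel interpolation on a 1.5x oversampled FFT grid
##              with analytic deapodization; used on larger problems.

.kbKernel <- function(t, width, beta) {
  out <- numeric(length(t))
  inside <- abs(t) <= width / 2
  z <- 1 - (2 * t[inside] / width)^2
  out[inside] <- besselI(beta * sqrt(pmax(z, 0)), 0)
  out
}

## Fourier transform of the KB kernel, evaluated by quadrature at positions x
## (in units where the oversampled k-grid spacing is 1). Simpson's rule on the
## compact support; accuracy far below the gridding error itself.
.kbDeapod <- function(x, width, beta) {
  nq <- 513L
  t <- seq(-width / 2, width / 2, length.out = nq)
  h <- t[2] - t[1]
  wts <- c(1, rep(c(4, 2), length.out = nq - 2L), 1)
  wts[nq - 1L] <- 4
  ct <- .kbKernel(t, width, beta)
  vapply(x, function(xx) sum(wts * ct * cos(2 * pi * t * xx)) * h / 3, numeric(1))
}

.rawFftc <- function(x, inverse = FALSE) {
  fftShift(stats::fft(ifftShift(x), inverse = inverse))
}

#' Plan a non-uniform Fourier transform
#'
#' Precomputes everything needed to evaluate the forward transform (image
#' grid to trajectory samples) and its exact adjoint repeatedly on one
#' trajectory.
#'
#' @param coords `[M, 2]` or `[M, 3]` k-space coordinates in centered integer
#'   units.
#' @param grid An [ImagingGrid-class].
#' @param method `"auto"` (direct up to 4096 grid points, gridding above),
#'   `"direct"` or `"gridding"`.
#' @param osf Grid oversampling factor of the gridding path (default 1.5).
#' @param width Kaiser-Bessel kernel width in oversampled grid units.
#' @return An opaque plan list consumed by [nufftApply()] / [nufftAdjoint()].
#' @export
nufftPlan <- function(coords, grid, method = c("auto", "direct", "gridding"),
                      osf = 1.5, width = 6L) {
  method <- match.arg(method)
  coords <- as.matrix(coords)
  if (ncol(coords) == 2L) coords <- cbind(coords, 0)
  d <- gridDims(grid)
  if (method == "auto") method <- if (prod(d) <= 4096) "direct" else "gridding"
  if (method == "direct") {
    ph <- 0
    for (i in 1:3) {
      if (d[i] == 1L) next
      ph <- ph + outer(coords[, i], centeredCoords(d[i])[.voxAxisIndex(d, i)] / d[i])
    }
    E <- exp(-2i * pi * ph) / sqrt(prod(d))
    return(list(method = "direct", grid = grid, d = d, M = nrow(coords), E = E))
  }
  ## gridding plan
  beta <- pi * sqrt((width / osf)^2 * (osf - 0.5)^2 - 0.8)
  G <- ifelse(d == 1L, 1L, 2L * as.integer(ceiling(osf * d / 2)))
  active <- which(d > 1L)
  ## sparse interpolation matrix S [M, prod(G)], real KB weights
  M <- nrow(coords)
  neigh <- vector("list", 3L)
  for (i in 1:3) {
    if (d[i] == 1L) {
      neigh[[i]] <- list(idx = matrix(1L, M, 1L), wt = matrix(1, M, 1L))
    } else {
      kap <- coords[, i] * G[i] / d[i]
      base <- floor(kap)
      offs <- seq_len(width) - (width %/% 2L)
      gg <- outer(base, offs, `+`)                      # centered labels
      wt <- .kbKernel(gg - kap, width, beta)
      dim(wt) <- dim(gg)
      idx <- ((gg + G[i] %/% 2L) %% G[i]) + 1L          # periodic wrap
      neigh[[i]] <- list(idx = idx, wt = wt)
    }
  }
  n1 <- ncol(neigh[[1]]$idx); n2 <- ncol(neigh[[2]]$idx); n3 <- ncol(neigh[[3]]$idx)
  rows <- rep(seq_len(M), times = n1 * n2 * n3)
  i1 <- neigh[[1]]$idx[, rep(seq_len(n1), times = n2 * n3), drop = FALSE]
  i2 <- neigh[[2]]$idx[, rep(rep(seq_len(n2), each = n1), times = n3), drop = FALSE]
  i3 <- neigh[[3]]$idx[, rep(seq_len(n3), each = n1 * n2), drop = FALSE]
  ww <- neigh[[1]]$wt[, rep(seq_len(n1), times = n2 * n3), drop = FALSE] *
        neigh[[2]]$wt[, rep(rep(seq_len(n2), each = n1), times = n3), drop = FALSE] *
        neigh[[3]]$wt[, rep(seq_len(n3), each = n1 * n2), drop = FALSE]
  cols <- as.vector(i1) + G[1] * (as.vector(i2) - 1L) + G[1] * G[2] * (as.vector(i3) - 1L)
  keep <- as.vector(ww) != 0
  S <- Matrix::sparseMatrix(i = rows[keep], j = cols[keep], x = as.vector(ww)[keep],
                            dims = c(M, prod(G)))
  ## separable deapodization on the original grid
  deap <- lapply(1:3, function(i) {
    if (d[i] == 1L) return(1)
    .kbDeapod(centeredCoords(d[i]) / G[i], width, beta)
  })
  dp <- outer(outer(deap[[1]], deap[[2]]), deap[[3]])
  dim(dp) <- d
  list(method = "gridding", grid = grid, d = d, G = G, M = M,
       S = S, deapod = dp, scale = 1 / sqrt(prod(d)))
}

.voxAxisIndex <- function(d, i) {
  ## per-voxel coordinate index along axis i, voxels in column-major order
  rep(rep(seq_len(d[i]), each = prod(d[seq_len(i - 1L)])),
      times = prod(d[seq(i + 1L, length.out = 3L - i)]))
}

.sparseCmplx <- function(S, v) {
  as.vector(S %*% Re(v)) + 1i * as.vector(S %*% Im(v))
}

.sparseCmplxT <- function(S, v) {
  as.vector(Matrix::crossprod(S, Re(v))) + 1i * as.vector(Matrix::crossprod(S, Im(v)))
}

#' Apply a planned non-uniform Fourier transform
#'
#' `nufftApply()` maps an image-domain array on the plan's grid to the M
#' trajectory samples; `nufftAdjoint()` is the exact adjoint of the
#' implemented discrete pipeline (so the inner-product identity holds to
#' machine precision on both paths).
#'
#' @param plan A plan from [nufftPlan()].
#' @param img Complex array on the grid (forward), or complex length-M sample
#'   vector (adjoint).
#' @return Complex sample vector (forward) / complex grid array (adjoint).
#' @export
nufftApply <- function(plan, img) {
  if (plan$method == "direct") return(as.vector(plan$E %*% as.vector(img)))
  d <- plan$d; G <- plan$G
  z <- img / plan$deapod
  big <- array(0 + 0i, dim = G)
  idx <- lapply(1:3, function(i) (G[i] - d[i]) %/% 2L + seq_len(d[i]))
  big[idx[[1]], idx[[2]], idx[[3]]] <- z
  K <- .rawFftc(big)
  .sparseCmplx(plan$S, as.vector(K)) * plan$scale
}

#' @rdname nufftApply
#' @param y Complex sample vector of length M.
#' @export
nufftAdjoint <- function(plan, y) {
  if (plan$method == "direct") {
    out <- as.vector(Conj(t(plan$E)) %*% y)
    dim(out) <- plan$d
    return(out)
  }
  d <- plan$d; G <- plan$G
  K <- .sparseCmplxT(plan$S, y)
  dim(K) <- G
  big <- .rawFftc(K, inverse = TRUE)           # adjoint of the raw forward DFT
  idx <- lapply(1:3, function(i) (G[i] - d[i]) %/% 2L + seq_len(d[i]))
  z <- big[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  dim(z) <- d
  (z / plan$deapod) * plan$scale
}
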