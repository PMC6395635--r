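## The bilinear forward model and its Gauss-Newton linearization.
##
## Unknown x = (m^i, chat^i_j): k image maps and k x NC coil profiles in the
## weighted k-space domain. The predicted data per coil j are
##     F(x)_j = P FT{ sum_i (Winv chat^i_j) * m^i }
## where P is the sampling projection (Cartesian mask or trajectory) and FT
## the unitary centered Fourier transform.

#' Precompute the operator context for one data geometry
#'
#' Builds the reusable pieces (penalty weights, NUFFT plan) that the forward
#' operator, its derivative and adjoint share. Heavier front-ends
#' ([enliveReconstruct()]) build this once; the exported operator functions
#' build it on the fly when not supplied.
#'
#' @param data A [KSpaceData-class] object.
#' @param weighting A [CoilWeighting-class].
#' @param nufftMethod Non-Cartesian evaluation method, see [nufftPlan()].
#' @return An opaque plan list.
#' @export
operatorPlan <- function(data, weighting = coilWeighting(),
                         nufftMethod = c("auto", "direct", "gridding")) {
  nufftMethod <- match.arg(nufftMethod)
  grid <- data@grid
  d <- gridDims(grid)
  plan <- list(grid = grid, d = d, N = prod(d), nc = nChannels(data),
               w = weightValues(weighting, grid), weighting = weighting)
  ## precomputed permutations for DC-centered transforms (single-copy shifts)
  shiftPerm <- function(half) {
    idx <- lapply(d, function(n) {
      s <- half(n / 2)
      if (n == 1L) 1L else c((s + 1L):n, 1L:s)
    })
    arr <- array(seq_len(prod(d)), dim = d)
    as.vector(arr[idx[[1]], idx[[2]], idx[[3]]])
  }
  plan$pIn <- shiftPerm(floor)      # ifftShift
  plan$pOut <- shiftPerm(ceiling)   # fftShift
  plan$sqrtN <- sqrt(prod(d))
  if (is(data, "KSpaceCartesian")) {
    plan$type <- "cartesian"
    plan$mask <- data@mask
    plan$maskIdx <- lapply(seq_len(plan$nc), function(j) {
      which(!as.vector(data@mask[, , , j]))
    })
  } else {
    plan$type <- "noncart"
    plan$nufft <- nufftPlan(data@coords, grid, method = nufftMethod)
    plan$M <- nrow(data@coords)
  }
  plan
}

## fast unitary centered transforms via precomputed permutations; x and the
## result are plain complex vectors of length plan$N
.fftcFast <- function(plan, x) {
  y <- x[plan$pIn]
  dim(y) <- plan$d
  y <- stats::fft(y)
  y[plan$pOut] / plan$sqrtN
}

.ifftcFast <- function(plan, x) {
  y <- x[plan$pIn]
  dim(y) <- plan$d
  y <- stats::fft(y, inverse = TRUE)
  y[plan$pOut] / plan$sqrtN
}

## image-domain coil profiles and images at the linearization point; all
## fields are flattened to plain complex vectors for the inner loops
.linearize <- function(x, plan) {
  N <- plan$N; k <- nSets(x); nc <- nCoils(x)
  wv <- as.vector(plan$w)
  wcv <- as.vector(x@wcoils)
  coils <- vector("list", nc * k)
  for (i in seq_len(k)) for (j in seq_len(nc)) {
    off <- ((i - 1L) * nc + (j - 1L)) * N
    coils[[(i - 1L) * nc + j]] <- .ifftcFast(plan, wcv[off + seq_len(N)] / wv)
  }
  images <- lapply(seq_len(k), function(i) as.vector(x@images)[((i - 1L) * N) + seq_len(N)])
  list(coils = coils, images = images, k = k, nc = nc, wv = wv)
}

.emptySamples <- function(plan) {
  if (plan$type == "cartesian") {
    array(0 + 0i, dim = c(plan$d, plan$nc))
  } else {
    matrix(0 + 0i, plan$M, plan$nc)
  }
}

.transformCoilImage <- function(plan, z, j) {
  ## z: image-domain complex vector; returns masked k-space vector / samples
  if (plan$type == "cartesian") {
    K <- .fftcFast(plan, z)
    K[plan$maskIdx[[j]]] <- 0 + 0i
    K
  } else {
    nufftApply(plan$nufft, array(z, dim = plan$d))
  }
}

.adjointCoilSamples <- function(plan, y, j) {
  if (plan$type == "cartesian") {
    y[plan$maskIdx[[j]]] <- 0 + 0i
    .ifftcFast(plan, y)
  } else {
    as.vector(nufftAdjoint(plan$nufft, y))
  }
}

.forwardFromCtx <- function(ctx, plan) {
  out <- .emptySamples(plan)
  N <- plan$N
  for (j in seq_len(ctx$nc)) {
    z <- complex(N)
    for (i in seq_len(ctx$k)) {
      z <- z + ctx$coils[[(i - 1L) * ctx$nc + j]] * ctx$images[[i]]
    }
    if (plan$type == "cartesian") {
      out[((j - 1L) * N) + seq_len(N)] <- .transformCoilImage(plan, z, j)
    } else {
      out[, j] <- .transformCoilImage(plan, z, j)
    }
  }
  out
}

#' Forward model: predicted k-space samples of a multiset estimate
#'
#' Evaluates \eqn{P F\{\sum_i (W^{-1}\hat c^i_j) \odot m^i\}} per coil.
#'
#' @param x A [MultisetEstimate-class].
#' @param data A [KSpaceData-class] carrying the sampling geometry (values
#'   are ignored, only geometry is used).
#' @param plan Optional precomputed [operatorPlan()].
#' @return Predicted samples in the data container's shape: complex array
#'   `[nx, ny, nz, NC]` (Cartesian, zero off-mask) or matrix `[M, NC]`.
#' @export
enliveForward <- function(x, data, plan = operatorPlan(data, x@weighting)) {
  if (!all(gridDims(x@grid) == plan$d)) stop("estimate and data grids differ")
  if (nCoils(x) != plan$nc) stop("estimate and data disagree on channel count")
  .forwardFromCtx(.linearize(x, plan), plan)
}

.derivativeFromCtx <- function(ctx, dimg, dwc, plan) {
  out <- .emptySamples(plan)
  N <- plan$N
  dimgv <- as.vector(dimg); dwcv <- as.vector(dwc)
  for (j in seq_len(ctx$nc)) {
    z <- complex(N)
    for (i in seq_len(ctx$k)) {
      off <- ((i - 1L) * ctx$nc + (j - 1L)) * N
      z <- z + ctx$coils[[(i - 1L) * ctx$nc + j]] * dimgv[((i - 1L) * N) + seq_len(N)] +
        .ifftcFast(plan, dwcv[off + seq_len(N)] / ctx$wv) * ctx$images[[i]]
    }
    if (plan$type == "cartesian") {
      out[((j - 1L) * N) + seq_len(N)] <- .transformCoilImage(plan, z, j)
    } else {
      out[, j] <- .transformCoilImage(plan, z, j)
    }
  }
  out
}

.adjointFromCtx <- function(ctx, dy, plan) {
  N <- plan$N
  d <- plan$d
  dyv <- as.vector(dy)
  dimg <- complex(N * ctx$k)
  dwc <- complex(N * ctx$nc * ctx$k)
  for (j in seq_len(ctx$nc)) {
    yj <- if (plan$type == "cartesian") dyv[((j - 1L) * N) + seq_len(N)] else dy[, j]
    b <- .adjointCoilSamples(plan, yj, j)
    for (i in seq_len(ctx$k)) {
      ii <- ((i - 1L) * N) + seq_len(N)
      dimg[ii] <- dimg[ii] + Conj(ctx$coils[[(i - 1L) * ctx$nc + j]]) * b
      off <- ((i - 1L) * ctx$nc + (j - 1L)) * N
      dwc[off + seq_len(N)] <- .fftcFast(plan, Conj(ctx$images[[i]]) * b) / ctx$wv
    }
  }
  dim(dimg) <- c(d, ctx$k)
  dim(dwc) <- c(d, ctx$nc, ctx$k)
  list(images = dimg, wcoils = dwc)
}

#' Gauss-Newton derivative of the forward model and its adjoint
#'
#' `enliveDerivative()` applies the Frechet derivative
#' \eqn{DF(x)[dx]_j = P F\{\sum_i c^i_j \odot dm^i + (W^{-1} d\hat c^i_j)
#' \odot m^i\}}; `enliveAdjointDerivative()` applies the exact adjoint
#' \eqn{DF(x)^H} under the standard complex inner products.
#'
#' @param x Linearization point, a [MultisetEstimate-class].
#' @param dx Perturbation: a `MultisetEstimate` or a list with elements
#'   `images` and `wcoils` shaped like the estimate's slots.
#' @param data,plan Sampling geometry as in [enliveForward()].
#' @return `enliveDerivative()`: predicted sample perturbation (data-shaped);
#'   `enliveAdjointDerivative()`: a list with `images` and `wcoils` arrays.
#' @export
enliveDerivative <- function(x, dx, data, plan = operatorPlan(data, x@weighting)) {
  dimg <- if (is(dx, "MultisetEstimate")) dx@images else dx$images
  dwc <- if (is(dx, "MultisetEstimate")) dx@wcoils else dx$wcoils
  if (!identical(dim(dimg), dim(x@images)) || !identical(dim(dwc), dim(x@wcoils)))
    stop("perturbation shape does not match the linearization point")
  .derivativeFromCtx(.linearize(x, plan), dimg, dwc, plan)
}

#' @rdname enliveDerivative
#' @param dy Data-shaped sample perturbation.
#' @export
enliveAdjointDerivative <- function(x, dy, data, plan = operatorPlan(data, x@weighting)) {
  if (plan$type == "cartesian") {
    if (!identical(dim(dy), as.integer(c(plan$d, plan$nc))) &&
        !identical(dim(dy), c(plan$d, plan$nc)))
      stop("sample perturbation shape does not match the geometry")
  } else if (nrow(dy) != plan$M || ncol(dy) != plan$nc) {
    stop("sample perturbation shape does not match the geometry")
  }
  .adjointFromCtx(.linearize(x, plan), dy, plan)
}
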