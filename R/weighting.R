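#' Evaluate the k-space smoothness penalty on a grid
#'
#' Samples \eqn{w(k) = (1 + a\|k\|^2)^{b/2}} at every k-space grid point.
#' With the `"grid"` normalization \eqn{\|k\|^2} is the sum over axes of the
#' squared centered integer coordinates \eqn{k_i \in [-n_i/2, n_i/2)}; with
#' `"unit"` each axis is first rescaled to \eqn{[-1/2, 1/2)}. The weight at
#' the k-space center is exactly 1 and is radially nondecreasing.
#'
#' @param spec A [CoilWeighting-class].
#' @param grid An [ImagingGrid-class].
#' @return Real array `[nx, ny, nz]` of strictly positive weights.
#' @export
weightValues <- function(spec, grid) {
  d <- gridDims(grid)
  ax <- lapply(d, centeredCoords)
  if (spec@normalization == "unit") {
    ax <- lapply(seq_along(ax), function(i) {
      if (d[i] == 1L) ax[[i]] else ax[[i]] / d[i]
    })
  }
  k2 <- outer(outer(ax[[1]]^2, ax[[2]]^2, `+`), ax[[3]]^2, `+`)
  (1 + spec@a * k2)^(spec@b / 2)
}

#' Apply the coil weighting transform and its inverse
#'
#' `applyWeighting()` maps an image-domain coil profile \eqn{c} to the
#' transformed variable \eqn{\hat c = W c} (Fourier transform to k-space, then
#' multiplication by the diagonal penalty [weightValues()]).
#' `applyWeightingInverse()` is the exact inverse
#' \eqn{c = F^{-1}(\hat c / w)}; `applyWeightingInvAdjoint()` is the adjoint
#' of the inverse, \eqn{(W^{-1})^H z = F(z) / w} (the weights are real).
#'
#' @param x Complex array on the grid (image domain for `applyWeighting`,
#'   transformed k-space domain for the inverse).
#' @param spec A [CoilWeighting-class].
#' @param grid An [ImagingGrid-class].
#' @param w Optional precomputed [weightValues()] array.
#' @return Complex array on the grid.
#' @export
applyWeighting <- function(x, spec, grid, w = weightValues(spec, grid)) {
  fftc(x) * w
}

#' @rdname applyWeighting
#' @export
applyWeightingInverse <- function(x, spec, grid, w = weightValues(spec, grid)) {
  ifftc(x / w)
}

#' @rdname applyWeighting
#' @export
applyWeightingInvAdjoint <- function(x, spec, grid, w = weightValues(spec, grid)) {
  fftc(x) / w
}

#' Image-domain coil profiles of an estimate
#'
#' Undoes the weighting transform on every stored profile, returning
#' \eqn{c^i_j = W^{-1} \hat c^i_j}.
#'
#' @param x A [MultisetEstimate-class].
#' @return Complex array `[nx, ny, nz, NC, k]` of image-domain coil profiles.
#' @export
unweightedCoils <- function(x) {
  w <- weightValues(x@weighting, x@grid)
  out <- x@wcoils
  k <- nSets(x); nc <- nCoils(x)
  for (i in seq_len(k)) for (j in seq_len(nc)) {
    out[, , , j, i] <- applyWeightingInverse(array(x@wcoils[, , , j, i], dim = gridDims(x@grid)),
                                             x@weighting, x@grid, w)
  }
  out
}
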