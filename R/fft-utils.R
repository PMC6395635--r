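#' @import methods
#' @importFrom stats rnorm runif
NULL

## Centered, unitary discrete Fourier transforms.
##
## Convention used throughout the package: the image grid carries centered
## integer spatial indices x_i in {-n_i/2, ..., n_i/2 - 1} (even n_i) and
## k-space carries centered integer frequencies k_i over the same range, so
## that the DC sample sits at 1-based array index n_i/2 + 1 on every axis.
## Transforms are unitary (scaled by 1/sqrt(N)); the forward transform maps
## image to k-space with kernel exp(-2*pi*1i * sum_i k_i x_i / n_i).

#' Circularly shift an array so the DC element moves between corner and center
#'
#' `fftShift()` moves the zero-frequency element from the first array position
#' to the center (`floor(n/2) + 1`); `ifftShift()` is its inverse. For even
#' dimensions the two coincide.
#'
#' @param x An array (any number of dimensions) or vector.
#' @return The shifted array.
#' @export
fftShift <- function(x) .shiftArray(x, ceiling)

#' @rdname fftShift
#' @export
ifftShift <- function(x) .shiftArray(x, floor)

.shiftArray <- function(x, half) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  idx <- lapply(d, function(n) {
    s <- half(n / 2)
    if (n == 1L) 1L else c((s + 1L):n, 1L:s)
  })
  if (is.null(dim(x))) return(x[idx[[1L]]])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

#' Unitary DC-centered Fourier transforms
#'
#' `fftc()` maps a DC-centered image-domain array to DC-centered k-space;
#' `ifftc()` is the exact inverse (and, because the transform is unitary, also
#' the adjoint of `fftc()`).
#'
#' @param x Complex array with the DC sample at index `floor(n/2) + 1` on each
#'   axis.
#' @return Complex array of the same shape.
#' @export
fftc <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  fftShift(stats::fft(ifftShift(x))) / sqrt(prod(d))
}

#' @rdname fftc
#' @export
ifftc <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  fftShift(stats::fft(ifftShift(x), inverse = TRUE)) / sqrt(prod(d))
}

#' Centered integer coordinates along one axis
#'
#' Returns the centered coordinate labels `-n/2, ..., n/2 - 1` (even `n`) used
#' for both image positions and k-space frequencies.
#'
#' @param n Axis length.
#' @return Numeric vector of length `n`.
#' @export
centeredCoords <- function(n) seq_len(n) - (floor(n / 2) + 1)
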