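#' ImagingGrid: the reconstruction grid
#'
#' Holds the sample counts of the (2D or 3D) reconstruction grid. All image
#' maps, coil profiles and Cartesian sampling masks in a problem share one
#' grid. `nVoxels()` returns the total number of grid points
#' \eqn{N_I = n_x n_y n_z}.
#'
#' @slot nx,ny,nz Positive integer sample counts; `nz = 1` for 2D imaging.
#'
#' @export
setClass("ImagingGrid",
  representation(nx = "integer", ny = "integer", nz = "integer"),
  validity = function(object) {
    d <- c(object@nx, object@ny, object@nz)
    if (any(is.na(d)) || any(d < 1L)) return("all grid dimensions must be >= 1")
    TRUE
  }
)

#' @param nx,ny,nz Grid dimensions (`nz = 1` for 2D).
#' @return `imagingGrid()` returns an `ImagingGrid` object.
#' @rdname ImagingGrid-class
#' @export
imagingGrid <- function(nx, ny = 1L, nz = 1L) {
  new("ImagingGrid", nx = as.integer(nx), ny = as.integer(ny), nz = as.integer(nz))
}

#' @param grid An `ImagingGrid`.
#' @rdname ImagingGrid-class
#' @export
nVoxels <- function(grid) prod(gridDims(grid))

#' @rdname ImagingGrid-class
#' @export
gridDims <- function(grid) c(grid@nx, grid@ny, grid@nz)

setMethod("show", "ImagingGrid", function(object) {
  cat("ImagingGrid:", object@nx, "x", object@ny, "x", object@nz,
      sprintf("(N_I = %d)\n", nVoxels(object)))
})

#' CoilWeighting: the invertible smoothness weighting W on coil profiles
#'
#' The coil profiles are estimated in a transformed domain
#' \eqn{\hat c_j = W c_j}, where \eqn{W} Fourier-transforms each profile to
#' k-space and multiplies by the radial penalty
#' \eqn{w(k) = (1 + a\|k\|^2)^{b/2}}, which grows with distance from the
#' k-space center and thereby enforces spatial smoothness when the
#' transformed variable is \eqn{\ell_2}-penalized.
#'
#' Two k-coordinate normalizations are supported for \eqn{\|k\|}:
#' `"unit"` (default) rescales each axis to \eqn{[-1/2, 1/2)} so the penalty
#' scale `a` is grid-size independent; `"grid"` uses the raw centered integer
#' coordinates \eqn{-n_i/2 \le k_i < n_i/2}.
#'
#' @slot a Positive penalty scale (default 240).
#' @slot b Positive exponent (default 40).
#' @slot normalization `"unit"` or `"grid"`.
#'
#' @export
setClass("CoilWeighting",
  representation(a = "numeric", b = "numeric", normalization = "character"),
  validity = function(object) {
    if (length(object@a) != 1L || !is.finite(object@a) || object@a <= 0)
      return("'a' must be a single positive number")
    if (length(object@b) != 1L || !is.finite(object@b) || object@b < 0)
      return("'b' must be a single nonnegative number")
    if (!object@normalization %in% c("unit", "grid"))
      return("normalization must be 'unit' or 'grid'")
    TRUE
  }
)

#' @param a,b Penalty scale and exponent of \eqn{(1 + a\|k\|^2)^{b/2}}.
#' @param normalization `"unit"` or `"grid"` (see class description).
#' @return `coilWeighting()` returns a `CoilWeighting` object.
#' @rdname CoilWeighting-class
#' @export
coilWeighting <- function(a = 240, b = 40, normalization = c("unit", "grid")) {
  new("CoilWeighting", a = a, b = b, normalization = match.arg(normalization))
}

setMethod("show", "CoilWeighting", function(object) {
  cat(sprintf("CoilWeighting: (1 + %g ||k||^2)^(%g/2), %s k-normalization\n",
              object@a, object@b, object@normalization))
})

#' MultisetEstimate: k image maps plus k x N_C transformed coil profiles
#'
#' The unknown of the relaxed reconstruction model: `k` complex image maps
#' \eqn{m^i} and, for each set, \eqn{N_C} coil profiles stored in the
#' transformed (weighted k-space) domain \eqn{\hat c^i_j = W c^i_j}.
#' Image-domain profiles are recovered with [unweightedCoils()].
#'
#' @slot grid The shared [ImagingGrid-class].
#' @slot images Complex array `[nx, ny, nz, k]`.
#' @slot wcoils Complex array `[nx, ny, nz, NC, k]` (weighted k-space domain).
#' @slot weighting The [CoilWeighting-class] defining W.
#'
#' @export
setClass("MultisetEstimate",
  representation(grid = "ImagingGrid", images = "array", wcoils = "array",
                 weighting = "CoilWeighting"),
  validity = function(object) {
    d <- gridDims(object@grid)
    di <- dim(object@images); dc <- dim(object@wcoils)
    if (length(di) != 4L || !all(di[1:3] == d))
      return("images must be a [nx, ny, nz, k] array on the grid")
    if (length(dc) != 5L || !all(dc[1:3] == d))
      return("wcoils must be a [nx, ny, nz, NC, k] array on the grid")
    if (dc[5L] != di[4L]) return("images and wcoils disagree on the number of sets k")
    if (di[4L] < 1L || dc[4L] < 1L) return("need k >= 1 sets and NC >= 1 coils")
    if (!is.complex(object@images) || !is.complex(object@wcoils))
      return("images and wcoils must be complex arrays")
    TRUE
  }
)

#' @param grid An [ImagingGrid-class].
#' @param images,wcoils Complex arrays `[nx, ny, nz, k]` and
#'   `[nx, ny, nz, NC, k]`.
#' @param weighting A [CoilWeighting-class].
#' @return `multisetEstimate()` returns a `MultisetEstimate`.
#' @rdname MultisetEstimate-class
#' @export
multisetEstimate <- function(grid, images, wcoils, weighting = coilWeighting()) {
  new("MultisetEstimate", grid = grid,
      images = .asComplexArray(images), wcoils = .asComplexArray(wcoils),
      weighting = weighting)
}

.asComplexArray <- function(x) {
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

#' @rdname MultisetEstimate-class
#' @param x A `MultisetEstimate`.
#' @export
nSets <- function(x) dim(x@images)[4L]

#' @rdname MultisetEstimate-class
#' @export
nCoils <- function(x) {
  if (is(x, "MultisetEstimate")) dim(x@wcoils)[4L] else nChannels(x)
}

#' @rdname MultisetEstimate-class
#' @export
imageMaps <- function(x) x@images

#' @rdname MultisetEstimate-class
#' @export
weightedCoils <- function(x) x@wcoils

setMethod("show", "MultisetEstimate", function(object) {
  cat(sprintf("MultisetEstimate: k = %d set(s), %d coil(s) on %d x %d x %d grid\n",
              nSets(object), nCoils(object),
              object@grid@nx, object@grid@ny, object@grid@nz))
})

#' KSpaceData: measured multichannel k-space samples
#'
#' Virtual parent of the two acquisition geometries. `KSpaceCartesian` stores
#' a full-grid complex array with a binary sampling mask (zeros off-mask);
#' `KSpaceNonCartesian` stores a sample list with the k-space trajectory.
#'
#' @slot grid The reconstruction [ImagingGrid-class].
#'
#' @export
setClass("KSpaceData", representation("VIRTUAL", grid = "ImagingGrid"))

#' @rdname KSpaceData-class
#' @slot kspace Complex array `[nx, ny, nz, NC]`, zero at unsampled positions.
#' @slot mask Logical array `[nx, ny, nz, NC]`; per-channel masks (virtual
#'   conjugate channels carry the point-reflected mask of their parent coil).
#' @export
setClass("KSpaceCartesian",
  contains = "KSpaceData",
  representation(kspace = "array", mask = "array"),
  validity = function(object) {
    d <- gridDims(object@grid)
    dk <- dim(object@kspace); dm <- dim(object@mask)
    if (length(dk) != 4L || !all(dk[1:3] == d))
      return("kspace must be [nx, ny, nz, NC] on the grid")
    if (!identical(dm, dk)) return("mask must have the same shape as kspace")
    if (!is.logical(object@mask)) return("mask must be logical")
    if (sum(object@mask) == 0L) return("empty sampling pattern")
    if (any(object@kspace[!object@mask] != 0))
      return("kspace must be zero at unsampled positions")
    TRUE
  }
)

#' @rdname KSpaceData-class
#' @slot samples Complex matrix `[M, NC]`: one column of trajectory samples
#'   per coil.
#' @slot coords Numeric matrix `[M, 3]` of k-space coordinates in centered
#'   integer units (`kz = 0` for 2D).
#' @export
setClass("KSpaceNonCartesian",
  contains = "KSpaceData",
  representation(samples = "matrix", coords = "matrix"),
  validity = function(object) {
    if (!is.complex(object@samples)) return("samples must be complex")
    if (ncol(object@coords) != 3L) return("coords must be an [M, 3] matrix")
    if (nrow(object@samples) != nrow(object@coords))
      return("per-coil sample count must equal trajectory length")
    if (nrow(object@samples) == 0L) return("empty trajectory")
    if (any(!is.finite(object@coords))) return("trajectory coordinates must be finite")
    TRUE
  }
)

#' Construct Cartesian k-space data
#'
#' @param grid An [ImagingGrid-class].
#' @param kspace Complex array `[nx, ny, nz, NC]` (a 2D/3D array is treated as
#'   a single channel).
#' @param mask Logical array on the grid, either shared (`[nx, ny, nz]`) or
#'   per channel (`[nx, ny, nz, NC]`); defaults to fully sampled. Off-mask
#'   entries of `kspace` are zeroed.
#' @return A `KSpaceCartesian` object.
#' @export
kspaceCartesian <- function(grid, kspace, mask = NULL) {
  d <- gridDims(grid)
  kspace <- .asComplexArray(kspace)
  if (length(dim(kspace)) == 2L) dim(kspace) <- c(dim(kspace), 1L, 1L)
  if (length(dim(kspace)) == 3L) dim(kspace) <- c(dim(kspace), 1L)
  nc <- dim(kspace)[4L]
  if (is.null(mask)) mask <- array(TRUE, dim = c(d, nc))
  if (length(dim(mask)) == 2L) dim(mask) <- c(dim(mask), 1L)
  if (length(dim(mask)) == 3L) mask <- array(rep(as.logical(mask), nc), dim = c(d, nc))
  mask <- array(as.logical(mask), dim = dim(mask))
  kspace[!mask] <- 0 + 0i
  new("KSpaceCartesian", grid = grid, kspace = kspace, mask = mask)
}

#' Construct non-Cartesian k-space data
#'
#' @param grid Reconstruction [ImagingGrid-class].
#' @param samples Complex matrix `[M, NC]` of measured samples.
#' @param coords `[M, 2]` or `[M, 3]` matrix of k-space coordinates in the
#'   centered integer convention (each axis within `[-n_i/2, n_i/2]`).
#' @return A `KSpaceNonCartesian` object.
#' @export
kspaceNonCartesian <- function(grid, samples, coords) {
  samples <- as.matrix(samples)
  if (!is.complex(samples)) storage.mode(samples) <- "complex"
  coords <- as.matrix(coords)
  if (ncol(coords) == 2L) coords <- cbind(coords, 0)
  storage.mode(coords) <- "double"
  new("KSpaceNonCartesian", grid = grid, samples = samples, coords = coords)
}

#' Number of receive channels of a data object
#' @param data A [KSpaceData-class] object.
#' @export
nChannels <- function(data) {
  if (is(data, "KSpaceCartesian")) dim(data@kspace)[4L] else ncol(data@samples)
}

#' @rdname nChannels
#' @export
sampleCounts <- function(data) {
  if (is(data, "KSpaceCartesian")) {
    apply(data@mask, 4L, sum)
  } else {
    rep(nrow(data@samples), ncol(data@samples))
  }
}

setMethod("show", "KSpaceCartesian", function(object) {
  d <- gridDims(object@grid)
  cat(sprintf("KSpaceCartesian: %d channel(s) on %d x %d x %d grid, %d/%d samples/channel (R = %.2f)\n",
              nChannels(object), d[1], d[2], d[3],
              round(mean(sampleCounts(object))), prod(d),
              prod(d) / mean(sampleCounts(object))))
})

setMethod("show", "KSpaceNonCartesian", function(object) {
  d <- gridDims(object@grid)
  cat(sprintf("KSpaceNonCartesian: %d channel(s), %d trajectory samples, %d x %d x %d grid\n",
              nChannels(object), nrow(object@samples), d[1], d[2], d[3]))
})
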