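#' CartesianPattern: a binary Cartesian sampling mask
#'
#' @slot mask Logical array `[nx, ny, nz]`.
#' @slot calib Integer vector of calibration-block sizes per axis (length 0
#'   when no calibration region was requested).
#' @slot achievedR Total grid points divided by sampled points.
#'
#' @export
setClass("CartesianPattern",
  representation(mask = "array", calib = "integer", achievedR = "numeric",
                 info = "list"),
  validity = function(object) {
    if (!is.logical(object@mask)) return("mask must be logical")
    if (sum(object@mask) == 0L) return("mask must be nonempty")
    if (object@achievedR < 1 - 1e-12) return("achieved R must be >= 1")
    TRUE
  }
)

.newPattern <- function(mask, calib = integer(0), info = list()) {
  new("CartesianPattern", mask = mask, calib = as.integer(calib),
      achievedR = length(mask) / sum(mask), info = info)
}

#' @rdname CartesianPattern-class
#' @param pattern A `CartesianPattern`.
#' @export
achievedR <- function(pattern) pattern@achievedR

#' @rdname CartesianPattern-class
#' @export
patternMask <- function(pattern) pattern@mask

setMethod("show", "CartesianPattern", function(object) {
  d <- dim(object@mask)
  cat(sprintf("CartesianPattern on %s: %d/%d samples, achieved R = %.3f%s\n",
              paste(d, collapse = " x "), sum(object@mask), length(object@mask),
              object@achievedR,
              if (length(object@calib)) paste0(", calib ",
                paste(object@calib, collapse = " x ")) else ""))
})

## fill the centered calibration block (adds samples, never removes)
.insertCalib <- function(mask, calib) {
  if (is.null(calib) || length(calib) == 0L) return(mask)
  d <- dim(mask)
  calib <- rep(as.integer(calib), length.out = 3L)
  calib <- pmin(calib, d)
  calib[d == 1L] <- 1L
  if (any(calib > d))
    stop(errorCondition("calibration block larger than the grid",
                        class = c("enlivr_usage_error", "error", "condition")))
  idx <- lapply(1:3, function(i) {
    ctr <- floor(d[i] / 2) + 1L
    lo <- ctr - floor(calib[i] / 2)
    seq(lo, length.out = calib[i])
  })
  mask[idx[[1]], idx[[2]], idx[[3]]] <- TRUE
  mask
}

.checkCalibFits <- function(grid, calib) {
  if (is.null(calib) || length(calib) == 0L) return(invisible(NULL))
  d <- gridDims(grid)
  cc <- rep(as.integer(calib), length.out = 3L)
  cc[d == 1L] <- 1L
  if (any(cc > d))
    stop(errorCondition("calibration block larger than the grid",
                        class = c("enlivr_usage_error", "error", "condition")))
  invisible(NULL)
}

#' Regular (equidistant) Cartesian undersampling
#'
#' Keeps every `accel`-th line along each axis, anchored so the k-space
#' center line is always kept, and optionally fills in a centered
#' fully-sampled calibration block.
#'
#' @param grid An [ImagingGrid-class].
#' @param accel Integer acceleration per axis. A single value undersamples
#'   the second (phase-encode) axis; a vector of length 2 or 3 applies per
#'   axis starting from the first.
#' @param calib Optional calibration block size (scalar or per-axis vector);
#'   applied to all non-singleton axes.
#' @return A [CartesianPattern-class] with the achieved undersampling factor.
#' @export
regularPattern <- function(grid, accel = 2L, calib = NULL) {
  d <- gridDims(grid)
  if (length(accel) == 1L) accel <- c(1L, accel, 1L)
  accel <- rep(as.integer(accel), length.out = 3L)
  if (any(accel < 1L))
    stop(errorCondition("acceleration factors must be >= 1",
                        class = c("enlivr_usage_error", "error", "condition")))
  .checkCalibFits(grid, calib)
  keep <- lapply(1:3, function(i) {
    ctr <- floor(d[i] / 2)                 # 0-based DC index
    ((seq_len(d[i]) - 1L) - ctr) %% accel[i] == 0L
  })
  mask <- outer(outer(keep[[1]], keep[[2]], `&`), keep[[3]], `&`)
  dim(mask) <- d
  mask <- .insertCalib(mask, calib)
  .newPattern(mask, if (is.null(calib)) integer(0) else calib)
}

#' Variable-density Poisson-disc sampling
#'
#' Greedy dart-throwing on the grid with a minimum-distance radius that grows
#' linearly with normalized distance from the k-space center,
#' \eqn{r(d) = r_0 (1 + s\,d)}. The base radius \eqn{r_0} is calibrated by
#' bisection so the achieved undersampling factor lands within 5% of
#' `targetR`. The k-space center point is always sampled. Fully reproducible
#' from `seed`.
#'
#' @param grid A 2D [ImagingGrid-class] (`nz = 1`).
#' @param targetR Target undersampling factor (>= 1).
#' @param calib Optional centered calibration block (adds samples after
#'   calibration of the radius; the reported achieved R accounts for it).
#' @param vdSlope Slope `s` of the linear variable-density law.
#' @param seed Integer seed.
#' @return A [CartesianPattern-class].
#' @export
poissonDiscPattern <- function(grid, targetR, calib = NULL, vdSlope = 2, seed = 1L) {
  d <- gridDims(grid)
  if (d[3] != 1L) stop("Poisson-disc generation is implemented for 2D grids")
  if (targetR < 1)
    stop(errorCondition("target undersampling factor must be >= 1",
                        class = c("enlivr_usage_error", "error", "condition")))
  .checkCalibFits(grid, calib)
  n <- d[1] * d[2]
  if (targetR == 1) {
    mask <- array(TRUE, dim = d)
    return(.newPattern(.insertCalib(mask, calib),
                       if (is.null(calib)) integer(0) else calib))
  }
  set.seed(seed)
  ord <- sample.int(n)
  xs <- ((ord - 1L) %% d[1]) + 1L
  ys <- ((ord - 1L) %/% d[1]) + 1L
  ctr <- floor(d[1:2] / 2) + 1L
  dn <- sqrt(((xs - ctr[1]) / (d[1] / 2))^2 + ((ys - ctr[2]) / (d[2] / 2))^2) / sqrt(2)
  ## move the always-kept center point to the front of the candidate order
  ci <- which(xs == ctr[1] & ys == ctr[2])
  ord2 <- c(ci, setdiff(seq_len(n), ci))
  xs <- xs[ord2]; ys <- ys[ord2]; dn <- dn[ord2]

  throwDarts <- function(r0) {
    rad <- r0 * (1 + vdSlope * dn)
    occ <- matrix(FALSE, d[1], d[2])
    for (t in seq_len(n)) {
      x <- xs[t]; y <- ys[t]; r <- rad[t]
      ri <- ceiling(r)
      x0 <- max(1L, x - ri); x1 <- min(d[1], x + ri)
      y0 <- max(1L, y - ri); y1 <- min(d[2], y + ri)
      win <- occ[x0:x1, y0:y1, drop = FALSE]
      if (any(win)) {
        wi <- which(win, arr.ind = TRUE)
        dd <- sqrt((wi[, 1] + x0 - 1L - x)^2 + (wi[, 2] + y0 - 1L - y)^2)
        if (any(dd < r)) next
      }
      occ[x, y] <- TRUE
    }
    occ
  }

  ## bisection on the base radius; larger r0 -> sparser mask -> larger R
  lo <- 0.5; hi <- 2 * sqrt(targetR)
  occ <- NULL
  for (it in seq_len(25L)) {
    mid <- (lo + hi) / 2
    occ <- throwDarts(mid)
    Rach <- n / sum(occ)
    if (abs(Rach - targetR) <= 0.05 * targetR) break
    if (Rach > targetR) hi <- mid else lo <- mid
  }
  mask <- array(occ, dim = d)
  mask <- .insertCalib(mask, calib)
  .newPattern(mask, if (is.null(calib)) integer(0) else calib,
              info = list(radius0 = mid, vdSlope = vdSlope, seed = seed))
}

#' CAIPIRINHA (sheared-lattice) Cartesian undersampling
#'
#' Samples position `(y, z)` (0-based indices on the grid's first two axes)
#' iff `y %% Ry == 0` and `(z - (y %/% Ry) * shift) %% Rz == 0`; the total
#' undersampling before any calibration region is `Ry * Rz`, and `shift = 0`
#' degenerates to the plain regular lattice.
#'
#' @param grid An [ImagingGrid-class]; the pattern lives on its first two
#'   axes (the two phase-encode directions).
#' @param Ry,Rz Integer lattice accelerations (>= 1).
#' @param shift Integer lattice shear, `0 <= shift < Rz`.
#' @param calib Optional centered calibration block.
#' @return A [CartesianPattern-class].
#' @export
caipirinhaPattern <- function(grid, Ry, Rz, shift = 1L, calib = NULL) {
  d <- gridDims(grid)
  Ry <- as.integer(Ry); Rz <- as.integer(Rz); shift <- as.integer(shift)
  if (Ry < 1L || Rz < 1L)
    stop(errorCondition("lattice accelerations must be >= 1",
                        class = c("enlivr_usage_error", "error", "condition")))
  if (shift < 0L || shift >= Rz)
    stop(errorCondition("shift must satisfy 0 <= shift < Rz",
                        class = c("enlivr_usage_error", "error", "condition")))
  .checkCalibFits(grid, calib)
  y <- seq_len(d[1]) - 1L
  z <- seq_len(d[2]) - 1L
  sampled <- outer(y, z, function(yy, zz) {
    yy %% Ry == 0L & ((zz - (yy %/% Ry) * shift) %% Rz) == 0L
  })
  mask <- array(sampled, dim = d)
  mask <- .insertCalib(mask, calib)
  .newPattern(mask, if (is.null(calib)) integer(0) else calib)
}

#' Partial-Fourier mask
#'
#' Keeps the contiguous `fraction` of lines along one axis starting from the
#' low-index edge; the retained block always contains the k-space center
#' line (which is why fractions of 1/2 or below are rejected). Composes
#' multiplicatively (logical AND) with any other pattern.
#'
#' @param grid An [ImagingGrid-class].
#' @param fraction Kept fraction, `0.5 < fraction <= 1`.
#' @param axis Axis index (1-3) along which k-space is truncated.
#' @return A [CartesianPattern-class].
#' @export
partialFourierMask <- function(grid, fraction, axis = 2L) {
  d <- gridDims(grid)
  if (fraction <= 0.5 || fraction > 1)
    stop(errorCondition("partial-Fourier fraction must be in (1/2, 1] to keep the center",
                        class = c("enlivr_usage_error", "error", "condition")))
  nKeep <- round(fraction * d[axis])
  keepAx <- seq_len(d[axis]) <= nKeep
  keep <- lapply(1:3, function(i) if (i == axis) keepAx else rep(TRUE, d[i]))
  mask <- outer(outer(keep[[1]], keep[[2]], `&`), keep[[3]], `&`)
  dim(mask) <- d
  .newPattern(mask)
}

#' Trajectory: non-Cartesian k-space sample coordinates
#'
#' @slot coords Numeric matrix `[M, 3]` in centered integer k-space units.
#' @slot nSpokes,samplesPerSpoke Radial structure (0 when not radial).
#'
#' @export
setClass("Trajectory",
  representation(coords = "matrix", nSpokes = "integer",
                 samplesPerSpoke = "integer"),
  validity = function(object) {
    if (ncol(object@coords) != 3L) return("coords must be an [M, 3] matrix")
    if (any(!is.finite(object@coords))) return("coordinates must be finite")
    TRUE
  }
)

#' @rdname Trajectory-class
#' @param traj A `Trajectory`.
#' @export
trajCoords <- function(traj) traj@coords

setMethod("show", "Trajectory", function(object) {
  cat(sprintf("Trajectory: %d samples", nrow(object@coords)))
  if (object@nSpokes > 0L)
    cat(sprintf(" (%d spokes x %d samples)", object@nSpokes, object@samplesPerSpoke))
  cat("\n")
})

#' Radial k-space trajectory
#'
#' Center-out-symmetric spokes through the k-space center. With the
#' `"uniform"` scheme spoke `l` lies at angle `(l-1) * pi / nSpokes` (half
#' circle, since opposite directions are covered by the symmetric spoke);
#' `rotation` adds a constant offset (e.g. for turn-based multi-frame
#' schemes). Sample radii span `[-rmax, rmax]` with
#' `rmax = min(nx, ny) / 2`, and every spoke contains the k = 0 sample.
#'
#' @param nSpokes Number of spokes (>= 1).
#' @param samplesPerSpoke Samples per spoke (even counts place a sample
#'   exactly at k = 0).
#' @param grid An [ImagingGrid-class] (2D).
#' @param scheme Angle scheme; only `"uniform"` angles are generated, with
#'   `rotation` providing turned variants.
#' @param rotation Constant angle offset in radians.
#' @return A [Trajectory-class].
#' @export
radialTrajectory <- function(nSpokes, samplesPerSpoke, grid,
                             scheme = c("uniform", "turned"), rotation = 0) {
  scheme <- match.arg(scheme)
  if (nSpokes < 1L)
    stop(errorCondition("need at least one spoke",
                        class = c("enlivr_usage_error", "error", "condition")))
  d <- gridDims(grid)
  rmax <- min(d[d > 1L]) / 2
  S <- as.integer(samplesPerSpoke)
  r <- (seq_len(S) - 1L - S %/% 2L) * (rmax / (S / 2))
  ang <- (seq_len(nSpokes) - 1L) * pi / nSpokes + rotation
  if (scheme == "turned") ang <- ang + pi / (2 * nSpokes)
  kx <- as.vector(outer(r, cos(ang)))
  ky <- as.vector(outer(r, sin(ang)))
  new("Trajectory", coords = cbind(kx, ky, 0),
      nSpokes = as.integer(nSpokes), samplesPerSpoke = S)
}
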