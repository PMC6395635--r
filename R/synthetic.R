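## Synthetic phantoms, coil models and k-space simulation. Every generator is
## deterministic given its arguments (and seed, where randomness is involved),
## and every generated dataset is exactly consistent with the package's k = 1
## forward model before noise injection.

#' Ellipse table of the numerical Shepp-Logan head phantom
#'
#' Standard ten-ellipse parameterization on the unit square, with the
#' higher-contrast intensity variant commonly used for reconstruction tests
#' (`modified = TRUE`) or the original low-contrast values.
#'
#' @param modified Use the high-contrast intensity set.
#' @return Data frame with columns `x`, `y` (center), `a`, `b` (semi-axes),
#'   `angle` (degrees) and `intensity` (additive).
#' @export
sheppLoganEllipses <- function(modified = TRUE) {
  e <- data.frame(
    x     = c(0,      0,      0.22,  -0.22,   0,      0,      0,     -0.08,   0,      0.06),
    y     = c(0,     -0.0184, 0,      0,      0.35,   0.1,   -0.1,   -0.605, -0.605, -0.605),
    a     = c(0.69,   0.6624, 0.11,   0.16,   0.21,   0.046,  0.046,  0.046,  0.023,  0.023),
    b     = c(0.92,   0.874,  0.31,   0.41,   0.25,   0.046,  0.046,  0.023,  0.023,  0.046),
    angle = c(0,      0,     -18,     18,     0,      0,      0,      0,      0,      0)
  )
  e$intensity <- if (modified) {
    c(1, -0.8, -0.2, -0.2, 0.1, 0.1, 0.1, 0.1, 0.1, 0.1)
  } else {
    c(2, -0.98, -0.02, -0.02, 0.01, 0.01, 0.01, 0.01, 0.01, 0.01)
  }
  e
}

#' Rasterize a piecewise-constant ellipse phantom
#'
#' Pixel centers lie on the normalized square \eqn{[-1, 1)^2}; a pixel inside
#' several ellipses accumulates their (signed) intensities, and the
#' background is exactly zero.
#'
#' @param grid A 2D [ImagingGrid-class].
#' @param ellipses Data frame as returned by [sheppLoganEllipses()]; an empty
#'   frame yields the zero image.
#' @param phase Optional real array `[nx, ny]` of phase values (radians)
#'   applied as `exp(1i * phase)`.
#' @param oversample Subpixel supersampling factor. 1 gives pure point-in-
#'   ellipse membership at pixel centers; larger values average an
#'   `oversample x oversample` subgrid per pixel, i.e. partial-volume edges.
#' @return Complex array `[nx, ny, 1]`.
#' @export
makePhantom <- function(grid, ellipses = sheppLoganEllipses(), phase = NULL,
                        oversample = 1L) {
  d <- gridDims(grid)
  ss <- as.integer(oversample)
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  u <- 2 * (rep(centeredCoords(d[1]), each = ss) + rep(sub, d[1])) / d[1]
  v <- 2 * (rep(centeredCoords(d[2]), each = ss) + rep(sub, d[2])) / d[2]
  U <- matrix(u, d[1] * ss, d[2] * ss)
  V <- matrix(v, d[1] * ss, d[2] * ss, byrow = TRUE)
  img <- matrix(0, d[1] * ss, d[2] * ss)
  if (nrow(ellipses) > 0) {
    for (r in seq_len(nrow(ellipses))) {
      th <- ellipses$angle[r] * pi / 180
      du <- U - ellipses$x[r]; dv <- V - ellipses$y[r]
      ru <- du * cos(th) + dv * sin(th)
      rv <- -du * sin(th) + dv * cos(th)
      inside <- (ru / ellipses$a[r])^2 + (rv / ellipses$b[r])^2 <= 1
      img <- img + ellipses$intensity[r] * inside
    }
  }
  if (ss > 1L) {
    img <- apply(array(img, c(ss, d[1], ss, d[2])), c(2, 4), mean)
  }
  out <- img * (1 + 0i)
  if (!is.null(phase)) out <- out * exp(1i * array(phase, dim = c(d[1], d[2])))
  array(out, dim = d)
}

#' Smooth simulated coil sensitivity profiles
#'
#' A ring of `nc` Gaussian sensitivity lobes centered just outside the FOV,
#' each with a mild coil-specific linear phase ramp. The profiles are
#' spatially smooth (their spectral energy is concentrated at the lowest
#' k-space frequencies, which is the model assumption the coil weighting
#' encodes) and their sum of squares is nowhere zero inside the FOV.
#'
#' @param grid A 2D [ImagingGrid-class].
#' @param nc Number of coils.
#' @param sigma Gaussian lobe width in FOV units (FOV spans `[-0.5, 0.5)`).
#' @param radius Ring radius of the lobe centers in FOV units.
#' @param phaseCycles Strength of the per-coil linear phase ramp, in cycles
#'   across the FOV.
#' @return Complex array `[nx, ny, 1, nc]`.
#' @export
makeCoils <- function(grid, nc, sigma = 0.45, radius = 0.55, phaseCycles = 0.5) {
  d <- gridDims(grid)
  u <- centeredCoords(d[1]) / d[1]
  v <- centeredCoords(d[2]) / d[2]
  U <- matrix(u, d[1], d[2])
  V <- matrix(v, d[1], d[2], byrow = TRUE)
  out <- array(0 + 0i, dim = c(d, nc))
  ## smooth spectral taper: removes the spectral leakage of lobes truncated
  ## at the FOV boundary, so the profiles are band-limited by construction
  kmax <- min(d[d > 1L]) / 2
  kr <- sqrt(outer(outer(centeredCoords(d[1])^2, centeredCoords(d[2])^2, `+`),
                   centeredCoords(d[3])^2, `+`))
  taper <- exp(-(kr / (0.18 * 2 * kmax))^8)
  for (j in seq_len(nc)) {
    th <- 2 * pi * (j - 1) / nc
    cx <- radius * cos(th); cy <- radius * sin(th)
    mag <- exp(-((U - cx)^2 + (V - cy)^2) / (2 * sigma^2))
    ph <- 2 * pi * phaseCycles * (cos(th) * U + sin(th) * V) + th / 3
    prof <- array(mag * exp(1i * ph), dim = d)
    out[, , , j] <- ifftc(fftc(prof) * taper)
  }
  out
}

#' Simulate multichannel k-space data from an image and coil profiles
#'
#' Exact evaluation of the single-set generative model
#' \eqn{y_j = P F\{c_j \odot m\}} on the requested geometry, consistent by
#' construction with the solver's `k = 1` forward model.
#'
#' @param image Complex array `[nx, ny, nz]`.
#' @param coils Complex array `[nx, ny, nz, NC]`.
#' @param geometry A [CartesianPattern-class], a logical mask array, a
#'   [Trajectory-class], or `NULL` for full Cartesian sampling.
#' @param nufftMethod Non-Cartesian evaluation path (default exact direct
#'   summation).
#' @return A [KSpaceData-class] object.
#' @export
simulateKspace <- function(image, coils, geometry = NULL,
                           nufftMethod = c("direct", "gridding", "auto")) {
  nufftMethod <- match.arg(nufftMethod)
  d <- dim(coils)[1:3]
  grid <- imagingGrid(d[1], d[2], d[3])
  nc <- dim(coils)[4]
  image <- array(image, dim = d)
  if (is(geometry, "Trajectory")) {
    plan <- nufftPlan(geometry@coords, grid, method = nufftMethod)
    samples <- vapply(seq_len(nc),
                      function(j) nufftApply(plan, array(coils[, , , j], dim = d) * image),
                      complex(nrow(geometry@coords)))
    return(kspaceNonCartesian(grid, samples, geometry@coords))
  }
  mask <- if (is.null(geometry)) {
    array(TRUE, dim = d)
  } else if (is(geometry, "CartesianPattern")) {
    geometry@mask
  } else {
    array(as.logical(geometry), dim = d)
  }
  ks <- array(0 + 0i, dim = c(d, nc))
  for (j in seq_len(nc)) {
    K <- fftc(array(coils[, , , j], dim = d) * image)
    K[!mask] <- 0 + 0i
    ks[, , , j] <- K
  }
  kspaceCartesian(grid, ks, mask)
}

#' Magnitude of the DC reference used for noise calibration
#'
#' Cartesian data: the largest channel magnitude of the k-space center
#' sample (falling back to the overall maximum if the center is unsampled);
#' non-Cartesian data: the maximum-magnitude sample, since a unique DC bin
#' does not exist off-grid.
#'
#' @param data A [KSpaceData-class].
#' @return A nonnegative scalar.
#' @export
dcMagnitude <- function(data) {
  if (is(data, "KSpaceCartesian")) {
    d <- gridDims(data@grid)
    ctr <- floor(d / 2) + 1L
    v <- max(Mod(data@kspace[ctr[1], ctr[2], ctr[3], ]))
    if (v > 0) return(v)
    return(max(Mod(data@kspace)))
  }
  max(Mod(data@samples))
}

#' Add calibrated complex Gaussian noise to k-space data
#'
#' The noise standard deviation per real/imaginary component is
#' `level / 100` times the DC magnitude ([dcMagnitude()]), matching the
#' convention of quoting noise as a percentage of the DC component. Only
#' sampled positions receive noise. Deterministic per seed.
#'
#' @param data A [KSpaceData-class].
#' @param level Noise level in percent of the DC magnitude (>= 0).
#' @param seed Integer seed.
#' @return The noisy [KSpaceData-class].
#' @export
addNoise <- function(data, level, seed = 1L) {
  if (level < 0) stop("noise level must be >= 0")
  if (level == 0) return(data)
  sdev <- level / 100 * dcMagnitude(data)
  set.seed(seed)
  if (is(data, "KSpaceCartesian")) {
    idx <- which(data@mask)
    nz <- length(idx)
    data@kspace[idx] <- data@kspace[idx] +
      complex(real = rnorm(nz, sd = sdev), imaginary = rnorm(nz, sd = sdev))
  } else {
    nz <- length(data@samples)
    data@samples <- data@samples +
      matrix(complex(real = rnorm(nz, sd = sdev), imaginary = rnorm(nz, sd = sdev)),
             nrow(data@samples))
  }
  data
}

#' Fold an extended-FOV image into a reduced FOV along the phase-encode axis
#'
#' Spatial aliasing: the reduced field of view superimposes copies of the
#' extended image shifted by multiples of the FOV,
#' \eqn{x_{fov}(y) = \sum_t x_{ext}(y + t\,n_y)}.
#'
#' @param imgExt Complex array whose second axis has length
#'   `factor * nyFov`.
#' @param nyFov Reduced-FOV length of the second axis.
#' @return Array with second axis of length `nyFov`.
#' @export
foldFov <- function(imgExt, nyFov) {
  dE <- dim(imgExt)
  f <- dE[2] / nyFov
  if (f != round(f)) stop("extended axis must be an integer multiple of the FOV")
  out <- array(0 + 0i, dim = c(dE[1], nyFov, dE[-(1:2)]))
  ## centered conventions: FOV position y (0-based centered at nyFov/2) sits at
  ## extended positions y + t*nyFov around the extended center
  ctrE <- floor(dE[2] / 2)
  ctrF <- floor(nyFov / 2)
  for (t in seq_len(f) - 1L) {
    src <- ((seq_len(nyFov) - 1L - ctrF + t * nyFov + ctrE) %% dE[2]) + 1L
    out <- out + array(imgExt[, src, , drop = FALSE], dim = dim(out))
  }
  out
}

#' Limited field-of-view acquisition scenario
#'
#' Builds an object wider (along the phase-encode axis) than the
#' reconstruction FOV, simulates its multichannel k-space on the extended
#' grid, and samples it at the reduced-FOV k-space spacing, so that the
#' object's lateral edges alias into the FOV. The returned data are fully
#' sampled on the FOV grid; compose with a [regularPattern()] for the
#' undersampled experiment. The fully-sampled (wrapped) root-sum-of-squares
#' image is returned as the reference against which undersampling artifacts
#' are measured.
#'
#' @param grid The reconstruction (FOV) [ImagingGrid-class], 2D.
#' @param margin Number of pixels by which the object exceeds the FOV on
#'   each side along axis 2 (`0 < margin <= ny/2`).
#' @param nc Number of coils.
#' @param ellipses Phantom ellipse table (drawn on the object extent).
#' @param coilArgs List of extra arguments passed to [makeCoils()] for the
#'   extended grid.
#' @param oversample Phantom rasterization supersampling (see [makePhantom()]);
#'   the default draws partial-volume edges.
#' @return List with `data` (fully sampled [KSpaceCartesian-class] on the
#'   FOV grid), `reference` (wrapped RSS magnitude on the FOV grid),
#'   `imageExt`, `coilsExt` and `foldedCoilImages`.
#' @export
limitedFovScenario <- function(grid, margin, nc = 8L,
                               ellipses = sheppLoganEllipses(),
                               coilArgs = list(), oversample = 4L) {
  d <- gridDims(grid)
  if (d[3] != 1L) stop("limited-FOV scenario is 2D")
  if (margin <= 0 || margin > d[2] / 2) stop("margin must be in (0, ny/2]")
  nyExt <- 2L * d[2]
  gridExt <- imagingGrid(d[1], nyExt)
  ## object drawn on its own (nx, ny + 2*margin) extent, embedded centered
  nyObj <- d[2] + 2L * as.integer(margin)
  objGrid <- imagingGrid(d[1], nyObj)
  obj <- makePhantom(objGrid, ellipses, oversample = oversample)
  imageExt <- array(0 + 0i, dim = gridDims(gridExt))
  off <- floor(nyExt / 2) - floor(nyObj / 2)
  imageExt[, off + seq_len(nyObj), 1] <- obj[, , 1]
  coilsExt <- do.call(makeCoils, c(list(grid = gridExt, nc = nc), coilArgs))
  dE <- gridDims(gridExt)
  folded <- array(0 + 0i, dim = c(d, nc))
  for (j in seq_len(nc)) {
    cim <- array(coilsExt[, , , j], dim = dE) * array(imageExt, dim = dE)
    folded[, , , j] <- foldFov(array(cim, dim = c(dE[1], dE[2], 1)), d[2])
  }
  ks <- array(0 + 0i, dim = c(d, nc))
  for (j in seq_len(nc)) ks[, , , j] <- fftc(array(folded[, , , j], dim = d))
  reference <- sqrt(apply(Mod(folded)^2, 1:3, sum))
  list(data = kspaceCartesian(grid, ks),
       reference = array(reference, dim = d),
       imageExt = imageExt, coilsExt = coilsExt, foldedCoilImages = folded)
}

#' Extend Cartesian data with virtual conjugate coils
#'
#' Appends, for every physical channel, a virtual channel
#' \eqn{\tilde y_j(k) = \overline{y_j(-k)}}; on a real-valued object the
#' virtual channels equal the physical ones, so they impose a real-value
#' (smooth-phase) constraint within the parallel-imaging model. The virtual
#' channels carry the point-reflected sampling mask.
#'
#' @param data A [KSpaceCartesian-class].
#' @return A [KSpaceCartesian-class] with `2 * NC` channels.
#' @export
vccExtend <- function(data) {
  if (!is(data, "KSpaceCartesian"))
    stop(errorCondition("virtual conjugate coils require Cartesian data",
                        class = c("enlivr_data_error", "error", "condition")))
  d <- gridDims(data@grid)
  nc <- nChannels(data)
  refl <- lapply(d, function(n) if (n == 1L) 1L else c(1L, n:2))
  ks <- array(0 + 0i, dim = c(d, 2L * nc))
  mk <- array(FALSE, dim = c(d, 2L * nc))
  ks[, , , seq_len(nc)] <- data@kspace
  mk[, , , seq_len(nc)] <- data@mask
  for (j in seq_len(nc)) {
    kj <- array(data@kspace[, , , j], dim = d)
    mj <- array(data@mask[, , , j], dim = d)
    ks[, , , nc + j] <- Conj(kj[refl[[1]], refl[[2]], refl[[3]], drop = FALSE])
    mk[, , , nc + j] <- mj[refl[[1]], refl[[2]], refl[[3]], drop = FALSE]
  }
  kspaceCartesian(data@grid, ks, mk)
}

#' Complex field with a phase singularity
#'
#' Phase winds by `2 * pi * charge` around `center` (FOV units in
#' `[-0.5, 0.5)`), with smooth unit magnitude. Used as an image-map initial
#' guess it reproduces the local-minimum trap in which single-set
#' reconstructions develop an artifactual signal void at the singularity.
#'
#' @param grid A 2D [ImagingGrid-class].
#' @param center Singularity position in FOV units.
#' @param charge Nonzero integer winding number (0 gives a constant field).
#' @return Complex array `[nx, ny, 1]` of unit magnitude.
#' @export
phaseSingularityImage <- function(grid, center = c(0, 0), charge = 1L) {
  d <- gridDims(grid)
  u <- centeredCoords(d[1]) / d[1]
  v <- centeredCoords(d[2]) / d[2]
  U <- matrix(u, d[1], d[2])
  V <- matrix(v, d[1], d[2], byrow = TRUE)
  z <- complex(real = U - center[1], imaginary = V - center[2])
  array(exp(1i * charge * Arg(z)), dim = d)
}

#' Initial estimate carrying a phase singularity
#'
#' Builds the initial guess that traps single-set reconstructions in the
#' signal-void local minimum: the first set's image map is the singular
#' phase field (magnitude one) and, when true coil profiles are supplied,
#' its coil maps are the smoothness-projected wound-compensating profiles
#' (the smooth best approximation of \eqn{c_j \overline{s}}, which develops
#' the characteristic magnitude hole at the singularity — the self-
#' consistent trapped state). Additional sets keep the standard
#' initialization (`m = 1`, coils 0), so they are free to rescue the void.
#'
#' @inheritParams phaseSingularityImage
#' @param k Number of sets.
#' @param nc Number of coils.
#' @param coils Optional complex array `[nx, ny, nz, nc]` of coil profiles
#'   used to seed the trapped first set; `NULL` leaves all coils zero.
#' @param lowpassCycles Spectral radius (in k-space cycles) of the Gaussian
#'   smoothing used for the wound-compensating projection.
#' @param weighting A [CoilWeighting-class].
#' @return A [MultisetEstimate-class].
#' @export
singularInitialGuess <- function(grid, k, nc, center = c(0, 0), charge = 1L,
                                 coils = NULL, lowpassCycles = 4,
                                 weighting = coilWeighting()) {
  d <- gridDims(grid)
  sing <- phaseSingularityImage(grid, center, charge)
  imgs <- array(0 + 0i, dim = c(d, k))
  imgs[, , , 1] <- sing
  if (k > 1L) for (i in 2:k) imgs[, , , i] <- 1 + 0i
  wc <- array(0 + 0i, dim = c(d, nc, k))
  if (!is.null(coils)) {
    kr <- sqrt(outer(outer(centeredCoords(d[1])^2, centeredCoords(d[2])^2, `+`),
                     centeredCoords(d[3])^2, `+`))
    lp <- array(exp(-(kr / lowpassCycles)^2), dim = d)
    w <- weightValues(weighting, grid)
    for (j in seq_len(nc)) {
      cw <- ifftc(fftc(array(coils[, , , j], dim = d) * Conj(sing)) * lp)
      wc[, , , j, 1] <- applyWeighting(cw, weighting, grid, w)
    }
  }
  multisetEstimate(imagingGrid(d[1], d[2], d[3]), imgs, wc, weighting)
}
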