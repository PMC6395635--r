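#' CombinedImage: magnitude images and set-energy diagnostics
#'
#' @slot perSet Real nonnegative array `[nx, ny, nz, k]`: per-set magnitude
#'   images \eqn{M^i}.
#' @slot combined Real nonnegative array `[nx, ny, nz]`: the single combined
#'   magnitude \eqn{M}.
#' @slot setEnergy Sum of squares of each \eqn{M^i}.
#' @slot energyFraction Set energies normalized to sum to 1 (all zero, with
#'   `allZero = TRUE`, for an identically zero estimate).
#' @slot allZero Flag raised when the estimate carries no energy.
#'
#' @export
setClass("CombinedImage",
  representation(perSet = "array", combined = "array", setEnergy = "numeric",
                 energyFraction = "numeric", allZero = "logical"),
  validity = function(object) {
    if (any(object@perSet < 0) || any(object@combined < 0))
      return("magnitude images must be nonnegative")
    tot <- sum(object@setEnergy)
    if (!object@allZero && abs(sum(object@energyFraction) - 1) > 1e-12)
      return("energy fractions must sum to 1")
    if (tot > 0 && object@allZero) return("allZero flag inconsistent with energies")
    TRUE
  }
)

#' Per-set magnitude images
#'
#' Combines each set's coil-weighted images into one magnitude image,
#' \eqn{M^i = \sqrt{\sum_j |m^i \odot c^i_j|^2}}, using the image-domain
#' (unweighted) coil profiles. The split of scale between an image and its
#' coils is not determined by the model, so \eqn{M^i} is invariant under
#' \eqn{(m^i, c^i_j) \to (\lambda m^i, c^i_j/\lambda)}.
#'
#' @param x A [MultisetEstimate-class].
#' @param coils Optional precomputed [unweightedCoils()] array.
#' @return Real array `[nx, ny, nz, k]`.
#' @export
combinePerSet <- function(x, coils = unweightedCoils(x)) {
  d <- gridDims(x@grid); k <- nSets(x); nc <- nCoils(x)
  out <- array(0, dim = c(d, k))
  for (i in seq_len(k)) {
    acc <- array(0, dim = d)
    for (j in seq_len(nc)) {
      acc <- acc + Mod(array(x@images[, , , i], dim = d) *
                         array(coils[, , , j, i], dim = d))^2
    }
    out[, , , i] <- sqrt(acc)
  }
  out
}

#' Combined magnitude image over all sets
#'
#' First sums the sets coherently per coil and then takes the root sum of
#' squares over coils:
#' \eqn{M = \sqrt{\sum_j |\sum_i m^i \odot c^i_j|^2}}. For `k = 1` this
#' equals [combinePerSet()].
#'
#' @inheritParams combinePerSet
#' @return Real array `[nx, ny, nz]`.
#' @export
combineAll <- function(x, coils = unweightedCoils(x)) {
  d <- gridDims(x@grid); k <- nSets(x); nc <- nCoils(x)
  acc <- array(0, dim = d)
  for (j in seq_len(nc)) {
    z <- array(0 + 0i, dim = d)
    for (i in seq_len(k)) {
      z <- z + array(x@images[, , , i], dim = d) * array(coils[, , , j, i], dim = d)
    }
    acc <- acc + Mod(z)^2
  }
  sqrt(acc)
}

#' Set-energy report
#'
#' Pixel-energy of each per-set magnitude image and the normalized fractions,
#' in set order. An identically zero estimate yields zero fractions and the
#' `allZero` flag instead of a division by zero.
#'
#' @inheritParams combinePerSet
#' @return List with `energy`, `fraction` and `allZero`.
#' @export
setEnergyReport <- function(x, coils = unweightedCoils(x)) {
  ps <- combinePerSet(x, coils)
  k <- nSets(x)
  en <- vapply(seq_len(k), function(i) sum(array(ps[, , , i], dim = gridDims(x@grid))^2),
               numeric(1))
  tot <- sum(en)
  if (tot > 0) {
    list(energy = en, fraction = en / tot, allZero = FALSE)
  } else {
    list(energy = en, fraction = rep(0, k), allZero = TRUE)
  }
}

#' Full post-processing of an estimate or fit
#'
#' @param x A [MultisetEstimate-class] or [EnliveFit-class].
#' @return A [CombinedImage-class].
#' @export
combineImages <- function(x) {
  if (is(x, "EnliveFit")) x <- x@estimate
  coils <- unweightedCoils(x)
  ps <- combinePerSet(x, coils)
  rep_ <- setEnergyReport(x, coils)
  new("CombinedImage", perSet = ps, combined = combineAll(x, coils),
      setEnergy = rep_$energy, energyFraction = rep_$fraction,
      allZero = rep_$allZero)
}

setMethod("show", "CombinedImage", function(object) {
  k <- dim(object@perSet)[4L]
  cat(sprintf("CombinedImage: %d set(s); energy fractions %s%s\n", k,
              paste(sprintf("%.4f", object@energyFraction), collapse = " "),
              if (object@allZero) " (all-zero estimate)" else ""))
})
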