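#' SolverConfig: parameters of the iteratively regularized Gauss-Newton solve
#'
#' @slot k Number of map sets (1 = single-set nonlinear inversion, NLINV).
#' @slot alpha0 Initial regularization \eqn{\alpha_0 > 0}.
#' @slot q Per-step reduction factor, \eqn{\alpha_n = \alpha_0 q^{n-1}},
#'   \eqn{0 < q < 1}.
#' @slot nNewton Number of Newton steps (the step count tunes the effective
#'   regularization of the result).
#' @slot cgMaxIter,cgTol Inner conjugate-gradient controls for the
#'   regularized normal equations.
#' @slot regReference `"zero"` penalizes toward 0 (the literal objective);
#'   `"initial"` penalizes toward the initial guess.
#' @slot refSteps Number of leading Newton steps that keep the initial-guess
#'   reference before `regReference = "zero"` takes effect. At the standard
#'   initialization the image block of the normal operator is degenerate, so
#'   the literal zero reference needs the iterate anchored first; once it is,
#'   dropping the anchor lets the solution settle on the stationary point of
#'   the objective as written, which empties unused-set content that the
#'   anchor otherwise pins at its initialization value. Ignored (all steps
#'   anchored) when `regReference = "initial"`.
#' @slot dataScaleTarget Input data are rescaled to this l2 norm before
#'   solving (undone on output), so `alpha0` is comparable across datasets.
#' @slot weighting The coil smoothness [CoilWeighting-class].
#' @slot nufftMethod Non-Cartesian path selection (see [nufftPlan()]).
#' @slot seed Integer seed recorded with the fit (the solver itself is
#'   deterministic; the seed governs synthetic-data generation only).
#'
#' @export
setClass("SolverConfig",
  representation(k = "integer", alpha0 = "numeric", q = "numeric",
                 nNewton = "integer", cgMaxIter = "integer", cgTol = "numeric",
                 regReference = "character", refSteps = "integer",
                 dataScaleTarget = "numeric",
                 weighting = "CoilWeighting", nufftMethod = "character",
                 seed = "integer"),
  validity = function(object) {
    if (object@k < 1L) return("k must be >= 1")
    if (!(object@q > 0 && object@q < 1)) return("q must lie in (0, 1)")
    if (object@alpha0 <= 0) return("alpha0 must be positive")
    if (object@nNewton < 1L) return("need at least one Newton step")
    if (!object@regReference %in% c("zero", "initial"))
      return("regReference must be 'zero' or 'initial'")
    if (object@refSteps < 1L)
      return("refSteps must be >= 1 (the first step needs the anchor)")
    if (object@dataScaleTarget <= 0) return("dataScaleTarget must be positive")
    TRUE
  }
)

#' @param k,alpha0,q,nNewton,cgMaxIter,cgTol,regReference,dataScaleTarget,weighting,nufftMethod,seed
#'   See the class slots. Defaults are the reference configuration:
#'   `k = 2`, `alpha0 = 1`, `q = 1/2`, 11 Newton steps.
#' @return `solverConfig()` returns a `SolverConfig`.
#' @rdname SolverConfig-class
#' @export
solverConfig <- function(k = 2L, alpha0 = 1, q = 0.5, nNewton = 11L,
                         cgMaxIter = 100L, cgTol = 1e-4,
                         regReference = c("initial", "zero"),
                         refSteps = max(1L, nNewton - 3L),
                         dataScaleTarget = 100, weighting = coilWeighting(),
                         nufftMethod = c("auto", "direct", "gridding"),
                         seed = 1L) {
  new("SolverConfig", k = as.integer(k), alpha0 = alpha0, q = q,
      nNewton = as.integer(nNewton), cgMaxIter = as.integer(cgMaxIter),
      cgTol = cgTol, regReference = match.arg(regReference),
      refSteps = as.integer(refSteps),
      dataScaleTarget = dataScaleTarget, weighting = weighting,
      nufftMethod = match.arg(nufftMethod), seed = as.integer(seed))
}

setMethod("show", "SolverConfig", function(object) {
  cat(sprintf("SolverConfig: k = %d, alpha0 = %g, q = %g, %d Newton steps, CG <= %d @ %g\n",
              object@k, object@alpha0, object@q, object@nNewton,
              object@cgMaxIter, object@cgTol))
})

#' SolveReport: per-Newton-step diagnostics
#'
#' @slot alpha Regularization \eqn{\alpha_n} used at each step.
#' @slot residual Data residual \eqn{\|y - F(x_n)\|_2} after each step (in
#'   the internal data scaling).
#' @slot relResidual Residual relative to \eqn{\|y\|_2}.
#' @slot objective Value of the regularized objective after each step.
#' @slot cgIters Inner CG iterations used.
#' @slot gramOffdiag Largest relative off-diagonal coil-set Gram entry after
#'   orthogonalization.
#'
#' @export
setClass("SolveReport",
  representation(alpha = "numeric", residual = "numeric",
                 relResidual = "numeric", objective = "numeric",
                 cgIters = "integer", gramOffdiag = "numeric"),
  validity = function(object) {
    n <- length(object@alpha)
    if (length(object@residual) != n || length(object@objective) != n ||
        length(object@cgIters) != n || length(object@gramOffdiag) != n ||
        length(object@relResidual) != n)
      return("all report vectors must have one entry per Newton step")
    if (n > 1L && any(diff(object@alpha) >= 0))
      return("alpha must be strictly decreasing")
    TRUE
  }
)

setMethod("show", "SolveReport", function(object) {
  cat("SolveReport over", length(object@alpha), "Newton steps\n")
  print(data.frame(alpha = object@alpha, relResidual = object@relResidual,
                   cgIters = object@cgIters, gramOffdiag = object@gramOffdiag))
})

#' EnliveFit: result container of a reconstruction
#'
#' @slot estimate The final [MultisetEstimate-class] (images rescaled back to
#'   the input data scale).
#' @slot report The [SolveReport-class].
#' @slot config The [SolverConfig-class] used.
#' @slot scale Internal data scaling factor that was applied.
#'
#' @export
setClass("EnliveFit",
  representation(estimate = "MultisetEstimate", report = "SolveReport",
                 config = "SolverConfig", scale = "numeric"))

setMethod("show", "EnliveFit", function(object) {
  cat("EnliveFit\n")
  show(object@config)
  n <- length(object@report@alpha)
  cat(sprintf("  final relative residual: %.3g\n", object@report@relResidual[n]))
  fr <- setEnergyReport(object@estimate)$fraction
  cat("  set energy fractions:", paste(sprintf("%.4f", fr), collapse = " "), "\n")
})

#' Initial guess of the Gauss-Newton iteration
#'
#' Every image map is the constant 1 and every (weighted) coil profile is 0,
#' for all sets alike; the set symmetry this creates is broken by
#' [gramSchmidtCoils()] during the iteration.
#'
#' @param grid An [ImagingGrid-class].
#' @param k Number of sets.
#' @param nc Number of coils.
#' @param weighting A [CoilWeighting-class].
#' @return A [MultisetEstimate-class].
#' @export
initializeEstimate <- function(grid, k, nc, weighting = coilWeighting()) {
  d <- gridDims(grid)
  multisetEstimate(grid,
                   array(1 + 0i, dim = c(d, k)),
                   array(0 + 0i, dim = c(d, nc, k)),
                   weighting)
}

#' Gram-Schmidt orthogonalization of the coil-profile sets
#'
#' Treats each set's weighted coil profiles as one stacked vector and removes,
#' in increasing set order, the projections onto all earlier sets. No
#' renormalization is applied and the images are not compensated; set 1 is
#' returned unchanged. A zero set stays zero.
#'
#' @param x A [MultisetEstimate-class].
#' @return The orthogonalized estimate.
#' @export
gramSchmidtCoils <- function(x) {
  k <- nSets(x)
  if (k == 1L) return(x)
  d <- dim(x@wcoils)
  V <- matrix(x@wcoils, ncol = k)
  for (ip in 2:k) {
    for (i in 1:(ip - 1L)) {
      nn <- Re(sum(Conj(V[, i]) * V[, i]))
      if (nn > 0) {
        V[, ip] <- V[, ip] - (sum(Conj(V[, i]) * V[, ip]) / nn) * V[, i]
      }
    }
  }
  x@wcoils <- array(V, dim = d)
  x
}

## largest off-diagonal Gram entry relative to the largest diagonal entry
## (norm-product scaling is ill-posed when a set is annihilated to rounding)
.gramOffdiagMax <- function(x) {
  k <- nSets(x)
  if (k == 1L) return(0)
  V <- matrix(x@wcoils, ncol = k)
  nrms2 <- Re(colSums(Conj(V) * V))
  if (max(nrms2) == 0) return(0)
  worst <- 0
  for (ip in 2:k) for (i in 1:(ip - 1L)) {
    worst <- max(worst, Mod(sum(Conj(V[, i]) * V[, ip])))
  }
  worst / max(nrms2)
}

## flat-vector bridge for the CG solve
.flatten <- function(img, wc) c(as.vector(img), as.vector(wc))
.unflatten <- function(v, dimg, dwc) {
  ni <- prod(dimg)
  list(images = array(v[seq_len(ni)], dim = dimg),
       wcoils = array(v[-seq_len(ni)], dim = dwc))
}

.normalOp <- function(v, ctx, plan, alpha, dimg, dwc) {
  ni <- prod(dimg)
  dy <- .derivativeFromCtx(ctx, v[seq_len(ni)], v[-seq_len(ni)], plan)
  bk <- .adjointFromCtx(ctx, dy, plan)
  c(as.vector(bk$images), as.vector(bk$wcoils)) + alpha * v
}

.cgSolve <- function(applyA, b, maxIter, relTol) {
  x <- complex(length(b))
  r <- b
  p <- r
  rz <- Re(sum(Conj(r) * r))
  b0 <- sqrt(rz)
  iters <- 0L
  if (b0 == 0) return(list(x = x, iters = 0L))
  for (it in seq_len(maxIter)) {
    Ap <- applyA(p)
    pAp <- Re(sum(Conj(p) * Ap))
    if (!is.finite(pAp) || pAp <= 0) {
      stop(errorCondition(sprintf("conjugate gradient broke down at inner iteration %d", it),
                          class = c("enlivr_solver_error", "error", "condition")))
    }
    a <- rz / pAp
    x <- x + a * p
    r <- r - a * Ap
    rzNew <- Re(sum(Conj(r) * r))
    iters <- it
    if (sqrt(rzNew) <= relTol * b0) break
    p <- r + (rzNew / rz) * p
    rz <- rzNew
  }
  if (any(!is.finite(Re(x))) || any(!is.finite(Im(x)))) {
    stop(errorCondition("conjugate gradient produced non-finite values",
                        class = c("enlivr_solver_error", "error", "condition")))
  }
  list(x = x, iters = iters)
}

.dataVec <- function(y) as.vector(y)

#' One iteratively regularized Gauss-Newton step
#'
#' Solves the regularized normal equations
#' \deqn{(DF^H DF + \alpha I)\,dx = DF^H(y - F(x_n)) - \alpha (x_n - x_{ref})}
#' by conjugate gradients, takes the full step and re-orthogonalizes the coil
#' sets.
#'
#' @param x Current [MultisetEstimate-class].
#' @param data A [KSpaceData-class] with the measured samples.
#' @param alpha Regularization of this step.
#' @param config A [SolverConfig-class] (CG controls, reference policy).
#' @param plan Optional [operatorPlan()].
#' @param xref Reference estimate for the Tikhonov term (`NULL` = zero).
#' @param freezeCoils Diagnostic switch: if `TRUE` the coil profiles are held
#'   fixed and only the image maps are updated, which turns the step into a
#'   plain linear SENSE-type Tikhonov solve.
#' @return List with the updated estimate (`estimate`), CG iterations used
#'   (`cgIters`) and the Gram off-diagonal maximum after orthogonalization
#'   (`gramOffdiag`).
#' @export
newtonStep <- function(x, data, alpha, config = solverConfig(k = nSets(x)),
                       plan = operatorPlan(data, x@weighting, config@nufftMethod),
                       xref = NULL, freezeCoils = FALSE) {
  ctx <- .linearize(x, plan)
  yv <- if (plan$type == "cartesian") data@kspace else data@samples
  res <- yv - .forwardFromCtx(ctx, plan)
  bk <- .adjointFromCtx(ctx, res, plan)
  dimg <- dim(x@images); dwc <- dim(x@wcoils)
  xv <- .flatten(x@images, x@wcoils)
  refv <- if (is.null(xref)) 0 * xv else .flatten(xref@images, xref@wcoils)
  b <- .flatten(bk$images, bk$wcoils) - alpha * (xv - refv)
  if (freezeCoils) {
    ni <- prod(dimg)
    maskIdx <- seq_len(ni)
    applyA <- function(v) {
      vv <- complex(length(xv)); vv[maskIdx] <- v
      out <- .normalOp(vv, ctx, plan, alpha, dimg, dwc)
      out[maskIdx]
    }
    sol <- .cgSolve(applyA, b[maskIdx], config@cgMaxIter, config@cgTol)
    dv <- complex(length(xv)); dv[maskIdx] <- sol$x
  } else {
    applyA <- function(v) .normalOp(v, ctx, plan, alpha, dimg, dwc)
    sol <- .cgSolve(applyA, b, config@cgMaxIter, config@cgTol)
    dv <- sol$x
  }
  upd <- .unflatten(xv + dv, dimg, dwc)
  xNew <- x
  xNew@images <- upd$images
  xNew@wcoils <- upd$wcoils
  xNew <- gramSchmidtCoils(xNew)
  list(estimate = xNew, cgIters = sol$iters, gramOffdiag = .gramOffdiagMax(xNew))
}

#' Reconstruct images and coil profiles from multichannel k-space data
#'
#' Runs the full iteratively regularized Gauss-Newton reconstruction of the
#' relaxed multi-set model: data scaling, initialization (`m = 1`, coils 0,
#' unless `init` overrides it), `nNewton` Newton steps with
#' \eqn{\alpha_n = \alpha_0 q^{n-1}} and Gram-Schmidt set orthogonalization
#' after every step, then undoes the data scaling on the image maps. With
#' `k = 1` this is single-set nonlinear inversion (NLINV); `k >= 2` is the
#' relaxed model whose extra sets absorb data inconsistencies.
#'
#' @param data A [KSpaceData-class].
#' @param config A [SolverConfig-class].
#' @param init Optional initial [MultisetEstimate-class] (e.g. a
#'   [singularInitialGuess()]); defaults to [initializeEstimate()].
#' @return An [EnliveFit-class].
#' @examples
#' grid <- imagingGrid(32, 32)
#' truth <- makePhantom(grid, sheppLoganEllipses())
#' coils <- makeCoils(grid, 4)
#' y <- simulateKspace(truth, coils)
#' fit <- enliveReconstruct(y, solverConfig(k = 1, nNewton = 8))
#' fit
#' @export
enliveReconstruct <- function(data, config = solverConfig(), init = NULL) {
  yv <- if (is(data, "KSpaceCartesian")) data@kspace else data@samples
  if (any(!is.finite(Re(yv))) || any(!is.finite(Im(yv))))
    stop(errorCondition("non-finite values in the input samples",
                        class = c("enlivr_data_error", "error", "condition")))
  ynorm <- sqrt(sum(Mod(yv)^2))
  if (ynorm == 0)
    stop(errorCondition("input samples are identically zero",
                        class = c("enlivr_data_error", "error", "condition")))
  s <- config@dataScaleTarget / ynorm
  dataS <- data
  if (is(data, "KSpaceCartesian")) dataS@kspace <- data@kspace * s
  else dataS@samples <- data@samples * s

  plan <- operatorPlan(dataS, config@weighting, config@nufftMethod)
  x <- if (is.null(init)) {
    initializeEstimate(data@grid, config@k, nChannels(data), config@weighting)
  } else {
    ## a supplied estimate is interpreted in data units; move it to the
    ## internal scale (the scale convention lives in the image maps)
    init@images <- init@images * s
    init
  }
  x0 <- x

  n <- config@nNewton
  alphas <- config@alpha0 * config@q^(seq_len(n) - 1)
  resid <- objective <- gram <- numeric(n)
  cgIters <- integer(n)
  ysv <- if (is(dataS, "KSpaceCartesian")) dataS@kspace else dataS@samples
  ynormS <- sqrt(sum(Mod(ysv)^2))
  for (nstep in seq_len(n)) {
    xref <- if (config@regReference == "initial" ||
                nstep <= config@refSteps) x0 else NULL
    st <- newtonStep(x, dataS, alphas[nstep], config, plan, xref = xref)
    x <- st$estimate
    cgIters[nstep] <- st$cgIters
    gram[nstep] <- st$gramOffdiag
    r <- ysv - .forwardFromCtx(.linearize(x, plan), plan)
    resid[nstep] <- sqrt(sum(Mod(r)^2))
    objective[nstep] <- resid[nstep]^2 +
      alphas[nstep] * (sum(Mod(x@wcoils)^2) + sum(Mod(x@images)^2))
  }
  x@images <- x@images / s
  report <- new("SolveReport", alpha = alphas, residual = resid,
                relResidual = resid / ynormS, objective = objective,
                cgIters = cgIters, gramOffdiag = gram)
  new("EnliveFit", estimate = x, report = report, config = config, scale = s)
}
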