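## Tiny-instance lifted formulation of the bilinear model. The unknown
## becomes the matrix X = U V^T (N_I x NC*N_I), u ~ image, v ~ stacked
## weighted coil profiles, and the forward map becomes the explicit linear
## operator A with A{u v^T} equal to the bilinear forward model. Used to test
## the theory that the l2-regularized factored problem matches nuclear-norm
## regularization whenever the nuclear-norm solution has rank <= k.

#' Dense lifted forward operator on a tiny grid
#'
#' Materializes the linear operator `A` mapping `vec(X)`,
#' `X` of shape `N_I x (NC * N_I)`, to the masked multichannel k-space
#' samples, such that on rank-1 `X = u v^T` it reproduces the bilinear
#' forward model (image `u`, stacked weighted coil profiles `v`). The coil
#' weighting is folded into `A`.
#'
#' @param grid A small [ImagingGrid-class] (dense matrices scale as
#'   `N_I^2 * NC`).
#' @param nc Number of coils.
#' @param mask Logical sampling mask on the grid (default fully sampled).
#' @param weighting A [CoilWeighting-class].
#' @return List with the dense complex matrix `A` (`(M * NC) x (N_I^2 * NC)`),
#'   the sampled index set and the problem dimensions.
#' @export
liftedOperator <- function(grid, nc, mask = NULL, weighting = coilWeighting()) {
  d <- gridDims(grid)
  N <- prod(d)
  if (is.null(mask)) mask <- array(TRUE, dim = d)
  sampIdx <- which(as.vector(mask))
  M <- length(sampIdx)
  ## dense unitary centered DFT matrix (x fastest, column-major voxel order)
  ph <- 0
  for (i in 1:3) {
    if (d[i] == 1L) next
    ax <- centeredCoords(d[i])[.voxAxisIndex(d, i)]
    ph <- ph + outer(ax, ax) / d[i]
  }
  Fm <- exp(-2i * pi * ph) / sqrt(N)
  w <- as.vector(weightValues(weighting, grid))
  Winv <- Conj(t(Fm)) %*% diag(1 / w, N)          # c = F^-1 diag(1/w) chat
  PF <- Fm[sampIdx, , drop = FALSE]
  A <- matrix(0 + 0i, M * nc, N * N * nc)
  for (j in seq_len(nc)) {
    rows <- (j - 1L) * M + seq_len(M)
    for (s in seq_len(N)) {
      colBlock <- ((j - 1L) * N + s - 1L) * N + seq_len(N)
      A[rows, colBlock] <- PF %*% diag(Winv[, s], N)
    }
  }
  list(A = A, N = N, nc = nc, M = M, sampIdx = sampIdx, grid = grid,
       weighting = weighting, d = d)
}

#' Apply the lifted operator
#'
#' @param lp A [liftedOperator()] structure.
#' @param X Complex matrix `N_I x (NC * N_I)` (or its vectorization).
#' @return Complex sample vector of length `M * NC` (coil blocks stacked).
#' @export
liftApply <- function(lp, X) {
  as.vector(lp$A %*% as.vector(X))
}

#' Stacked data vector of a [KSpaceCartesian-class] for the lifted problem
#'
#' @param lp A [liftedOperator()] structure.
#' @param data Cartesian data on the same grid and mask.
#' @return Complex vector of length `M * NC`.
#' @export
liftedDataVector <- function(lp, data) {
  ks <- matrix(data@kspace, ncol = nChannels(data))
  as.vector(ks[lp$sampIdx, , drop = FALSE])
}

#' Nuclear-norm regularized solution of the lifted linear problem
#'
#' Minimizes \eqn{\|y - A X\|_2^2 + 2\alpha \|X\|_*} by accelerated proximal
#' gradient (iterative singular-value soft-thresholding) to a relative
#' fixed-point tolerance.
#'
#' @param lp A [liftedOperator()] structure.
#' @param y Complex data vector (length `M * NC`).
#' @param alpha Regularization parameter.
#' @param tol Relative fixed-point tolerance.
#' @param maxIter Iteration cap.
#' @return List with the solution matrix `X`, its `objective`, singular
#'   values `sv` and numerical `rank` (singular values above `1e-6` of the
#'   largest).
#' @export
solveNuclear <- function(lp, y, alpha, tol = 1e-8, maxIter = 20000L) {
  N <- lp$N; nc <- lp$nc
  L <- 2 * (svd(lp$A, nu = 0, nv = 0)$d[1])^2
  t_ <- 1 / L
  X <- matrix(0 + 0i, N, nc * N)
  Z <- X
  tk <- 1
  Ah <- Conj(t(lp$A))
  svt <- function(M_, thr) {
    s <- svd(M_)
    dv <- pmax(s$d - thr, 0)
    keep <- dv > 0
    if (!any(keep)) return(matrix(0 + 0i, nrow(M_), ncol(M_)))
    s$u[, keep, drop = FALSE] %*% (dv[keep] * Conj(t(s$v[, keep, drop = FALSE])))
  }
  for (it in seq_len(maxIter)) {
    G <- Z - t_ * matrix(2 * (Ah %*% (lp$A %*% as.vector(Z) - y)), N, nc * N)
    Xn <- svt(G, 2 * alpha * t_)
    tkn <- (1 + sqrt(1 + 4 * tk^2)) / 2
    Z <- Xn + ((tk - 1) / tkn) * (Xn - X)
    dX <- sqrt(sum(Mod(Xn - X)^2))
    X <- Xn
    tk <- tkn
    if (dX <= tol * max(1, sqrt(sum(Mod(X)^2)))) break
  }
  sv <- svd(X, nu = 0, nv = 0)$d
  obj <- sum(Mod(y - lp$A %*% as.vector(X))^2) + 2 * alpha * sum(sv)
  list(X = X, objective = obj, sv = sv,
       rank = sum(sv > 1e-6 * max(sv, .Machine$double.eps)))
}

#' Factored (rank-k) solution of the lifted problem
#'
#' Minimizes \eqn{\|y - A(UV^T)\|_2^2 + \alpha(\|U\|_F^2 + \|V\|_F^2)} by
#' alternating exact ridge solves in `U` and `V` from seeded random starts,
#' keeping the best stationary point.
#'
#' @param lp A [liftedOperator()] structure.
#' @param y Complex data vector.
#' @param k Factor rank.
#' @param alpha Regularization parameter.
#' @param restarts Number of random restarts.
#' @param tol Relative change tolerance declaring stationarity.
#' @param maxIter Alternation cap per restart.
#' @param seed Seed for the random starts.
#' @return List with `U`, `V`, the attained `objective` and the number of
#'   alternations of the best run.
#' @export
solveFactored <- function(lp, y, k, alpha, restarts = 3L, tol = 1e-10,
                          maxIter = 2000L, seed = 1L) {
  N <- lp$N; nc <- lp$nc
  nr <- nrow(lp$A)
  Aarr <- array(lp$A, dim = c(nr, N, nc * N))
  AmatR <- matrix(Aarr, nr * N, nc * N)      # [row, r] x [c] contraction helper
  objective <- function(U, V) {
    X <- U %*% t(V)
    sum(Mod(y - lp$A %*% as.vector(X))^2) + alpha * (sum(Mod(U)^2) + sum(Mod(V)^2))
  }
  ridge <- function(B, yv, a) {
    H <- Conj(t(B)) %*% B
    diag(H) <- diag(H) + a
    solve(H, Conj(t(B)) %*% yv)
  }
  set.seed(seed)
  best <- NULL
  for (rs in seq_len(restarts)) {
    U <- matrix(complex(real = rnorm(N * k), imaginary = rnorm(N * k)), N, k) * 0.1
    V <- matrix(complex(real = rnorm(nc * N * k), imaginary = rnorm(nc * N * k)),
                nc * N, k) * 0.1
    objPrev <- Inf
    iters <- 0L
    repeat {
      iters <- iters + 1L
      ## design for U given V: columns (l, r) -> A applied to e_r v_l^T
      BV <- matrix(matrix(Aarr, nr * N, nc * N) %*% V, nr, N * k)
      U <- matrix(ridge(BV, y, alpha), N, k)
      ## design for V given U: columns (l, c) -> A applied to (U e_l) e_c^T
      CU <- array(0 + 0i, dim = c(nr, nc * N, k))
      for (l in seq_len(k)) {
        for (cidx in seq_len(nc * N)) {
          CU[, cidx, l] <- Aarr[, , cidx] %*% U[, l]
        }
      }
      V <- matrix(ridge(matrix(CU, nr, nc * N * k), y, alpha), nc * N, k)
      obj <- objective(U, V)
      if (iters >= maxIter || abs(objPrev - obj) <= tol * max(1, obj)) break
      objPrev <- obj
    }
    if (is.null(best) || obj < best$objective) {
      best <- list(U = U, V = V, objective = obj, iterations = iters)
    }
  }
  best
}

#' Balanced factorization of a low-rank matrix
#'
#' Thin SVD factorization \eqn{X = U V^T} distributing the singular values
#' equally as square roots to both factors, so that
#' \eqn{\|U\|_F^2 = \|V\|_F^2 = \|X\|_*}.
#'
#' @param X Complex matrix of (numerical) rank at most `k`.
#' @param k Retained rank.
#' @return List with `U`, `V` and the nuclear norm `nuc`.
#' @export
balancedFactorization <- function(X, k) {
  s <- svd(X, nu = min(k, nrow(X)), nv = min(k, ncol(X)))
  dv <- s$d[seq_len(k)]
  rt <- sqrt(dv)
  list(U = s$u[, seq_len(k), drop = FALSE] %*% diag(rt, k),
       V = Conj(s$v[, seq_len(k), drop = FALSE]) %*% diag(rt, k),
       nuc = sum(s$d))
}
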