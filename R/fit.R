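#' Objective of the weighted sparse semi-nonnegative factorization
#'
#' Evaluates
#' \deqn{\frac{1}{2D}\| (X - L F^\top) \odot W \|_F^2 + \alpha \|L\|_1 + \lambda \|F\|_1}
#' where `W` is the elementwise reciprocal of the standard errors (zero on
#' unobserved entries) and `D` is the number of eQTLs. Unobserved cells
#' contribute nothing to the residual term.
#'
#' @param effects a [MultiTissueEffects-class] object.
#' @param F T x K nonnegative factor matrix (nonnegativity is not required
#'   for evaluation, so mid-optimization iterates can be scored).
#' @param L D x K loading matrix.
#' @param alpha,lambda nonnegative L1 penalties on `L` and `F`.
#' @return the objective value (nonnegative scalar).
#' @export
computeObjective <- function(effects, F, L, alpha, lambda) {
  X <- effectSizes(effects); W <- eqtlWeights(effects)
  if (nrow(L) != nrow(X) || nrow(F) != ncol(X) || ncol(F) != ncol(L))
    stop("shape mismatch between effects, F and L")
  R <- (X - L %*% t(F)) * W
  sum(R^2) / (2 * nrow(X)) + alpha * sum(abs(L)) + lambda * sum(abs(F))
}

#' One ALS half-step: update the loading matrix
#'
#' With `F` fixed, each row d of `L` solves the weighted lasso
#' \eqn{\min_l \frac{1}{2D}\|(x_d - F l) \odot w_d\|^2 + \alpha\|l\|_1}
#' (unconstrained sign), by cyclic coordinate descent with exact
#' soft-thresholding. Rows whose weights are all zero get all-zero loadings.
#'
#' @inheritParams computeObjective
#' @param L_init starting value (D x K); defaults to zeros.
#' @param inner_tol,inner_max coordinate-descent stopping parameters.
#' @return updated D x K loading matrix.
#' @export
updateLoadings <- function(effects, F, alpha, L_init = NULL,
                           inner_tol = 1e-8, inner_max = 1000L) {
  X <- effectSizes(effects); W <- eqtlWeights(effects)
  K <- ncol(F); D <- nrow(X)
  if (nrow(F) != ncol(X)) stop("F rows must match tissue count")
  if (is.null(L_init)) L_init <- matrix(0, D, K)
  L <- .cdUpdateMatrix(X, W^2, F, L_init, alpha, D, FALSE, inner_tol, inner_max)
  dimnames(L) <- list(rownames(X), colnames(F))
  L
}

#' One ALS half-step: update the nonnegative factor matrix
#'
#' With `L` fixed, each row t of `F` solves the nonnegative weighted lasso
#' for tissue t's column of `X`, by coordinate descent with a nonnegativity
#' clamp on the soft-threshold update.
#'
#' @inheritParams updateLoadings
#' @param F_init starting value (T x K); defaults to zeros.
#' @return updated T x K nonnegative factor matrix.
#' @export
updateFactors <- function(effects, L, lambda, F_init = NULL,
                          inner_tol = 1e-8, inner_max = 1000L) {
  X <- effectSizes(effects); W <- eqtlWeights(effects)
  K <- ncol(L); D <- nrow(X)
  if (nrow(L) != nrow(X)) stop("L rows must match eQTL count")
  if (is.null(F_init)) F_init <- matrix(0, ncol(X), K)
  F <- .cdUpdateMatrix(t(X), t(W^2), L, F_init, lambda, D, TRUE,
                       inner_tol, inner_max)
  dimnames(F) <- list(colnames(X), colnames(L))
  F
}

#' Fit the weighted sparse semi-nonnegative matrix factorization
#'
#' Alternating least squares: starting from a random nonnegative `F`
#' (entries Uniform(0,1) under `seed`), alternately solve the loading and
#' factor subproblems until the Frobenius norm of the change in `F` between
#' two iterations falls below `tol` (default 0.01) or `max_iter` is reached.
#' Each half-step solves its convex subproblem exactly, so the objective is
#' non-increasing. All-zero factor columns (empty factors) are dropped from
#' the returned model, with the matching loading columns removed.
#'
#' @inheritParams computeObjective
#' @param K requested rank (number of factors); a warning is raised when
#'   `K` exceeds the tissue count.
#' @param seed integer seed for the initialization.
#' @param max_iter iteration cap (default 100); exceeding it returns an
#'   unconverged model rather than an error so that unstable
#'   hyper-parameter settings can still be scored during model selection.
#' @param tol Frobenius-norm convergence threshold on the change in `F`.
#' @param inner_tol,inner_max coordinate-descent stopping parameters.
#' @return a [FactorModel-class].
#' @examples
#' sim <- simulateDataset(N = 40, T = 6, K = 2, sigma2 = 0, seed = 1)
#' fit <- fitSnSpMF(sim$effects, K = 2, alpha = 0.049, lambda = 0.049, seed = 1)
#' rrmse(loadingMatrix(fit) %*% t(factorMatrix(fit)), effectSizes(sim$effects))
#' @export
fitSnSpMF <- function(effects, K, alpha, lambda, seed = 1L,
                      max_iter = 100L, tol = 0.01,
                      inner_tol = 1e-8, inner_max = 1000L) {
  stopifnot(K >= 1)
  X <- effectSizes(effects)
  T <- ncol(X); D <- nrow(X)
  if (K > T) warning("requested rank exceeds tissue count; sparsity may empty factors")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  F <- matrix(stats::runif(T * K), T, K)
  L <- matrix(0, D, K)
  W <- eqtlWeights(effects)
  W2 <- W^2; tX <- t(X); tW2 <- t(W2)
  trace <- numeric(0)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    L <- .cdUpdateMatrix(X, W2, F, L, alpha, D, FALSE, inner_tol, inner_max)
    F_new <- .cdUpdateMatrix(tX, tW2, L, F, lambda, D, TRUE, inner_tol, inner_max)
    R <- (X - L %*% t(F_new)) * W
    obj <- sum(R^2) / (2 * D) + alpha * sum(abs(L)) + lambda * sum(abs(F_new))
    if (!is.finite(obj)) stop(sprintf("non-finite objective at iteration %d", it))
    trace <- c(trace, obj)
    delta <- sqrt(sum((F_new - F)^2))
    F <- F_new
    if (delta < tol) { converged <- TRUE; break }
  }
  keep <- colSums(abs(F)) > 0
  F <- F[, keep, drop = FALSE]
  L <- L[, keep, drop = FALSE]
  if (ncol(F)) colnames(F) <- colnames(L) <- paste0("Factor", seq_len(ncol(F)))
  rownames(F) <- colnames(X); rownames(L) <- rownames(X)
  new("FactorModel", F = F, L = L, K_input = as.integer(K),
      alpha = alpha, lambda = lambda, objective_trace = trace,
      converged = converged, seed = as.integer(seed))
}
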