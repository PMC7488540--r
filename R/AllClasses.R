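#' @import methods
#' @importFrom Rcpp sourceCpp
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @useDynLib snspmf, .registration = TRUE
NULL

#' Multi-tissue eQTL effect container
#'
#' Holds a D x T matrix of eQTL effect sizes (`X`), their standard errors
#' (`SE`), an observation mask (`observed`) and the derived weight matrix
#' (`W`), as assays of a [SummarizedExperiment::SummarizedExperiment].
#' Rows are eQTLs (gene:variant pairs), columns are tissues. The weight of
#' each observed entry is the reciprocal of its standard error; unobserved
#' entries carry weight zero so they never contribute to the factorization
#' objective.
#'
#' @slot ... inherited from `SummarizedExperiment`; assays must contain
#'   `X`, `SE`, `W` and `observed` with identical dimensions.
#'
#' @seealso [multiTissueEffects()], [loadSummaryStats()], [fitSnSpMF()]
#' @export
setClass("MultiTissueEffects", contains = "SummarizedExperiment")

setValidity("MultiTissueEffects", function(object) {
  a <- SummarizedExperiment::assays(object)
  need <- c("X", "SE", "W", "observed")
  if (!all(need %in% names(a)))
    return(sprintf("assays must contain %s", paste(need, collapse = ", ")))
  X <- a$X; SE <- a$SE; W <- a$W; obs <- a$observed
  if (!is.logical(obs)) return("'observed' assay must be logical")
  if (any(duplicated(rownames(object)))) return("eQTL ids must be unique")
  if (any(obs & (!is.finite(X)))) return("non-finite effect size on an observed entry")
  if (any(obs & (!is.finite(SE) | SE <= 0)))
    return("standard errors must be positive and finite wherever observed")
  w_exp <- ifelse(obs, 1 / SE, 0)
  w_exp[!obs] <- 0
  if (!isTRUE(all.equal(as.vector(W), as.vector(w_exp), tolerance = 1e-12)))
    return("W must equal 1/SE on observed entries and 0 elsewhere")
  TRUE
})

#' Construct a MultiTissueEffects object
#'
#' @param X D x T numeric matrix of eQTL effect sizes (regression slopes).
#' @param SE D x T numeric matrix of standard errors; must be positive
#'   wherever `observed` is `TRUE`.
#' @param observed D x T logical mask; defaults to entries where both `X`
#'   and `SE` are finite and `SE > 0`.
#' @param eqtl_ids,tissue_ids row / column identifiers; default to the
#'   dimnames of `X`.
#'
#' @return A [MultiTissueEffects-class] object with the weight assay
#'   `W = 1/SE` on observed entries and `0` elsewhere.
#' @examples
#' X <- matrix(c(0.5, -0.2), 1, 2, dimnames = list("g1:v1", c("Liver", "Lung")))
#' SE <- matrix(c(0.25, 0.1), 1, 2, dimnames = dimnames(X))
#' mte <- multiTissueEffects(X, SE)
#' eqtlWeights(mte)  # 4 and 10
#' @export
multiTissueEffects <- function(X, SE, observed = NULL,
                               eqtl_ids = rownames(X), tissue_ids = colnames(X)) {
  X <- as.matrix(X); SE <- as.matrix(SE)
  stopifnot(all(dim(X) == dim(SE)))
  if (is.null(eqtl_ids)) eqtl_ids <- paste0("eqtl", seq_len(nrow(X)))
  if (is.null(tissue_ids)) tissue_ids <- paste0("tissue", seq_len(ncol(X)))
  if (is.null(observed)) {
    observed <- is.finite(X) & is.finite(SE) & SE > 0
  }
  observed <- as.matrix(observed)
  mode(observed) <- "logical"
  bad <- observed & (!is.finite(SE) | SE <= 0)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("non-positive or non-finite SE on observed entry (eqtl '%s', tissue '%s')",
                 eqtl_ids[idx[1]], tissue_ids[idx[2]]))
  }
  W <- matrix(0, nrow(X), ncol(X))
  W[observed] <- 1 / SE[observed]
  X[!observed] <- 0
  SE[!observed] <- NA_real_
  dn <- list(eqtl_ids, tissue_ids)
  dimnames(X) <- dimnames(SE) <- dimnames(W) <- dimnames(observed) <- dn
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(X = X, SE = SE, W = W, observed = observed))
  new("MultiTissueEffects", se)
}

#' @describeIn multiTissueEffects effect-size matrix (unobserved entries 0)
#' @param object,x a `MultiTissueEffects`
#' @export
effectSizes <- function(object) SummarizedExperiment::assay(object, "X")

#' @describeIn multiTissueEffects standard-error matrix (NA where unobserved)
#' @export
standardErrors <- function(object) SummarizedExperiment::assay(object, "SE")

#' @describeIn multiTissueEffects weight matrix, 1/SE or 0
#' @export
eqtlWeights <- function(object) SummarizedExperiment::assay(object, "W")

#' @describeIn multiTissueEffects logical observation mask
#' @export
observedMask <- function(object) SummarizedExperiment::assay(object, "observed")

#' @describeIn multiTissueEffects eQTL (row) identifiers
#' @export
eqtlIds <- function(object) rownames(object)

#' @describeIn multiTissueEffects tissue (column) identifiers
#' @export
tissueIds <- function(object) colnames(object)

setMethod("show", "MultiTissueEffects", function(object) {
  cat(sprintf("MultiTissueEffects: %d eQTLs x %d tissues (%.1f%% observed)\n",
              nrow(object), ncol(object),
              100 * mean(observedMask(object))))
})

#' Fitted semi-nonnegative sparse matrix factorization
#'
#' The result of [fitSnSpMF()]: a nonnegative tissue-factor matrix `F`
#' (T x K) and a real-valued loading matrix `L` (D x K), together with the
#' penalties that produced them, the objective trace, and convergence state.
#' Empty (all-zero) factors are removed at convergence, so the number of
#' columns may be smaller than the requested rank `K_input`.
#'
#' @slot F nonnegative T x K numeric matrix of tissue factors.
#' @slot L D x K numeric matrix of loadings (both signs allowed).
#' @slot K_input integer, the requested rank.
#' @slot alpha,lambda nonnegative L1 penalties on `L` and `F`.
#' @slot objective_trace numeric vector of objective values per iteration.
#' @slot converged logical.
#' @slot seed integer seed that generated the initialization.
#'
#' @seealso [fitSnSpMF()], [factorMatrix()], [loadingMatrix()]
#' @export
setClass("FactorModel",
  representation(F = "matrix", L = "matrix", K_input = "integer",
                 alpha = "numeric", lambda = "numeric",
                 objective_trace = "numeric", converged = "logical",
                 seed = "integer"))

setValidity("FactorModel", function(object) {
  if (ncol(object@F) != ncol(object@L)) return("F and L must have the same number of columns")
  if (length(object@F) && min(object@F) < 0) return("F must be nonnegative")
  if (ncol(object@F) > object@K_input) return("more factors than requested rank")
  if (object@alpha < 0 || object@lambda < 0) return("penalties must be nonnegative")
  TRUE
})

#' @describeIn FactorModel the nonnegative tissue-factor matrix (T x K)
#' @param object a `FactorModel`
#' @export
factorMatrix <- function(object) object@F

#' @describeIn FactorModel the loading matrix (D x K)
#' @export
loadingMatrix <- function(object) object@L

#' @describeIn FactorModel objective value after each full ALS iteration
#' @export
objectiveTrace <- function(object) object@objective_trace

#' @describeIn FactorModel whether the Frobenius-norm stopping rule fired
#' @export
isConverged <- function(object) object@converged

#' @describeIn FactorModel number of retained (non-empty) factors
#' @export
numFactors <- function(object) ncol(object@F)

setMethod("show", "FactorModel", function(object) {
  cat(sprintf(paste0("FactorModel: %d tissues x %d factors (requested K = %d)\n",
                     "  alpha = %g, lambda = %g, %s after %d iterations\n"),
              nrow(object@F), ncol(object@F), object@K_input,
              object@alpha, object@lambda,
              if (object@converged) "converged" else "NOT converged",
              length(object@objective_trace)))
})

#' Hyper-parameter grid evaluation report
#'
#' One row per (K, alpha, lambda) setting, carrying the stability and
#' factor-independence summaries used by the three-stage selector, plus the
#' consensus matrices from the repeated random-initialization runs.
#'
#' @slot table data.frame with columns `K`, `alpha`, `lambda`, `K_prime`,
#'   `mean_nonempty_K`, `cophenetic`, `independence`, `eliminated_at_stage`.
#' @slot consensus list of T x T consensus matrices, one per setting.
#' @slot n_runs number of random-initialization runs per setting.
#'
#' @seealso [evaluateGrid()], [selectModel()]
#' @export
setClass("GridReport",
  representation(table = "data.frame", consensus = "list", n_runs = "integer"))

#' @describeIn GridReport the per-setting summary table
#' @param object a `GridReport`
#' @export
gridTable <- function(object) object@table

setMethod("show", "GridReport", function(object) {
  cat(sprintf("GridReport: %d settings x %d runs\n", nrow(object@table), object@n_runs))
  print(utils::head(object@table, 10))
})
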