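#' Tissue co-assignment consensus matrix over repeated runs
#'
#' Each tissue is assigned to the factor holding its row-maximum in `F`
#' (ties to the lowest-index factor; a tissue whose row is all zero is
#' unassigned and co-assigned with nobody). The consensus entry C[s,t] is the
#' fraction of runs in which tissues s and t land in the same factor; the
#' diagonal is 1 by definition. A run with zero retained factors contributes
#' "no pair co-assigned".
#'
#' @param runs list of [FactorModel-class] objects fitted on the same tissues.
#' @return symmetric T x T matrix with entries in [0, 1].
#' @export
consensusMatrix <- function(runs) {
  stopifnot(length(runs) >= 2)
  T <- nrow(factorMatrix(runs[[1]]))
  C <- matrix(0, T, T)
  for (run in runs) {
    F <- factorMatrix(run)
    if (nrow(F) != T) stop("runs disagree on tissue count")
    if (ncol(F) == 0) next
    assign <- apply(F, 1, function(row) {
      if (all(row == 0)) NA_integer_ else which.max(row)
    })
    same <- outer(assign, assign, `==`)
    same[is.na(same)] <- FALSE
    C <- C + same
  }
  C <- C / length(runs)
  diag(C) <- 1
  dimnames(C) <- list(rownames(factorMatrix(runs[[1]])),
                      rownames(factorMatrix(runs[[1]])))
  C
}

#' Cophenetic correlation of a consensus matrix
#'
#' Measures factorization stability: the Pearson correlation between the
#' off-diagonal consensus dissimilarities 1 - C and the cophenetic distances
#' of their average-linkage hierarchical clustering. A consensus whose
#' off-diagonal dissimilarities are all equal is perfectly stable by
#' convention and returns 1.
#'
#' @param C symmetric consensus matrix with entries in [0, 1].
#' @return correlation in [-1, 1].
#' @export
copheneticCorrelation <- function(C) {
  T <- nrow(C)
  if (T < 3) stop("cophenetic correlation undefined for fewer than 3 tissues")
  d <- stats::as.dist(1 - C)
  if (stats::sd(d) == 0) return(1.0)
  hc <- stats::hclust(d, method = "average")
  coph <- stats::cophenetic(hc)
  if (stats::sd(coph) == 0) {
    warning("degenerate cophenetic distances; correlation undefined")
    return(NA_real_)
  }
  stats::cor(as.vector(d), as.vector(coph))
}

#' Mean factor-independence score across runs
#'
#' For each run, computes the Pearson correlation between every pair of
#' distinct factor columns and takes the Frobenius norm of the off-diagonal
#' pairwise-correlation matrix; the score is the mean over runs. Lower means
#' more independent (and adequately sparse) factors. A constant factor column
#' contributes zero correlations, with a warning.
#'
#' @param runs list of [FactorModel-class] objects with >= 2 non-empty factors.
#' @return nonnegative scalar.
#' @export
factorIndependenceScore <- function(runs) {
  scores <- vapply(runs, function(run) {
    F <- factorMatrix(run)
    if (ncol(F) < 2) stop("factor independence needs >= 2 non-empty factors")
    const <- apply(F, 2, stats::sd) == 0
    if (any(const)) warning("zero-variance factor column; correlations set to 0")
    R <- suppressWarnings(stats::cor(F))
    R[is.na(R)] <- 0
    diag(R) <- 0
    sqrt(sum(R^2))
  }, 0)
  mean(scores)
}

#' Evaluate a hyper-parameter grid by repeated random-initialization fits
#'
#' For every (K, alpha, lambda) combination, fits the model `n_runs` times
#' with seeds derived from `seed`, and records the consensus matrix, its
#' cophenetic correlation, the mean number of non-empty factors, and the
#' factor-independence score.
#'
#' @param effects a [MultiTissueEffects-class].
#' @param K_grid,alpha_grid,lambda_grid numeric vectors of candidate values.
#'   Defaults follow the search space used for a 49-tissue analysis.
#' @param n_runs number of random initializations per setting (default 30).
#' @param seed root seed; run r of setting i uses a seed derived from both.
#' @param ... passed to [fitSnSpMF()].
#' @return a [GridReport-class].
#' @export
evaluateGrid <- function(effects, K_grid = c(20, 25, 30, 35, 40),
                         alpha_grid = c(4.9, 24.5, 49, 245, 490),
                         lambda_grid = alpha_grid,
                         n_runs = 30L, seed = 1L, ...) {
  settings <- expand.grid(K = K_grid, alpha = alpha_grid, lambda = lambda_grid,
                          KEEP.OUT.ATTRS = FALSE)
  consensus <- vector("list", nrow(settings))
  tab <- cbind(settings, K_prime = NA_real_, mean_nonempty_K = NA_real_,
               cophenetic = NA_real_, independence = NA_real_,
               eliminated_at_stage = 0L)
  for (i in seq_len(nrow(settings))) {
    runs <- lapply(seq_len(n_runs), function(r)
      fitSnSpMF(effects, K = settings$K[i], alpha = settings$alpha[i],
                lambda = settings$lambda[i],
                seed = deriveSeed(seed, "fit", i * 1000L + r), ...))
    nonempty <- vapply(runs, numFactors, 0L)
    consensus[[i]] <- consensusMatrix(runs)
    tab$mean_nonempty_K[i] <- mean(nonempty)
    tab$K_prime[i] <- round(mean(nonempty))
    tab$cophenetic[i] <- copheneticCorrelation(consensus[[i]])
    tab$independence[i] <- if (all(nonempty >= 2))
      factorIndependenceScore(runs) else NA_real_
  }
  new("GridReport", table = tab, consensus = consensus,
      n_runs = as.integer(n_runs))
}

#' Three-stage stability-based model selection
#'
#' Stage 1 groups settings by their rounded mean non-empty factor count K'
#' and eliminates every group whose median cophenetic correlation is below
#' `stability_threshold`. Stage 2 eliminates the remaining individual
#' settings with cophenetic correlation below the threshold. Stage 3 picks,
#' among the survivors, the setting with the minimum factor-independence
#' score (ties: smaller K', then larger alpha + lambda).
#'
#' @param grid a [GridReport-class] from [evaluateGrid()].
#' @param stability_threshold cophenetic cutoff (default 0.9).
#' @return list with `chosen` (one-row data.frame: K, alpha, lambda, K_prime,
#'   cophenetic, independence) and `audit` (the grid table with
#'   `eliminated_at_stage`: 1, 2, or 0 for survivors).
#' @export
selectModel <- function(grid, stability_threshold = 0.9) {
  tab <- gridTable(grid)
  tab$eliminated_at_stage <- 0L
  med <- tapply(tab$cophenetic, tab$K_prime, stats::median, na.rm = TRUE)
  bad_kp <- as.numeric(names(med))[is.na(med) | med < stability_threshold]
  tab$eliminated_at_stage[tab$K_prime %in% bad_kp] <- 1L
  s2 <- tab$eliminated_at_stage == 0L &
    (is.na(tab$cophenetic) | tab$cophenetic < stability_threshold)
  tab$eliminated_at_stage[s2] <- 2L
  alive <- which(tab$eliminated_at_stage == 0L & !is.na(tab$independence))
  if (!length(alive))
    stop("all settings eliminated; expand the hyper-parameter grid")
  ord <- alive[order(tab$independence[alive], tab$K_prime[alive],
                     -(tab$alpha[alive] + tab$lambda[alive]))]
  chosen <- tab[ord[1], c("K", "alpha", "lambda", "K_prime",
                          "cophenetic", "independence")]
  rownames(chosen) <- NULL
  list(chosen = chosen, audit = tab)
}
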