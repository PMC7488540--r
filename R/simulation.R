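#' Simulate a multi-tissue eQTL effect-size matrix with known factors
#'
#' Generates one dense (ubiquitous) factor supported on every tissue and
#' `K - 1` sparse factors, each supported on `ceiling(T / (K - 1))` tissues
#' (disjoint where possible). Nonzero factor entries are Uniform(0.5, 1.5);
#' each eQTL activates each factor independently with probability
#' `loading_prob` (at least one forced), with nonzero loadings drawn from a
#' standard normal. The observed matrix is \eqn{X = L F^\top + E} with
#' i.i.d. Gaussian noise of variance `sigma2`; the standard-error matrix is
#' the constant \eqn{\sqrt{\sigma^2}} (so every weight is
#' \eqn{1/\sqrt{\sigma^2}}), or 1 when `sigma2 = 0`.
#'
#' @param N number of eQTLs (default 100).
#' @param T number of tissues (default 10).
#' @param K number of factors including the dense one (default 5; must not
#'   exceed `T`).
#' @param sigma2 noise variance; the study grid is 0.001, 0.01, 0.05, 0.1.
#' @param seed integer seed; the whole dataset is reproducible from it.
#' @param loading_prob per-factor activation probability per eQTL (default 0.3).
#' @param support_size tissues per sparse factor; default `ceiling(T/(K-1))`.
#' @return list with `effects` (a [MultiTissueEffects-class]) and `truth`
#'   (list: `F_true`, `L_true`, `sigma2`, `seed`, `u_labels`, `ts_labels` —
#'   logical vector / list derived from the loading support).
#' @export
simulateDataset <- function(N = 100, T = 10, K = 5, sigma2 = 0.01, seed = 1L,
                            loading_prob = 0.3,
                            support_size = ceiling(T / (K - 1))) {
  if (K > T) stop("K must not exceed the number of tissues")
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  F_true <- matrix(0, T, K)
  F_true[, 1] <- stats::runif(T, 0.5, 1.5)          # dense, full-support factor
  pool <- sample.int(T)                              # disjoint supports while they last
  for (k in seq_len(K - 1) + 1) {
    if (length(pool) >= support_size) {
      supp <- pool[seq_len(support_size)]
      pool <- pool[-seq_len(support_size)]
    } else {
      supp <- c(pool, sample(setdiff(seq_len(T), pool),
                             support_size - length(pool)))
      pool <- integer(0)
    }
    F_true[supp, k] <- stats::runif(support_size, 0.5, 1.5)
  }
  active <- matrix(stats::runif(N * K) < loading_prob, N, K)
  none <- !rowSums(active)
  if (any(none))
    active[cbind(which(none), sample.int(K, sum(none), replace = TRUE))] <- TRUE
  L_true <- matrix(0, N, K)
  L_true[active] <- stats::rnorm(sum(active))
  E <- matrix(stats::rnorm(N * T, sd = sqrt(sigma2)), N, T)
  X <- L_true %*% t(F_true) + E
  se_const <- if (sigma2 > 0) sqrt(sigma2) else 1
  SE <- matrix(se_const, N, T)
  dimnames(X) <- dimnames(SE) <- list(paste0("gene", seq_len(N), ":v", seq_len(N)),
                                      paste0("tissue", seq_len(T)))
  rownames(L_true) <- rownames(X)
  rownames(F_true) <- colnames(X)
  colnames(F_true) <- colnames(L_true) <- paste0("Factor", seq_len(K))
  effects <- multiTissueEffects(X, SE)
  truth <- list(F_true = F_true, L_true = L_true, sigma2 = sigma2,
                seed = as.integer(seed),
                u_labels = L_true[, 1] != 0,
                ts_labels = lapply(seq_len(N), function(i)
                  which(L_true[i, -1] != 0) + 1L))
  list(effects = effects, truth = truth)
}

#' Align learned factors to simulated truth and score recovery
#'
#' Exhaustively searches column permutations (feasible for K <= 8) of the
#' learned factor matrix to maximize the mean column-wise Pearson correlation
#' with the true factors (zero-variance columns contribute 0), then reports
#' the mean factor and loading correlations under that permutation. When
#' `labels` (from [classifyEqtls()]) are supplied, also computes precision
#' and recall of u-eQTL recovery and of tissue-specific (eQTL, factor)-pair
#' recovery against the truth's loading support.
#'
#' @param F_learned,L_learned learned matrices; fewer columns than the truth
#'   are padded with zeros.
#' @param truth the `truth` list from [simulateDataset()].
#' @param labels optional data.frame from [classifyEqtls()] on the learned
#'   model (row order matching the simulated eQTLs).
#' @return list: `permutation` (learned column for each true column),
#'   `factor_corr`, `loading_corr`, and (with labels) `u_precision`,
#'   `u_recall`, `ts_precision`, `ts_recall`.
#' @export
alignAndScore <- function(F_learned, L_learned, truth, labels = NULL) {
  F_true <- truth$F_true; L_true <- truth$L_true
  K <- ncol(F_true)
  if (K > 8) stop("exhaustive permutation search supported for K <= 8")
  pad <- K - ncol(F_learned)
  if (pad < 0) stop("more learned factors than true factors")
  if (pad > 0) {
    F_learned <- cbind(F_learned, matrix(0, nrow(F_learned), pad))
    L_learned <- cbind(L_learned, matrix(0, nrow(L_learned), pad))
  }
  col_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
    stats::cor(a, b)
  }
  perms <- allPermutations(K)
  best <- NULL; best_score <- -Inf
  for (p in perms) {
    score <- mean(vapply(seq_len(K), function(k)
      col_cor(F_learned[, p[k]], F_true[, k]), 0))
    if (score > best_score) { best_score <- score; best <- p }
  }
  factor_corr <- best_score
  loading_corr <- mean(vapply(seq_len(K), function(k)
    col_cor(L_learned[, best[k]], L_true[, k]), 0))
  out <- list(permutation = best, factor_corr = factor_corr,
              loading_corr = loading_corr)
  if (!is.null(labels)) {
    true_u <- truth$u_labels
    pred_u <- labels$u_eqtl
    out$u_precision <- safeRatio(sum(pred_u & true_u), sum(pred_u))
    out$u_recall <- safeRatio(sum(pred_u & true_u), sum(true_u))
    # tissue-specific pairs: map learned factor names back through the permutation
    learned_names <- colnames(F_learned)
    if (is.null(learned_names)) learned_names <- paste0("Factor", seq_len(K))
    true_pairs <- unlist(lapply(seq_along(truth$ts_labels), function(i) {
      k <- truth$ts_labels[[i]]
      if (!length(k)) return(character(0))   # paste(i, integer(0)) is "i "
      paste(i, k)
    }))
    pred_pairs <- unlist(lapply(seq_len(nrow(labels)), function(i) {
      fs <- strsplit(labels$ts_factors[i], ",")[[1]]
      fs <- fs[nzchar(fs)]
      if (!length(fs)) return(character(0))
      kl <- match(fs, learned_names)             # learned column index
      kt <- match(kl, best)                      # true column it aligns to
      kt <- kt[!is.na(kt)]
      paste(i, kt)
    }))
    out$ts_precision <- safeRatio(length(intersect(pred_pairs, true_pairs)),
                                  length(pred_pairs))
    out$ts_recall <- safeRatio(length(intersect(pred_pairs, true_pairs)),
                               length(true_pairs))
  }
  out
}

safeRatio <- function(num, den) if (den == 0) NA_real_ else num / den

allPermutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- allPermutations(n - 1L)
  out <- list()
  for (p in sub) for (i in seq_len(n)) out[[length(out) + 1L]] <- append(p, n, after = i - 1L)
  out
}
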