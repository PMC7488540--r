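# Shared helpers: small generators and independent oracles used across files.

# Random MultiTissueEffects with optional missingness.
randomEffects <- function(D, T, seed, missing_frac = 0) {
  set.seed(seed)
  X <- matrix(rnorm(D * T), D, T)
  SE <- matrix(runif(D * T, 0.5, 1.5), D, T)
  obs <- matrix(runif(D * T) >= missing_frac, D, T)
  # keep at least one observed entry per row and column
  obs[cbind(seq_len(D), sample.int(T, D, replace = TRUE))] <- TRUE
  dimnames(X) <- dimnames(SE) <- dimnames(obs) <-
    list(paste0("g", seq_len(D), ":v", seq_len(D)), paste0("t", seq_len(T)))
  multiTissueEffects(X, SE, observed = obs)
}

# Construct a FactorModel directly (for consensus / selection tests).
makeModel <- function(F, L = NULL, K_input = ncol(F)) {
  F <- as.matrix(F)
  if (is.null(L)) L <- matrix(0, 2, ncol(F))
  new("FactorModel", F = F, L = as.matrix(L), K_input = as.integer(K_input),
      alpha = 0, lambda = 0, objective_trace = numeric(0),
      converged = TRUE, seed = 1L)
}

# Independent step-up BH oracle (hand formula, not p.adjust).
bhOracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

# Explicit normal-equations WLS oracle with weights (1/se)^2.
wlsOracle <- function(F, x, se) {
  w <- 1 / se^2
  A <- t(F) %*% (F * w)
  b <- t(F) %*% (w * x)
  drop(solve(A, b))
}

# Grid-search minimizer of a 1-D objective over [-5, 5] step 1e-4.
gridSearch1d <- function(obj, lower = -5, upper = 5, step = 1e-4) {
  grid <- seq(lower, upper, by = step)
  grid[which.min(vapply(grid, obj, 0))]
}
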