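#' Derive a reproducible sub-stream seed from a root seed
#'
#' All randomized stages derive their seeds from one root seed plus a named
#' stream and an index, so repeated runs (consensus fits, background
#' sampling, simulations) are independent yet fully reproducible.
#'
#' @param root integer root seed.
#' @param stream character stream name (e.g. "fit", "sim", "background").
#' @param index integer within-stream index.
#' @return an integer in [1, 2^31 - 2].
#' @export
deriveSeed <- function(root, stream = "main", index = 0L) {
  M <- 2147483647  # 2^31 - 1, Mersenne prime
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream))) %% M
  s <- ((abs(as.numeric(root)) %% M) * 48271 + h * 97 + as.numeric(index)) %% M
  as.integer(s %% (M - 2) + 1)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard BH with monotonicity enforcement, preserving input order.
#' `NA`/`NaN` entries stay `NA` and are excluded from the number of tests.
#'
#' @param pvals numeric vector of p-values in [0, 1] (NA allowed).
#' @return q-values, same length and order.
#' @examples
#' bhAdjust(c(0.005, 0.05, 0.5))  # 0.015 0.075 0.500
#' @export
bhAdjust <- function(pvals) {
  q <- rep(NA_real_, length(pvals))
  ok <- !is.na(pvals)
  if (any(pvals[ok] < 0 | pvals[ok] > 1)) stop("p-values must lie in [0, 1]")
  q[ok] <- stats::p.adjust(pvals[ok], method = "BH")
  q
}

frobenius <- function(m) sqrt(sum(m^2))

#' Relative root mean squared error
#'
#' \deqn{RRMSE(\hat X, X) = \sqrt{\sum_{ij}(\hat X_{ij} - X_{ij})^2 / \sum_{ij} X_{ij}^2}}
#'
#' @param X_hat,X matrices of identical shape; `X` must not be all zero.
#' @return nonnegative scalar; 0 for a perfect reconstruction, 1 for the
#'   all-zero reconstruction.
#' @export
rrmse <- function(X_hat, X) {
  if (!all(dim(X_hat) == dim(X))) stop("shape mismatch")
  denom <- sum(X^2)
  if (denom == 0) stop("reference matrix is all zero")
  sqrt(sum((X_hat - X)^2) / denom)
}
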