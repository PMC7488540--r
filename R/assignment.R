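#' Collapse perfect-LD variant groups before factor assignment
#'
#' Within each gene, variants connected (transitively) by r² = 1 edges form
#' one group; only the group representative (smallest variant id) is carried
#' into the regression, and its q-values are later propagated back to the
#' other members with [propagateQValues()]. Variants without LD information
#' form singleton groups; the r² threshold is strictly 1.
#'
#' @param eqtl_ids character vector of `gene:variant` keys.
#' @param ld data.frame with columns `variant_a`, `variant_b`, `r2`
#'   (see [readLdTable()]).
#' @return list with `representatives` (character vector of kept keys) and
#'   `groups` (named list: representative key -> member keys).
#' @export
prunePerfectLd <- function(eqtl_ids, ld) {
  parts <- strsplit(eqtl_ids, ":", fixed = TRUE)
  gene <- vapply(parts, `[`, "", 1L)
  variant <- vapply(parts, function(x) paste(x[-1], collapse = ":"), "")
  groups <- list()
  for (g in unique(gene)) {
    vs <- variant[gene == g]
    edges <- ld[ld$r2 == 1 & ld$variant_a %in% vs & ld$variant_b %in% vs, , drop = FALSE]
    gr <- igraph::graph_from_data_frame(
      d = edges[, c("variant_a", "variant_b"), drop = FALSE],
      directed = FALSE, vertices = data.frame(name = vs))
    comp <- igraph::components(gr)$membership
    for (cid in unique(comp)) {
      members <- sort(names(comp)[comp == cid])
      rep_key <- paste(g, members[1], sep = ":")
      groups[[rep_key]] <- paste(g, members, sep = ":")
    }
  }
  list(representatives = names(groups), groups = groups)
}

#' Assign an eQTL set to learned factors by weighted linear regression
#'
#' For every eQTL, fits x = F l by weighted least squares over its observed
#' tissues, with weight (1/se)² in the normal equations — the same weighting
#' convention as the factorization objective. Coefficient covariance is
#' \eqn{\hat\sigma^2 (F^\top W^2 F)^{-1}} with
#' \eqn{\hat\sigma^2 = \mathrm{weighted\ RSS}/(T_{obs} - K)}; two-sided
#' t-tests give per-factor p-values, and one Benjamini-Hochberg family over
#' all (eQTL, factor) tests gives q-values. eQTLs with fewer than K + 1
#' observed tissues are untestable and returned with NA statistics; a
#' singular design marks the aliased coefficients `collinear_na` while the
#' rest are fitted on the reduced design.
#'
#' @param effects a [MultiTissueEffects-class] (rows to assign).
#' @param F the learned T x K nonnegative factor matrix.
#' @return data.frame with one row per (eQTL, factor): `eqtl_id`, `factor`,
#'   `coef`, `coef_se`, `t`, `p`, `q`, `df`, `testable`, `collinear`.
#' @export
assignFactors <- function(effects, F) {
  X <- effectSizes(effects); SE <- standardErrors(effects)
  obs <- observedMask(effects)
  K <- ncol(F)
  fnames <- colnames(F)
  if (is.null(fnames)) fnames <- paste0("Factor", seq_len(K))
  out <- vector("list", nrow(X))
  for (d in seq_len(nrow(X))) {
    o <- obs[d, ]
    n <- sum(o)
    row <- data.frame(eqtl_id = rownames(X)[d], factor = fnames,
                      coef = NA_real_, coef_se = NA_real_, t = NA_real_,
                      p = NA_real_, q = NA_real_, df = NA_integer_,
                      testable = n >= K + 1, collinear = FALSE,
                      stringsAsFactors = FALSE)
    if (n >= K + 1) {
      Fo <- F[o, , drop = FALSE]
      y <- X[d, o]
      w <- 1 / SE[d, o]^2
      fit <- stats::lm.wfit(Fo, y, w)
      r <- fit$rank
      df <- n - r
      coefs <- fit$coefficients                       # NA for aliased columns
      if (df >= 1) {
        sigma2 <- sum(w * fit$residuals^2) / df
        R <- qr.R(fit$qr)[seq_len(r), seq_len(r), drop = FALSE]
        cov_unscaled <- chol2inv(R)
        piv <- fit$qr$pivot[seq_len(r)]
        ses <- rep(NA_real_, K)
        ses[piv] <- sqrt(sigma2 * diag(cov_unscaled))
        row$coef <- coefs
        row$coef_se <- ses
        row$t <- coefs / ses
        row$p <- 2 * stats::pt(-abs(row$t), df)
        row$df <- df
      }
      row$collinear <- is.na(coefs)
      row$testable <- df >= 1
    }
    out[[d]] <- row
  }
  res <- do.call(rbind, out)
  res$q <- bhAdjust(res$p)
  rownames(res) <- NULL
  res
}

#' Drop factors whose coefficients contradict the observed effects
#'
#' Two filters applied to each eQTL's significant factors (q < `fdr`):
#' \enumerate{
#'   \item \strong{sign_mismatch}: a factor is dropped when the sign of its
#'     coefficient differs from the sign of the weighted mean (weights
#'     F[t,k]/se_t) of the partial observed effects over the factor's support
#'     tissues — the observed effects minus the fitted contribution of every
#'     other factor — a symptom of collinearity between factors. Raw rather
#'     than partial effects would flag eQTLs whose several true factors
#'     legitimately pull in opposite directions.
#'   \item \strong{opposite_small_z}: relative to the significant factor with
#'     the strongest effect (largest |t|), an oppositely signed significant
#'     factor is dropped when every one of its observed support tissues has
#'     |Z| < 3 (per-tissue Z = x/se; equivalently nominal p > 0.00135),
#'     since such opposite effects more often reflect allelic heterogeneity
#'     or LD contamination than a true flip.
#' }
#'
#' @param assignments data.frame from [assignFactors()].
#' @param effects the same [MultiTissueEffects-class] used for assignment.
#' @param F the factor matrix used for assignment.
#' @param fdr significance threshold on q (default 0.05).
#' @return `assignments` with added columns `kept` (logical) and
#'   `drop_reason` in none/fdr/sign_mismatch/opposite_small_z/collinear_na.
#' @export
filterDiscrepantFactors <- function(assignments, effects, F, fdr = 0.05) {
  X <- effectSizes(effects); SE <- standardErrors(effects)
  obs <- observedMask(effects)
  a <- assignments
  a$kept <- !is.na(a$q) & a$q < fdr
  a$drop_reason <- ifelse(a$collinear, "collinear_na",
                          ifelse(a$kept, "none", "fdr"))
  fmap <- match(a$factor, colnames(F))
  for (id in unique(a$eqtl_id)) {
    rows <- which(a$eqtl_id == id & a$kept)
    if (!length(rows)) next
    d <- match(id, rownames(X))
    o <- obs[d, ]
    # (a) sign mismatch: the coefficient's sign must agree with the observed
    # effects over the factor's support tissues once the other factors'
    # fitted contributions are removed (raw effects would penalize genuine
    # multi-factor superposition rather than collinearity artifacts)
    all_rows <- which(a$eqtl_id == id & !is.na(a$coef))
    for (i in rows) {
      k <- fmap[i]
      supp <- o & F[, k] > 0
      if (!any(supp)) next
      other <- setdiff(all_rows, i)
      fitted_other <- if (length(other))
        F[supp, fmap[other], drop = FALSE] %*% a$coef[other] else 0
      partial <- X[d, supp] - fitted_other
      wm <- sum(F[supp, k] / SE[d, supp] * partial) /
            sum(F[supp, k] / SE[d, supp])
      if (sign(a$coef[i]) != sign(wm) && wm != 0) {
        a$kept[i] <- FALSE
        a$drop_reason[i] <- "sign_mismatch"
      }
    }
    # (b) opposite sign with uniformly weak support, vs the strongest factor
    rows <- which(a$eqtl_id == id & a$kept)
    if (length(rows) < 2) next
    star <- rows[which.max(abs(a$t[rows]))]
    for (i in setdiff(rows, star)) {
      if (sign(a$coef[i]) == sign(a$coef[star])) next
      k <- fmap[i]
      supp <- o & F[, k] > 0
      if (!any(supp)) next
      z <- X[d, supp] / SE[d, supp]
      if (all(abs(z) < 3)) {
        a$kept[i] <- FALSE
        a$drop_reason[i] <- "opposite_small_z"
      }
    }
  }
  a
}

#' Detect the ubiquitous factor in a factor matrix
#'
#' The ubiquitous factor is the one active in every tissue (all entries
#' positive); when several qualify, the one with minimal coefficient of
#' variation across tissues (the flattest pattern) is used.
#'
#' @param F T x K nonnegative factor matrix.
#' @return integer column index, or NA when no factor has full support.
#' @export
ubiquitousFactor <- function(F) {
  full <- which(colSums(F > 0) == nrow(F))
  if (!length(full)) return(NA_integer_)
  if (length(full) == 1) return(full)
  cv <- apply(F[, full, drop = FALSE], 2, function(f) stats::sd(f) / mean(f))
  full[which.min(cv)]
}

#' Label eQTLs as ubiquitous and/or tissue-specific
#'
#' An eQTL is a u-eQTL when the ubiquitous factor is among its kept factors,
#' and a ts-eQTL for every kept non-ubiquitous factor; the two labels can
#' co-occur. When no factor spans all tissues the ubiquitous label is
#' disabled (warning) and every kept factor counts as tissue-specific.
#'
#' @param assignments filtered data.frame from [filterDiscrepantFactors()].
#' @param F the factor matrix (used to find the ubiquitous factor).
#' @param ubiquitous optional explicit ubiquitous factor index.
#' @return data.frame with one row per eQTL: `eqtl_id`, `u_eqtl` (logical),
#'   `ts_factors` (comma-separated factor names, "" when none), `n_kept`.
#' @export
classifyEqtls <- function(assignments, F, ubiquitous = NULL) {
  if (is.null(ubiquitous)) ubiquitous <- ubiquitousFactor(F)
  if (is.na(ubiquitous)) {
    warning("no factor has full tissue support; ubiquitous label disabled")
    u_name <- NA_character_
  } else {
    u_name <- colnames(F)[ubiquitous]
    if (is.null(u_name)) u_name <- paste0("Factor", ubiquitous)
  }
  ids <- unique(assignments$eqtl_id)
  res <- data.frame(eqtl_id = ids, u_eqtl = FALSE, ts_factors = "",
                    n_kept = 0L, stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    kept <- assignments$factor[assignments$eqtl_id == ids[i] & assignments$kept]
    res$n_kept[i] <- length(kept)
    if (!is.na(u_name)) {
      res$u_eqtl[i] <- u_name %in% kept
      kept <- setdiff(kept, u_name)
    }
    res$ts_factors[i] <- paste(kept, collapse = ",")
  }
  res
}

#' Propagate a representative's assignment to its perfect-LD group
#'
#' Every non-representative variant inherits its representative's per-factor
#' statistics, flags and labels; only the id differs. Untested
#' representatives yield untested groups.
#'
#' @param groups the `groups` list from [prunePerfectLd()].
#' @param assignments data.frame from [assignFactors()] (optionally filtered),
#'   computed on the representatives.
#' @return expanded assignments covering every group member.
#' @export
propagateQValues <- function(groups, assignments) {
  out <- lapply(names(groups), function(rep_key) {
    block <- assignments[assignments$eqtl_id == rep_key, , drop = FALSE]
    if (!nrow(block)) return(NULL)
    do.call(rbind, lapply(groups[[rep_key]], function(member) {
      b <- block
      b$eqtl_id <- member
      b
    }))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' End-to-end factor assignment for an eQTL set
#'
#' Convenience wrapper: perfect-LD pruning, weighted regression on the
#' representatives, BH correction, discrepancy filtering, propagation back
#' to LD-group members, and u-/ts- classification.
#'
#' @inheritParams assignFactors
#' @param ld optional LD table (see [readLdTable()]); `NULL` means singleton
#'   groups.
#' @param fdr significance threshold (default 0.05).
#' @param ubiquitous optional explicit ubiquitous factor index, forwarded to
#'   [classifyEqtls()]; by default detected with [ubiquitousFactor()].
#' @return list with `assignments` (per eQTL x factor) and `labels`
#'   (per eQTL, from [classifyEqtls()]).
#' @export
mapEqtlsToFactors <- function(effects, F, ld = NULL, fdr = 0.05,
                              ubiquitous = NULL) {
  ids <- eqtlIds(effects)
  if (is.null(ld))
    ld <- data.frame(variant_a = character(0), variant_b = character(0),
                     r2 = numeric(0))
  pruned <- prunePerfectLd(ids, ld)
  reps <- effects[match(pruned$representatives, ids), ]
  asg <- assignFactors(reps, F)
  asg <- filterDiscrepantFactors(asg, reps, F, fdr = fdr)
  full <- propagateQValues(pruned$groups, asg)
  labels <- classifyEqtls(full, F, ubiquitous = ubiquitous)
  list(assignments = full, labels = labels)
}
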