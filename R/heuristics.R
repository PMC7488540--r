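#' Threshold-based baseline: single-tissue specific and ubiquitous eQTLs
#'
#' For a universe of `T` tissues, a variant is a tissue-specific eQTL in
#' tissue t when (1) its nominal p-value exceeds 0.001 in at least `T - 5`
#' other tissues, (2) its p-value in t is below 100 times the most extreme
#' p-value of its gene in t, and (3) it belongs to the 95% credible set for
#' t. It is a ubiquitous eQTL when it belongs to credible sets in at least 5
#' tissues. Untested tissues shrink requirement and tally together (a
#' missing test is not evidence of a weak effect), so the quiet requirement
#' in (1) is `T - 5` minus the number of untested other tissues.
#'
#' @param variants long-format data.frame with columns `gene_id`,
#'   `variant_id`, `tissue`, `pval`, `in_credible_set` — one row per tested
#'   gene-variant-tissue. The per-gene most extreme p-value in each tissue is
#'   computed from this table.
#' @param tissue_ids the full tissue universe (defines `T`).
#' @param quiet_p p-value above which a tissue counts as quiet (default 0.001).
#' @param fold strength multiplier against the gene's most extreme p
#'   (default 100).
#' @param min_credible_tissues credible-set tissue count for the ubiquitous
#'   call (default 5).
#' @return list with `ts` (data.frame `gene_id`, `variant_id`, `tissue`) and
#'   `u` (data.frame `gene_id`, `variant_id`).
#' @export
heuristic1Classify <- function(variants, tissue_ids, quiet_p = 0.001,
                               fold = 100, min_credible_tissues = 5) {
  stopifnot(all(c("gene_id", "variant_id", "tissue", "pval",
                  "in_credible_set") %in% names(variants)))
  T <- length(tissue_ids)
  key <- paste(variants$gene_id, variants$variant_id, sep = ":")
  gene_tissue_min <- tapply(variants$pval,
                            paste(variants$gene_id, variants$tissue, sep = "\r"),
                            min)
  ts <- list(); u <- list()
  for (k in unique(key)) {
    rows <- variants[key == k, , drop = FALSE]
    gene <- rows$gene_id[1]; var <- rows$variant_id[1]
    if (sum(rows$in_credible_set) >= min_credible_tissues)
      u[[k]] <- data.frame(gene_id = gene, variant_id = var,
                           stringsAsFactors = FALSE)
    tested <- rows$tissue
    for (i in seq_len(nrow(rows))) {
      t <- rows$tissue[i]
      if (!rows$in_credible_set[i]) next
      others <- rows[rows$tissue != t, , drop = FALSE]
      untested_others <- (T - 1) - nrow(others)
      quiet <- sum(others$pval > quiet_p)
      if (quiet < (T - min_credible_tissues) - untested_others) next
      minp <- gene_tissue_min[[paste(gene, t, sep = "\r")]]
      if (rows$pval[i] < fold * minp)
        ts[[paste(k, t)]] <- data.frame(gene_id = gene, variant_id = var,
                                        tissue = t, stringsAsFactors = FALSE)
    }
  }
  list(ts = if (length(ts)) do.call(rbind, c(ts, make.row.names = FALSE)) else
         data.frame(gene_id = character(0), variant_id = character(0),
                    tissue = character(0)),
       u = if (length(u)) do.call(rbind, c(u, make.row.names = FALSE)) else
         data.frame(gene_id = character(0), variant_id = character(0)))
}

#' Threshold-based baseline over predefined tissue subsets
#'
#' Generalizes the single-tissue heuristic to disjoint subsets of similar
#' tissues. For a subset S of size N, a variant is subset-specific when its
#' p-value exceeds 0.001 in at least `T - N - 5` tissues outside S (untested
#' tissues shrink the requirement) and it shows a strong signal — p below 100
#' times the gene's most extreme p in that tissue — in at least half
#' (ceiling) of the subset's tissues. It is ubiquitous when it holds
#' credible-set membership in tissues of at least 5 distinct subsets.
#'
#' @inheritParams heuristic1Classify
#' @param groups data.frame with columns `subset_name`, `tissue`; subsets
#'   must be disjoint.
#' @param min_subsets subsets-with-support count for the ubiquitous call.
#' @return list with `ts` (data.frame `gene_id`, `variant_id`, `subset`) and
#'   `u` (data.frame `gene_id`, `variant_id`).
#' @export
heuristic2Classify <- function(variants, tissue_ids, groups, quiet_p = 0.001,
                               fold = 100, min_subsets = 5) {
  stopifnot(all(c("subset_name", "tissue") %in% names(groups)))
  if (anyDuplicated(groups$tissue))
    stop("tissue subsets must be disjoint")
  T <- length(tissue_ids)
  key <- paste(variants$gene_id, variants$variant_id, sep = ":")
  gene_tissue_min <- tapply(variants$pval,
                            paste(variants$gene_id, variants$tissue, sep = "\r"),
                            min)
  subsets <- split(groups$tissue, groups$subset_name)
  ts <- list(); u <- list()
  for (k in unique(key)) {
    rows <- variants[key == k, , drop = FALSE]
    gene <- rows$gene_id[1]; var <- rows$variant_id[1]
    cred_tissues <- rows$tissue[rows$in_credible_set]
    n_support <- sum(vapply(subsets, function(s) any(cred_tissues %in% s), TRUE))
    if (n_support >= min_subsets)
      u[[k]] <- data.frame(gene_id = gene, variant_id = var,
                           stringsAsFactors = FALSE)
    for (sname in names(subsets)) {
      s <- subsets[[sname]]
      N <- length(s)
      outside <- rows[!(rows$tissue %in% s), , drop = FALSE]
      untested_outside <- (T - N) - nrow(outside)
      quiet <- sum(outside$pval > quiet_p)
      if (quiet < (T - N - min_subsets) - untested_outside) next
      inside <- rows[rows$tissue %in% s, , drop = FALSE]
      if (!nrow(inside)) next
      strong <- sum(vapply(seq_len(nrow(inside)), function(i) {
        minp <- gene_tissue_min[[paste(gene, inside$tissue[i], sep = "\r")]]
        inside$pval[i] < fold * minp
      }, TRUE))
      if (strong >= ceiling(N / 2))
        ts[[paste(k, sname)]] <- data.frame(gene_id = gene, variant_id = var,
                                            subset = sname,
                                            stringsAsFactors = FALSE)
    }
  }
  list(ts = if (length(ts)) do.call(rbind, c(ts, make.row.names = FALSE)) else
         data.frame(gene_id = character(0), variant_id = character(0),
                    subset = character(0)),
       u = if (length(u)) do.call(rbind, c(u, make.row.names = FALSE)) else
         data.frame(gene_id = character(0), variant_id = character(0)))
}
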