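#' Sample background variants matched on MAF, TSS distance and SNPs per gene
#'
#' Stratified sampling without replacement from a pool of candidate variants,
#' matching each focal variant's stratum: MAF bins of width 0.05 over
#' (0, 0.5], signed log10-decade bins of TSS distance, and per-gene SNP count
#' (exact up to 10, then 11-20 / 21-50 / >50). When a stratum is exhausted
#' the nearest stratum (smallest L1 distance on bin indices) is used and the
#' relaxation is counted.
#'
#' @param focal,pool data.frames with columns `variant_id`, `gene_id`, `maf`,
#'   `tss_distance`; the pool must not contain the focal records.
#' @param n_per background variants drawn per focal variant (default 1).
#' @param seed integer seed.
#' @return list with `background` (sampled rows of `pool`) and `relaxations`
#'   (number of draws that needed a neighboring stratum).
#' @export
sampleMatchedBackground <- function(focal, pool, n_per = 1L, seed = 1L) {
  stopifnot(all(c("variant_id", "gene_id", "maf", "tss_distance") %in% names(focal)),
            all(c("variant_id", "gene_id", "maf", "tss_distance") %in% names(pool)))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  bins <- function(df) {
    snp_per_gene <- table(df$gene_id)[df$gene_id]
    cbind(maf = pmin(floor(df$maf / 0.05), 9),
          tss_sign = sign(df$tss_distance),
          tss_decade = ifelse(abs(df$tss_distance) < 1, 0,
                              floor(log10(abs(df$tss_distance)))),
          snps = ifelse(snp_per_gene <= 10, snp_per_gene,
                        ifelse(snp_per_gene <= 20, 15,
                               ifelse(snp_per_gene <= 50, 35, 75))))
  }
  fb <- bins(focal); pb <- bins(pool)
  available <- rep(TRUE, nrow(pool))
  picked <- integer(0); relaxations <- 0L
  for (i in seq_len(nrow(focal))) {
    for (r in seq_len(n_per)) {
      dist <- rowSums(abs(sweep(pb, 2, fb[i, ])))
      dist[!available] <- Inf
      if (!any(is.finite(dist))) stop("background pool exhausted")
      best <- min(dist)
      if (best > 0) relaxations <- relaxations + 1L
      cand <- which(dist == best)
      j <- if (length(cand) == 1) cand else sample(cand, 1)
      picked <- c(picked, j)
      available[j] <- FALSE
    }
  }
  list(background = pool[picked, , drop = FALSE], relaxations = relaxations)
}

#' Flag variants whose centered window overlaps annotation intervals
#'
#' Builds a `window_bp`-wide closed window centered on each 1-based variant
#' position (5 bp means positions pos-2 .. pos+2) and intersects it with the
#' annotation ranges, optionally restricted to one tissue.
#'
#' @param variants data.frame with columns `chrom`, `pos` (1-based).
#' @param intervals a `GRanges` from [readBed()] with optional `tissue`
#'   metadata.
#' @param window_bp odd window width (default 5).
#' @param tissue optional tissue filter; `NULL` keeps all intervals.
#' @param label optional annotation-label filter on the `label` metadata.
#' @return logical vector, one flag per variant.
#' @export
windowOverlap <- function(variants, intervals, window_bp = 5,
                          tissue = NULL, label = NULL) {
  if (window_bp %% 2 != 1) stop("window_bp must be odd")
  if (!is.null(tissue))
    intervals <- intervals[!is.na(S4Vectors::mcols(intervals)$tissue) &
                             S4Vectors::mcols(intervals)$tissue == tissue]
  if (!is.null(label))
    intervals <- intervals[!is.na(S4Vectors::mcols(intervals)$label) &
                             S4Vectors::mcols(intervals)$label == label]
  half <- (window_bp - 1) / 2
  win <- GenomicRanges::GRanges(variants$chrom,
                                IRanges::IRanges(start = pmax(1, variants$pos - half),
                                                 end = variants$pos + half))
  GenomicRanges::countOverlaps(win, intervals) > 0
}

#' Fisher's exact test on a 2x2 table by hypergeometric enumeration
#'
#' The p-value is computed by exact enumeration over all tables with the
#' observed margins: for `alternative = "greater"`, the upper tail of the
#' hypergeometric distribution at the observed top-left cell; for
#' `two_sided`, the sum of the probabilities of all tables no more likely
#' than the observed one. The odds ratio is the sample estimate
#' \eqn{ad/bc}, with the Haldane 0.5 correction applied to every cell when
#' any cell is zero (the p-value is never corrected).
#'
#' @param table 2x2 nonnegative integer matrix: row 1 = focal set, row 2 =
#'   background; column 1 = in annotation.
#' @param alternative "greater" (enrichment) or "two_sided".
#' @return list with `odds_ratio` and `p` (`p = 1`, `odds_ratio = NaN` on a
#'   zero margin).
#' @export
fisherExact <- function(table, alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0),
            all(table == round(table)))
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  m <- a + b; n <- c + d; k <- a + c
  if (m == 0 || n == 0 || k == 0 || b + d == 0)
    return(list(odds_ratio = NaN, p = 1))
  or <- if (any(table == 0)) ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
        else (a * d) / (b * c)
  lo <- max(0, k - n); hi <- min(k, m)
  support <- lo:hi
  probs <- stats::dhyper(support, m, n, k)
  p <- if (alternative == "greater") {
    sum(probs[support >= a])
  } else {
    p_obs <- probs[support == a]
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  list(odds_ratio = or, p = min(1, p))
}

#' Chromatin-state enrichment of factor variants over matched background
#'
#' For every (state label, tissue) pair present in the annotation (optionally
#' restricted), counts focal and background variants whose 5-bp windows
#' overlap the state's intervals, forms the 2x2 table, and applies the
#' one-sided (greater) Fisher test; all tables produced in the run form one
#' Benjamini-Hochberg family.
#'
#' @param focal,background data.frames with `chrom`, `pos` columns (1-based).
#' @param states a `GRanges` from [readBed()] with `label` and `tissue`.
#' @param tissues optional subset of tissues to test; default all in `states`.
#' @param factor_name provenance string stored in the output.
#' @param window_bp window width for [windowOverlap()] (default 5).
#' @return data.frame: `factor`, `label`, `tissue`, `a`, `b`, `c`, `d`,
#'   `odds_ratio`, `p`, `q`.
#' @export
chromatinStateEnrichment <- function(focal, background, states, tissues = NULL,
                                     factor_name = NA_character_, window_bp = 5) {
  mc <- S4Vectors::mcols(states)
  combos <- unique(data.frame(label = mc$label, tissue = mc$tissue,
                              stringsAsFactors = FALSE))
  if (!is.null(tissues)) combos <- combos[combos$tissue %in% tissues, , drop = FALSE]
  if (!nrow(combos)) stop("no (state, tissue) combinations to test")
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    inf <- windowOverlap(focal, states, window_bp,
                         tissue = combos$tissue[i], label = combos$label[i])
    inb <- windowOverlap(background, states, window_bp,
                         tissue = combos$tissue[i], label = combos$label[i])
    tab <- matrix(c(sum(inf), sum(inb), sum(!inf), sum(!inb)), 2, 2)
    ft <- fisherExact(tab, "greater")
    data.frame(factor = factor_name, label = combos$label[i],
               tissue = combos$tissue[i],
               a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
               odds_ratio = ft$odds_ratio, p = ft$p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$q <- bhAdjust(res$p)
  res
}

#' Gene-level transcription-factor binding-site enrichment
#'
#' For each transcription factor, counts genes in the focal and background
#' sets that carry at least one qualifying variant inside the TF's binding
#' sites, forms the gene-level 2x2 table, and applies the one-sided Fisher
#' test with one BH family across TFs. TFs whose binding sites touch fewer
#' than `min_genes` genes in total are excluded.
#'
#' @param focal_variants,background_variants data.frames with `chrom`, `pos`,
#'   `gene_id`.
#' @param tfbs `GRanges` with a `label` metadata column naming the TF
#'   (already intersected upstream with tissue-matched regulatory regions).
#' @param min_genes minimum total genes with TFBS variants per TF (default 10).
#' @param factor_name provenance string.
#' @param window_bp variant window width (default 5).
#' @return data.frame: `factor`, `tf`, `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `p`, `q`.
#' @export
tfbsEnrichment <- function(focal_variants, background_variants, tfbs,
                           min_genes = 10, factor_name = NA_character_,
                           window_bp = 5) {
  tfs <- unique(S4Vectors::mcols(tfbs)$label)
  n_focal_genes <- length(unique(focal_variants$gene_id))
  n_bg_genes <- length(unique(background_variants$gene_id))
  rows <- lapply(tfs, function(tf) {
    hitf <- windowOverlap(focal_variants, tfbs, window_bp, label = tf)
    hitb <- windowOverlap(background_variants, tfbs, window_bp, label = tf)
    gf <- unique(focal_variants$gene_id[hitf])
    gb <- unique(background_variants$gene_id[hitb])
    if (length(unique(c(gf, gb))) < min_genes) return(NULL)
    tab <- matrix(c(length(gf), length(gb),
                    n_focal_genes - length(gf), n_bg_genes - length(gb)), 2, 2)
    ft <- fisherExact(tab, "greater")
    data.frame(factor = factor_name, tf = tf,
               a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
               odds_ratio = ft$odds_ratio, p = ft$p, stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows))
    return(data.frame(factor = character(0), tf = character(0),
                      a = integer(0), b = integer(0), c = integer(0),
                      d = integer(0), odds_ratio = numeric(0),
                      p = numeric(0), q = numeric(0)))
  res <- do.call(rbind, rows)
  res$q <- bhAdjust(res$p)
  res
}

#' Filter transcription factors by expression in a factor's tissues
#'
#' A TF is eligible for a factor when its median TPM exceeds 1 in at least
#' half (ceiling) of the factor's tissues with available expression data; a
#' TF with no available tissue is ineligible.
#'
#' @param tf_tpm numeric matrix of median TPM, TFs x tissues (NA = no data).
#' @param factor_tissues character vector of the factor's tissue names.
#' @param tpm_threshold expression cutoff (default 1).
#' @return character vector of eligible TF names.
#' @export
filterExpressedTfs <- function(tf_tpm, factor_tissues, tpm_threshold = 1) {
  cols <- intersect(factor_tissues, colnames(tf_tpm))
  sub <- tf_tpm[, cols, drop = FALSE]
  eligible <- vapply(rownames(sub), function(tf) {
    v <- sub[tf, ]
    avail <- !is.na(v)
    if (!any(avail)) return(FALSE)
    sum(v[avail] > tpm_threshold) >= ceiling(sum(avail) / 2)
  }, TRUE)
  rownames(sub)[eligible]
}

#' Combine log odds ratios with a DerSimonian-Laird random-effects model
#'
#' Computes the method-of-moments heterogeneity variance
#' \eqn{\tau^2 = \max(0, (Q - df)/(\sum w - \sum w^2/\sum w))} from the
#' fixed-effect Cochran Q, re-weights each study by
#' \eqn{w^*_i = 1/(se_i^2 + \tau^2)}, and returns the combined estimate and
#' its standard error on both the log and the odds-ratio scale.
#'
#' @param log_ors numeric vector of per-study log odds ratios.
#' @param ses positive per-study standard errors of the log odds ratios.
#' @return list: `combined_log_or`, `combined_se`, `tau2`, `combined_or`.
#' @export
randomEffectsCombine <- function(log_ors, ses) {
  stopifnot(length(log_ors) == length(ses), all(ses > 0))
  n <- length(log_ors)
  if (n == 1)
    return(list(combined_log_or = log_ors, combined_se = ses, tau2 = 0,
                combined_or = exp(log_ors)))
  w <- 1 / ses^2
  y_fe <- sum(w * log_ors) / sum(w)
  Q <- sum(w * (log_ors - y_fe)^2)
  tau2 <- max(0, (Q - (n - 1)) / (sum(w) - sum(w^2) / sum(w)))
  ws <- 1 / (ses^2 + tau2)
  est <- sum(ws * log_ors) / sum(ws)
  se <- 1 / sqrt(sum(ws))
  list(combined_log_or = est, combined_se = se, tau2 = tau2,
       combined_or = exp(est))
}

#' Allele-specific binding test on ChIP-seq read counts
#'
#' Each variant covered by more than 10 reads is tested for allelic
#' imbalance with a two-tailed exact binomial test at success probability
#' 0.5; significance across the batch is decided by Benjamini-Hochberg at
#' `fdr`. Variants with 10 or fewer reads are returned untested.
#'
#' @param counts data.frame with columns `variant_id`, `ref_reads`,
#'   `alt_reads` (nonnegative integers).
#' @param fdr FDR threshold for the `significant` call (default 0.05).
#' @param min_reads read-depth threshold; tested means strictly more reads
#'   than this (default 10).
#' @return data.frame: `variant_id`, `ref_reads`, `alt_reads`, `tested`,
#'   `p`, `q`, `significant`.
#' @export
asbBinomialTest <- function(counts, fdr = 0.05, min_reads = 10) {
  stopifnot(all(c("variant_id", "ref_reads", "alt_reads") %in% names(counts)),
            all(counts$ref_reads >= 0), all(counts$alt_reads >= 0))
  total <- counts$ref_reads + counts$alt_reads
  tested <- total > min_reads
  p <- rep(NA_real_, nrow(counts))
  p[tested] <- vapply(which(tested), function(i)
    stats::binom.test(counts$ref_reads[i], total[i], p = 0.5,
                      alternative = "two.sided")$p.value, 0)
  q <- bhAdjust(p)
  data.frame(variant_id = counts$variant_id, ref_reads = counts$ref_reads,
             alt_reads = counts$alt_reads, tested = tested, p = p, q = q,
             significant = !is.na(q) & q < fdr, stringsAsFactors = FALSE)
}
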