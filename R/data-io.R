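#' Load per-tissue eQTL summary statistics into a MultiTissueEffects object
#'
#' Each tissue contributes one tab-separated file with header columns
#' `gene_id`, `variant_id`, `slope`, `slope_se`, `pval_nominal` (extra columns
#' are ignored). The union of gene:variant keys across tissues forms the rows;
#' entries absent from a tissue's file are marked unobserved and receive
#' weight zero.
#'
#' @param paths character vector of file paths, one per tissue.
#' @param tissue_ids tissue names, same length/order as `paths`.
#' @return A [MultiTissueEffects-class] object.
#' @export
loadSummaryStats <- function(paths, tissue_ids) {
  stopifnot(length(paths) == length(tissue_ids))
  tabs <- lapply(seq_along(paths), function(i) {
    tab <- utils::read.table(paths[i], header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("gene_id", "variant_id", "slope", "slope_se", "pval_nominal")
    miss <- setdiff(need, names(tab))
    if (length(miss))
      stop(sprintf("'%s' lacks required columns: %s", paths[i],
                   paste(miss, collapse = ", ")))
    key <- paste(tab$gene_id, tab$variant_id, sep = ":")
    if (anyDuplicated(key))
      stop(sprintf("duplicate (gene, variant) rows in '%s': %s", paths[i],
                   key[duplicated(key)][1]))
    bad <- !is.finite(tab$slope_se) | tab$slope_se <= 0
    if (any(bad))
      stop(sprintf("non-positive or non-finite SE in '%s' for %s",
                   paths[i], key[bad][1]))
    data.frame(key = key, slope = tab$slope, slope_se = tab$slope_se,
               stringsAsFactors = FALSE)
  })
  keys <- sort(unique(unlist(lapply(tabs, `[[`, "key"))))
  D <- length(keys); T <- length(tissue_ids)
  X <- matrix(NA_real_, D, T, dimnames = list(keys, tissue_ids))
  SE <- X
  for (i in seq_along(tabs)) {
    idx <- match(tabs[[i]]$key, keys)
    X[idx, i] <- tabs[[i]]$slope
    SE[idx, i] <- tabs[[i]]$slope_se
  }
  multiTissueEffects(X, SE, observed = !is.na(X))
}

#' Select one lead variant per gene by geometric-mean p-value
#'
#' Within each gene's credible-set candidates, picks the variant with the most
#' extreme (smallest) geometric mean of nominal p-values across the tissues in
#' which it was tested. Ties break to the lexicographically smallest
#' variant id; p-values of exactly zero are floored at 1e-300.
#'
#' @param variants data.frame with columns `gene_id`, `variant_id`, `tissue`,
#'   `pval` (long format; one row per tested gene-variant-tissue).
#' @return character vector of `gene:variant` keys, one per gene with at
#'   least one candidate.
#' @export
selectLeadVariants <- function(variants) {
  stopifnot(all(c("gene_id", "variant_id", "tissue", "pval") %in% names(variants)))
  variants <- variants[!is.na(variants$pval), , drop = FALSE]
  if (!nrow(variants)) return(character(0))
  p <- pmax(variants$pval, 1e-300)
  key <- paste(variants$gene_id, variants$variant_id, sep = ":")
  mean_logp <- tapply(log(p), key, mean)      # geometric mean over tested tissues
  kdf <- data.frame(key = names(mean_logp), logp = as.vector(mean_logp),
                    stringsAsFactors = FALSE)
  split_keys <- strsplit(kdf$key, ":", fixed = TRUE)
  kdf$gene <- vapply(split_keys, `[`, "", 1L)
  kdf$variant <- vapply(split_keys, function(x) paste(x[-1], collapse = ":"), "")
  kdf <- kdf[order(kdf$gene, kdf$logp, kdf$variant), , drop = FALSE]
  kdf$key[!duplicated(kdf$gene)]
}

#' Read a BED3+2 annotation file as a GRanges
#'
#' BED coordinates are 0-based half-open; the returned
#' [GenomicRanges::GRanges] uses the 1-based closed convention. Columns 4 and
#' 5, when present, are kept as metadata `label` and `tissue`. Strand is
#' ignored (eQTL variants are strand-free).
#'
#' @param path file path.
#' @return A `GRanges` with metadata columns `label` and `tissue`.
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    return(GenomicRanges::GRanges(label = character(0), tissue = character(0)))
  fields <- strsplit(lines, "\t| +")
  n <- vapply(fields, length, 0L)
  if (any(n < 3))
    stop(sprintf("malformed BED line %d in '%s' (fewer than 3 fields)",
                 which(n < 3)[1], path))
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- !is.finite(start) | !is.finite(end)
  if (any(bad))
    stop(sprintf("malformed BED line %d in '%s' (non-numeric coordinates)",
                 which(bad)[1], path))
  if (any(start >= end))
    stop(sprintf("malformed BED line %d in '%s' (start >= end)",
                 which(start >= end)[1], path))
  label <- ifelse(n >= 4, vapply(fields, function(x) x[min(4, length(x))], ""), NA_character_)
  tissue <- ifelse(n >= 5, vapply(fields, function(x) x[min(5, length(x))], ""), NA_character_)
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start + 1, end = end),
                         label = label, tissue = tissue)
}

#' Write a GRanges annotation back to BED3+2
#'
#' @param gr a `GRanges` with optional `label`/`tissue` metadata.
#' @param path output path.
#' @export
writeBed <- function(gr, path) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr) - 1L,
                   end = GenomicRanges::end(gr))
  mc <- S4Vectors::mcols(gr)
  if ("label" %in% names(mc)) df$label <- mc$label
  if ("tissue" %in% names(mc)) df$tissue <- mc$tissue
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Round-trip-exact TSV matrix writer / reader
#'
#' Writes numeric matrices with a leading id column at 17 significant digits
#' so values survive the text round-trip bit-identically.
#'
#' @param m numeric matrix with dimnames.
#' @param path file path.
#' @param id_col name of the leading identifier column.
#' @export
writeMatrixTsv <- function(m, path, id_col = "eqtl_id") {
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("c", seq_len(ncol(m)))
  header <- paste(c(id_col, colnames(m)), collapse = "\t")
  body <- vapply(seq_len(nrow(m)), function(i)
    paste(c(rownames(m)[i], formatC(m[i, ], digits = 17, format = "g")),
          collapse = "\t"), "")
  writeLines(c(header, body), path)
  invisible(path)
}

#' @rdname writeMatrixTsv
#' @return `readMatrixTsv` returns the numeric matrix with row names taken
#'   from the identifier column.
#' @export
readMatrixTsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  m
}

#' Read a pairwise LD table
#'
#' @param path TSV with header columns `variant_a`, `variant_b`, `r2`.
#' @return data.frame with those columns; `r2` validated to lie in [0, 1].
#' @export
readLdTable <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  stopifnot(all(c("variant_a", "variant_b", "r2") %in% names(tab)))
  if (any(tab$r2 < 0 | tab$r2 > 1, na.rm = TRUE))
    stop("r2 values must lie in [0, 1]")
  tab
}
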