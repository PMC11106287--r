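# Integration of regional stain load with bulk RNA-seq counts: expected-read-
# count filtering, median-of-ratios normalization, plain and age-adjusted
# (within-group centered, repeated-measures style) Pearson correlations, FDR
# control, gene categorization, and export of ranked coefficients for gene
# set enrichment.

#' Filter genes on expected read counts
#'
#' Keeps a gene when the fraction of samples with count strictly greater than
#' `min_count` strictly exceeds `min_frac` (the conventional filter: >10 ERCs
#' in more than 50% of samples).
#'
#' @param counts Non-negative integer matrix, genes x samples, with gene ids
#'   as rownames.
#' @param min_count Count threshold (strict).
#' @param min_frac Sample-fraction threshold (strict).
#' @return The filtered count matrix.
#' @export
filter_genes <- function(counts, min_count = 10, min_frac = 0.5) {
  counts <- as.matrix(counts)
  if (!length(counts)) stopf("empty count matrix")
  if (any(counts < 0)) stopf("counts must be non-negative")
  frac <- rowMeans(counts > min_count)
  counts[frac > min_frac, , drop = FALSE]
}

#' Median-of-ratios size factors and normalization
#'
#' Size factors are computed against a per-gene geometric-mean reference over
#' the genes with all-positive counts; the size factor of a sample is the
#' median across those genes of count / reference. Normalized counts are
#' count / size factor; by default they are returned as `log2(normalized + 1)`.
#'
#' @param counts Non-negative matrix, genes x samples (>= 2 samples).
#' @param log Logical; FALSE returns linear normalized counts.
#' @return Matrix of normalized (transformed) values with the size factors in
#'   attribute `size_factors`.
#' @export
normalize_counts <- function(counts, log = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stopf("normalization needs at least 2 samples")
  allpos <- rowSums(counts <= 0) == 0L
  if (!any(allpos)) stopf("no gene with all-positive counts; cannot form reference")
  lgm <- rowMeans(log(counts[allpos, , drop = FALSE]))
  sf <- apply(counts[allpos, , drop = FALSE], 2, function(cj) {
    exp(stats::median(log(cj) - lgm))
  })
  norm <- sweep(counts, 2, sf, "/")
  out <- if (log) log2(norm + 1) else norm
  attr(out, "size_factors") <- sf
  out
}

#' Per-gene Pearson correlation of expression with load
#'
#' Plain Pearson correlation of each gene's (normalized) expression with the
#' per-sample load vector; two-sided p from the t transform with n - 2
#' degrees of freedom. Zero-variance genes get `NA` r, are flagged in the
#' `defined` column, and should be excluded from FDR.
#'
#' @param load Numeric per-sample load vector (variance > 0; length >= 3).
#' @param values Matrix genes x samples of normalized expression.
#' @return Data frame: `gene_id`, `r`, `p`, `n`, `defined`.
#' @export
correlate_load <- function(load, values) {
  values <- as.matrix(values)
  n <- length(load)
  if (ncol(values) != n) stopf("load length and sample count differ")
  if (n < 3L) stopf("correlation needs at least 3 samples")
  if (stats::var(load) <= 0) stopf("load has zero variance")
  xc <- load - mean(load)
  yc <- values - rowMeans(values)
  sy <- sqrt(rowSums(yc^2))
  sx <- sqrt(sum(xc^2))
  r <- as.vector(yc %*% xc) / (sx * sy)
  defined <- is.finite(r) & sy > 0
  r[!defined] <- NA_real_
  df <- n - 2L
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  data.frame(gene_id = rownames(values) %||% as.character(seq_len(nrow(values))),
             r = r, p = p, n = n, defined = defined, row.names = NULL)
}

#' Age-adjusted (within-group centered) correlation of expression with load
#'
#' Repeated-measures-style correlation: load and expression are centered
#' within each age group and the Pearson correlation is computed on the
#' pooled centered values, with the two-sided p from a t transform on
#' `n - k - 1` degrees of freedom (k = number of age groups). For a two-level
#' grouping this matches the random-intercept-per-group mixed-model
#' correlation. Groups with fewer than 2 samples are dropped with a warning.
#'
#' @param load Numeric per-sample load vector.
#' @param values Matrix genes x samples of normalized expression.
#' @param age_group Factor/character vector of per-sample age groups
#'   (conventionally `"6m"` / `"14m"`).
#' @return Data frame: `gene_id`, `r`, `p`, `n`, `k`, `defined`.
#' @export
correlate_load_adjusted <- function(load, values, age_group) {
  values <- as.matrix(values)
  n0 <- length(load)
  if (ncol(values) != n0 || length(age_group) != n0) {
    stopf("load, values and age_group must agree on sample count")
  }
  g <- as.character(age_group)
  sizes <- table(g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning(sprintf("dropping age group(s) with < 2 samples: %s",
                    paste(small, collapse = ", ")), call. = FALSE)
    keep <- !g %in% small
    load <- load[keep]; values <- values[, keep, drop = FALSE]; g <- g[keep]
  }
  if (!length(load)) stopf("all age groups dropped; nothing to correlate")
  k <- length(unique(g))
  n <- length(load)
  df <- n - k - 1L
  if (df < 2L) stopf("not enough samples: n - k - 1 must be >= 2")
  gm_x <- stats::ave(load, g)
  xc <- load - gm_x
  gm_y <- t(apply(values, 1, function(y) stats::ave(y, g)))
  yc <- values - gm_y
  sx <- sqrt(sum(xc^2))
  if (sx <= 0) stopf("load has zero within-group variance")
  sy <- sqrt(rowSums(yc^2))
  r <- as.vector(yc %*% xc) / (sx * sy)
  defined <- is.finite(r) & sy > 0
  r[!defined] <- NA_real_
  tt <- r * sqrt(df / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(abs(tt), df, lower.tail = FALSE)
  data.frame(gene_id = rownames(values) %||% as.character(seq_len(nrow(values))),
             r = r, p = p, n = n, k = k, defined = defined, row.names = NULL)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false discovery rate control; never decreases a p-value and is
#' monotone non-decreasing in the sorted order. `NA` entries are passed
#' through.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values.
#' @export
fdr_adjust <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stopf("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Correlate load with expression, unadjusted and age-adjusted
#'
#' End-to-end convenience wrapper producing one correlation record per gene:
#' plain and age-adjusted r and p, FDR q-values (computed over genes with
#' defined r), and the category assignment from [categorize_correlations()].
#'
#' @param load Per-sample load vector (paired 1:1 with the columns of
#'   `values`).
#' @param values Normalized expression matrix, genes x samples.
#' @param age_group Per-sample age group.
#' @param alpha Significance level for categorization.
#' @return Data frame of correlation records.
#' @export
correlate_expression <- function(load, values, age_group, alpha = 0.05) {
  un <- correlate_load(load, values)
  ad <- correlate_load_adjusted(load, values, age_group)
  rec <- data.frame(gene_id = un$gene_id,
                    r_unadj = un$r, p_unadj = un$p,
                    r_adj = ad$r, p_adj = ad$p,
                    defined = un$defined & ad$defined)
  rec$q_unadj <- NA_real_
  rec$q_adj <- NA_real_
  rec$q_unadj[rec$defined] <- fdr_adjust(rec$p_unadj[rec$defined])
  rec$q_adj[rec$defined] <- fdr_adjust(rec$p_adj[rec$defined])
  categorize_correlations(rec, alpha = alpha)
}

#' Categorize genes by age-dependence of their load correlation
#'
#' A gene significantly correlated (uncorrected p < alpha) only before age
#' adjustment is `age_dependent`; only after adjustment, `age_independent`;
#' under both conditions, `both`; otherwise `neither`. Genes with undefined r
#' in either method are `neither` and flagged. The four category percentages
#' over all tested genes are attached as attribute `category_pct`.
#'
#' @param records Data frame with columns `p_unadj` and `p_adj` (and
#'   optionally `defined`).
#' @param alpha Significance level (default 0.05, uncorrected).
#' @return `records` with a `category` column and `category_pct` attribute.
#' @export
categorize_correlations <- function(records, alpha = 0.05) {
  def <- if ("defined" %in% names(records)) records$defined else
    !is.na(records$p_unadj) & !is.na(records$p_adj)
  sig_u <- records$p_unadj < alpha
  sig_a <- records$p_adj < alpha
  cat <- ifelse(sig_u & sig_a, "both",
                ifelse(sig_u, "age_dependent",
                       ifelse(sig_a, "age_independent", "neither")))
  cat[!def] <- "neither"
  records$category <- cat
  pct <- 100 * vapply(c("age_dependent", "age_independent", "both", "neither"),
                      function(k) mean(cat == k), numeric(1))
  attr(records, "category_pct") <- pct
  records
}

#' Export a ranked coefficient list for gene set enrichment
#'
#' Writes a two-column TSV (gene_id, coefficient) sorted by decreasing
#' coefficient; genes with undefined (NA/NaN) coefficients are omitted. This
#' is the ranked input consumed by GSEA tools; enrichment itself is not
#' computed here.
#'
#' @param records Correlation records.
#' @param by Which coefficient to rank by: `"r_unadj"` or `"r_adj"`.
#' @param path Output TSV path.
#' @export
export_ranking <- function(records, by = c("r_unadj", "r_adj"), path) {
  by <- match.arg(by)
  if (!nrow(records)) stopf("no records to export")
  co <- records[[by]]
  keep <- is.finite(co)
  out <- data.frame(gene_id = records$gene_id[keep], coefficient = co[keep])
  out <- out[order(-out$coefficient), ]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a counts matrix and sample metadata TSV
#'
#' Counts: genes x samples TSV with gene ids in the first column. Metadata:
#' TSV with columns `sample`, `brain`, `age_group`, `strain`.
#'
#' @param path File path.
#' @return `read_counts` returns an integer matrix; `read_sample_meta` a
#'   data frame.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_counts
#' @param counts Integer matrix with gene rownames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_counts
#' @export
read_sample_meta <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
}

#' @rdname read_counts
#' @param meta Sample metadata data frame.
#' @export
write_sample_meta <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
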