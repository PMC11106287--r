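# Regional stain-load quantification: combine refined region maps,
# segmentation masks, and exclusion (hemibrain) masks into per-region,
# per-brain loads; load differences between registration methods; group
# comparisons.
#
# load = 100 * stained_pixels / region_pixels, per atlas region. Background,
# unassigned, and mask-excluded pixels contribute to neither numerator nor
# denominator. Brain-level loads pool pixel counts across retained sections
# (not averages of per-section loads), weighting regions by sampled area.

#' Stain-specific default downscale factors
#'
#' Image downscale factors applied before segmentation, per stain.
#'
#' @format Named numeric vector.
#' @export
STAIN_SCALE_FACTORS <- c("AB1-42" = 0.20, "GFAP" = 0.40, "Iba1" = 0.40,
                         "NeuN" = 0.40, "thionine" = 0.35)

#' Downscale an image by area interpolation
#'
#' Area-weighted (box) resampling: each output pixel averages the input area
#' it covers, so mean intensity is preserved. Output dimensions are
#' `round(dims * factor)`.
#'
#' @param image Numeric matrix (grayscale) or logical mask.
#' @param factor Scale factor in `(0, 1]`; when omitted and `stain` names a
#'   known stain, the stain-specific default from [STAIN_SCALE_FACTORS] is
#'   used.
#' @param stain Optional stain name.
#' @return Numeric matrix of size `round(dim(image) * factor)`.
#' @export
downscale <- function(image, factor = NULL, stain = NULL) {
  if (is.null(factor)) {
    if (is.null(stain) || !stain %in% names(STAIN_SCALE_FACTORS)) {
      stopf("factor missing and stain %s has no default scale factor",
            if (is.null(stain)) "<none>" else stain)
    }
    factor <- STAIN_SCALE_FACTORS[[stain]]
  }
  if (!is.numeric(factor) || factor <= 0) stopf("scale factor must be > 0")
  if (factor > 1) stopf("scale factor must be <= 1 (downscaling only)")
  image <- matrix(as.numeric(image), nrow = nrow(image))
  if (factor == 1) return(image)
  resample_1d <- function(n_in, n_out) {
    # weight matrix n_out x n_in: fraction of input cell covered by output cell
    w <- matrix(0, n_out, n_in)
    step <- n_in / n_out
    for (o in seq_len(n_out)) {
      lo <- (o - 1) * step; hi <- o * step
      cells <- seq.int(floor(lo) + 1L, min(ceiling(hi), n_in))
      ov <- pmin(cells, hi) - pmax(cells - 1, lo)
      w[o, cells] <- ov
    }
    w / rowSums(w)
  }
  n_out_r <- max(1L, round(nrow(image) * factor))
  n_out_c <- max(1L, round(ncol(image) * factor))
  wr <- resample_1d(nrow(image), n_out_r)
  wc <- resample_1d(ncol(image), n_out_c)
  wr %*% image %*% t(wc)
}

#' Threshold segmentation of a grayscale image
#'
#' Minimal intensity-threshold segmenter: the mask is
#' `intensity >= cutoff` (or `<= cutoff` with `invert = TRUE` for
#' dark-on-light stains such as DAB).
#'
#' @param image Numeric matrix of intensities.
#' @param cutoff Threshold.
#' @param invert Logical; TRUE marks pixels at or below the cutoff.
#' @param stain Stain name recorded on the result.
#' @return An object of class `segmentation_image`: list with logical `mask`
#'   and `stain`.
#' @export
threshold_segment <- function(image, cutoff, invert = FALSE, stain = "stain") {
  image <- matrix(as.numeric(image), nrow = nrow(image))
  mask <- if (invert) image <= cutoff else image >= cutoff
  segmentation_image(mask, stain)
}

#' Construct a segmentation image
#'
#' @param mask Logical matrix, TRUE at stain-positive pixels, image-indexed
#'   `[y + 1, x + 1]`.
#' @param stain Stain name (free text; conventional values are NeuN, GFAP,
#'   Iba1, AB1-42, thionine).
#' @return An object of class `segmentation_image`.
#' @export
segmentation_image <- function(mask, stain = "stain") {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  mask <- matrix(as.logical(mask), nrow = nrow(mask))
  structure(list(mask = mask, stain = stain), class = "segmentation_image")
}

#' Per-region pixel counts for one section
#'
#' Tallies region area and stain-positive area per region. Pixels that are
#' background (0), [UNASSIGNED], or excluded by the mask contribute to
#' neither count; regions with zero remaining pixels are absent from the
#' output (no 0/0 rows).
#'
#' @param map A [region_map] (custom granularity for hierarchy-level output).
#' @param seg A [segmentation_image] with matching dimensions.
#' @param exclude Optional logical matrix (TRUE = exclude), e.g. a hemibrain
#'   mask.
#' @return Data frame with columns `region_id`, `region_pixels`,
#'   `stained_pixels`, `load` (percent).
#' @export
section_load <- function(map, seg, exclude = NULL) {
  stopifnot(inherits(map, "region_map"), inherits(seg, "segmentation_image"))
  if (!all(dim(map$labels) == dim(seg$mask))) {
    stopf("dimension mismatch between region map and segmentation")
  }
  keep <- !(map$labels == 0L | map$labels == UNASSIGNED)
  if (!is.null(exclude)) {
    if (!all(dim(exclude) == dim(map$labels))) {
      stopf("dimension mismatch between region map and exclusion mask")
    }
    keep <- keep & !exclude
  }
  labs <- map$labels[keep]
  if (!length(labs)) {
    return(data.frame(region_id = integer(0), region_pixels = integer(0),
                      stained_pixels = integer(0), load = numeric(0)))
  }
  stained <- seg$mask[keep]
  region_pixels <- tapply(rep(1L, length(labs)), labs, sum)
  stained_pixels <- tapply(as.integer(stained), labs, sum)
  ids <- as.integer(names(region_pixels))
  ord <- order(ids)
  data.frame(region_id = ids[ord],
             region_pixels = as.integer(region_pixels)[ord],
             stained_pixels = as.integer(stained_pixels)[ord],
             load = 100 * as.integer(stained_pixels)[ord] /
               as.integer(region_pixels)[ord])
}

#' Pool section counts into per-brain loads
#'
#' Sums region and stained pixel counts over the retained sections of one
#' brain and computes the load from the pooled counts (not the mean of
#' per-section loads), so regions are weighted by sampled area.
#'
#' @param sections List of per-section count data frames from
#'   [section_load()].
#' @param excluded Logical vector marking sections to drop (e.g. the
#'   `excluded` column of damage reports); default keeps all.
#' @param brain,stain Identifiers recorded on the output rows.
#' @return A load table: data frame with columns `brain`, `stain`,
#'   `region_id`, `region_pixels`, `stained_pixels`, `load`.
#' @export
brain_load <- function(sections, excluded = NULL, brain = "", stain = "") {
  if (!length(sections)) stopf("at least one section is required")
  if (is.null(excluded)) excluded <- rep(FALSE, length(sections))
  if (length(excluded) != length(sections)) {
    stopf("excluded flags must match the number of sections")
  }
  kept <- sections[!excluded]
  if (!length(kept)) stopf("all sections excluded; no retained section")
  all_counts <- do.call(rbind, kept)
  region_pixels <- tapply(all_counts$region_pixels, all_counts$region_id, sum)
  stained_pixels <- tapply(all_counts$stained_pixels, all_counts$region_id, sum)
  ids <- as.integer(names(region_pixels))
  ord <- order(ids)
  data.frame(brain = brain, stain = stain,
             region_id = ids[ord],
             region_pixels = as.integer(region_pixels)[ord],
             stained_pixels = as.integer(stained_pixels)[ord],
             load = 100 * as.integer(stained_pixels)[ord] /
               as.integer(region_pixels)[ord])
}

#' Read / write a load report TSV (Nutil-like)
#'
#' Columns: brain, stain, region_id, region_name, region_pixels,
#' stained_pixels, load_pct.
#'
#' @param loads A load table from [brain_load()] (rows from several brains
#'   may be concatenated).
#' @param path File path.
#' @param tree Optional [structure_tree] for region names.
#' @export
write_load_table <- function(loads, path, tree = NULL) {
  nm <- as.character(loads$region_id)
  nm[loads$region_id == UNASSIGNED] <- "Unassigned"
  if (!is.null(tree)) {
    hit <- match(loads$region_id, tree$id)
    nm[!is.na(hit)] <- tree$name[hit[!is.na(hit)]]
  }
  out <- data.frame(brain = loads$brain, stain = loads$stain,
                    region_id = loads$region_id, region_name = nm,
                    region_pixels = loads$region_pixels,
                    stained_pixels = loads$stained_pixels,
                    load_pct = loads$load)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_load_table
#' @export
read_load_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  data.frame(brain = as.character(df$brain), stain = df$stain,
             region_id = df$region_id, region_pixels = df$region_pixels,
             stained_pixels = df$stained_pixels, load = df$load_pct)
}

#' Per-region load difference between registration methods
#'
#' `difference = refined load - linear load` for every matching
#' (brain, stain, region) row; both tables must cover the same rows.
#'
#' @param refined,linear Load tables from [brain_load()] (refined = after
#'   nonlinear adjustment, linear = linear registration only).
#' @return Data frame with columns `brain`, `stain`, `region_id`,
#'   `load_refined`, `load_linear`, `difference`.
#' @export
load_difference <- function(refined, linear) {
  key <- function(t) paste(t$brain, t$stain, t$region_id, sep = "\r")
  kr <- key(refined); kl <- key(linear)
  if (length(kr) != length(kl) || !setequal(kr, kl)) {
    stopf("load tables do not cover the same (brain, stain, region) rows")
  }
  m <- match(kr, kl)
  data.frame(brain = refined$brain, stain = refined$stain,
             region_id = refined$region_id,
             load_refined = refined$load,
             load_linear = linear$load[m],
             difference = refined$load - linear$load[m])
}

#' Two-way group comparison of regional loads
#'
#' Per region, fits a two-way ANOVA `load ~ age_group + strain` across brains
#' and reports the F statistic and p-value of each factor; p-values are
#' FDR-adjusted (Benjamini-Hochberg) across regions per factor.
#'
#' @param loads A load table (one stain) with one row per brain x region.
#' @param metadata Data frame with columns `brain`, `age_group`, `strain`.
#' @param factors Factors to test (default age_group and strain); each must
#'   have at least two levels among the matched brains.
#' @return Data frame with one row per region: per factor `F_<f>`, `p_<f>`,
#'   `q_<f>`.
#' @export
compare_groups <- function(loads, metadata, factors = c("age_group", "strain")) {
  m <- match(as.character(loads$brain), as.character(metadata$brain))
  if (anyNA(m)) stopf("brain(s) missing from metadata: %s",
                      paste(unique(loads$brain[is.na(m)]), collapse = ", "))
  df <- cbind(loads, metadata[m, factors, drop = FALSE])
  for (f in factors) {
    if (length(unique(df[[f]])) < 2L) {
      stopf("factor %s has fewer than two levels", f)
    }
    df[[f]] <- factor(df[[f]])
  }
  fml <- stats::as.formula(paste("load ~", paste(factors, collapse = " + ")))
  res <- lapply(sort(unique(df$region_id)), function(rid) {
    sub <- df[df$region_id == rid, , drop = FALSE]
    fit <- stats::aov(fml, data = sub)
    tab <- summary(fit)[[1]]
    row <- data.frame(region_id = rid)
    for (f in factors) {
      i <- match(f, trimws(rownames(tab)))
      row[[paste0("F_", f)]] <- if (is.na(i)) NA_real_ else tab[i, "F value"]
      row[[paste0("p_", f)]] <- if (is.na(i)) NA_real_ else tab[i, "Pr(>F)"]
    }
    row
  })
  out <- do.call(rbind, res)
  for (f in factors) {
    out[[paste0("q_", f)]] <- fdr_adjust(out[[paste0("p_", f)]])
  }
  out
}

#' Rank-based paired comparison of loads between registration methods
#'
#' Per region, a paired two-sided Wilcoxon signed-rank test of refined vs
#' linear loads across brains, FDR-adjusted across regions. This is the
#' nonparametric companion to [load_difference()].
#'
#' @param refined,linear Load tables covering the same brains and regions.
#' @return Data frame with columns `region_id`, `statistic`, `p`, `q`.
#' @export
compare_methods <- function(refined, linear) {
  d <- load_difference(refined, linear)
  res <- lapply(sort(unique(d$region_id)), function(rid) {
    sub <- d[d$region_id == rid, , drop = FALSE]
    if (all(sub$difference == 0)) {
      return(data.frame(region_id = rid, statistic = NA_real_, p = 1))
    }
    wt <- suppressWarnings(
      stats::wilcox.test(sub$load_refined, sub$load_linear, paired = TRUE))
    data.frame(region_id = rid, statistic = unname(wt$statistic), p = wt$p.value)
  })
  out <- do.call(rbind, res)
  out$q <- fdr_adjust(out$p)
  out
}

#' Read / write boolean masks and segmentation masks as PNG
#'
#' Masks follow the convention nonzero = TRUE (for exclusion masks,
#' TRUE = excluded).
#'
#' @param path PNG path.
#' @return `read_mask_png` returns a logical matrix.
#' @export
read_mask_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1]
  img > 0.5
}

#' @rdname read_mask_png
#' @param mask Logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}
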