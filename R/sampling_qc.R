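# Systematic random sampling QC: assessment grids, marker bookkeeping,
# accuracy/uncertainty scoring across assessments, and damage-based section
# exclusion.
#
# Score definitions:
#   accuracy    = n_accurate / (n_accurate + n_inaccurate)   (undefined if 0/0)
#   uncertainty = n_uncertain / (n_accurate + n_inaccurate + n_uncertain)
#   damage      = n_damage / n_total_on_section; sections with damage > 30%
#                 (strictly) are excluded from analysis.
# Mean regional scores are unweighted means over assessments; assessments in
# which a region was marked entirely uncertain have undefined accuracy and are
# excluded from that region's mean.

MARKER_LABELS <- c("accurate", "inaccurate", "uncertain", "damage", "outside")

#' Generate a systematic random sampling grid
#'
#' Points lie on a regular lattice `(ox + i*s, oy + j*s)` for all `i, j >= 0`
#' that fall inside the image, with the global offset `(ox, oy)` drawn
#' uniformly from `[0, s)^2` under the given seed (clamped to the image
#' extent when the spacing exceeds it, so a coarser-than-image lattice still
#' samples one point). The same seed always yields the same grid.
#'
#' @param width,height Image size in pixels.
#' @param spacing Grid spacing in pixels (registration-resolution voxels);
#'   QC assessment conventionally uses 15, damage assessment 5.
#' @param seed Integer seed for the random offset; `NULL` uses the current
#'   RNG state.
#' @return n x 2 matrix of point coordinates (columns `x`, `y`) with the
#'   offset and seed stored as attributes.
#' @export
make_grid <- function(width, height, spacing = 15, seed = NULL) {
  if (!is.numeric(spacing) || spacing <= 0) stopf("spacing must be > 0")
  # the offset is clamped to the image extent so a lattice coarser than the
  # image still places its first point inside
  off <- with_seed(seed, stats::runif(2) * c(min(spacing, width),
                                             min(spacing, height)))
  xs <- seq(off[1], width + spacing, by = spacing)
  ys <- seq(off[2], height + spacing, by = spacing)
  xs <- xs[xs < width]; ys <- ys[ys < height]
  pts <- cbind(x = rep(xs, times = length(ys)), y = rep(ys, each = length(xs)))
  attr(pts, "offset") <- off
  attr(pts, "seed") <- seed
  attr(pts, "spacing") <- spacing
  pts
}

#' Construct a marker set
#'
#' @param pos n x 2 matrix of marker positions (pixel coordinates).
#' @param region_id Integer vector: custom region id at each marker.
#' @param label Character vector of marker labels, each one of
#'   `"accurate"`, `"inaccurate"`, `"uncertain"`, `"damage"`, `"outside"`.
#' @param brain,section,rater,spacing,seed Provenance fields.
#' @return An object of class `marker_set` (a data frame of markers plus
#'   provenance attributes).
#' @export
marker_set <- function(pos, region_id, label, brain = "", section = "",
                       rater = "", spacing = NA_real_, seed = NA_integer_) {
  pos <- matrix(as.numeric(pos), ncol = 2)
  bad <- setdiff(unique(label), MARKER_LABELS)
  if (length(bad)) stopf("unknown marker label(s): %s", paste(bad, collapse = ", "))
  df <- data.frame(x = pos[, 1], y = pos[, 2],
                   region_id = as.integer(region_id),
                   label = as.character(label))
  structure(df, class = c("marker_set", "data.frame"),
            brain = brain, section = section, rater = rater,
            spacing = spacing, seed = seed)
}

marker_provenance <- function(m) {
  list(brain = attr(m, "brain"), section = attr(m, "section"),
       rater = attr(m, "rater"), spacing = attr(m, "spacing"),
       seed = attr(m, "seed"))
}

#' Oracle rater: assess registration accuracy against a ground-truth map
#'
#' Synthetic stand-in for a human rater: a marker is `"accurate"` when the
#' refined map and the truth map carry the same label at its position,
#' `"uncertain"` when either label is background or [UNASSIGNED], and
#' `"inaccurate"` otherwise. The marker's region id is taken from the refined
#' map (as a human sees only the registered overlay). Markers take the label
#' of the pixel they fall in (pixel-center rule, no border tie-breaking).
#'
#' @param refined,truth [region_map]s at custom granularity with equal dims.
#' @param grid n x 2 matrix of marker positions, from [make_grid()].
#' @param h Optional `hierarchy_mapping`; when given, both maps are relabeled
#'   from full granularity first.
#' @param brain,section,rater Provenance strings.
#' @return A [marker_set].
#' @export
oracle_assess <- function(refined, truth, grid, h = NULL,
                          brain = "", section = "", rater = "oracle") {
  stopifnot(inherits(refined, "region_map"), inherits(truth, "region_map"))
  if (!is.null(h)) {
    if (refined$granularity == "full") refined <- relabel(refined, h)
    if (truth$granularity == "full") truth <- relabel(truth, h)
  }
  if (refined$width != truth$width || refined$height != truth$height) {
    stopf("dimension mismatch between refined and truth maps")
  }
  px <- floor(grid[, 1]); py <- floor(grid[, 2])
  keep <- px >= 0 & px < refined$width & py >= 0 & py < refined$height
  px <- px[keep]; py <- py[keep]
  idx <- cbind(py + 1L, px + 1L)
  ref_lab <- refined$labels[idx]
  tru_lab <- truth$labels[idx]
  unc <- ref_lab %in% c(0L, UNASSIGNED) | tru_lab %in% c(0L, UNASSIGNED)
  label <- ifelse(unc, "uncertain",
                  ifelse(ref_lab == tru_lab, "accurate", "inaccurate"))
  marker_set(grid[keep, , drop = FALSE], ref_lab, label,
             brain = brain, section = section, rater = rater,
             spacing = attr(grid, "spacing"),
             seed = if (is.null(attr(grid, "seed"))) NA_integer_ else attr(grid, "seed"))
}

#' Read / write marker sets (human markup dialect)
#'
#' File format: JSON `{"brain", "section", "rater", "spacing", "seed",
#' "markers": [[x, y, region_id, "label"], ...]}`.
#'
#' @param path File path.
#' @return `load_markers` returns a [marker_set].
#' @export
load_markers <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyMatrix = FALSE, simplifyDataFrame = FALSE)
  mk <- obj$markers
  if (is.null(mk)) stopf("marker file %s has no markers field", path)
  if (length(mk)) {
    pos <- do.call(rbind, lapply(mk, function(m) as.numeric(m[1:2])))
    region <- vapply(mk, function(m) as.integer(m[[3]]), integer(1))
    label <- vapply(mk, function(m) as.character(m[[4]]), character(1))
  } else {
    pos <- matrix(numeric(0), ncol = 2); region <- integer(0); label <- character(0)
  }
  marker_set(pos, region, label,
             brain = obj$brain %||% "", section = obj$section %||% "",
             rater = obj$rater %||% "",
             spacing = obj$spacing %||% NA_real_,
             seed = obj$seed %||% NA_integer_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname load_markers
#' @param m A [marker_set].
#' @export
save_markers <- function(m, path) {
  stopifnot(inherits(m, "marker_set"))
  prov <- marker_provenance(m)
  markers <- lapply(seq_len(nrow(m)), function(i) {
    list(m$x[i], m$y[i], m$region_id[i], m$label[i])
  })
  jsonlite::write_json(c(prov, list(markers = markers)), path,
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Score registration accuracy and uncertainty per region
#'
#' Each marker set is one assessment (one rater on one brain/section series).
#' Per (region, assessment): `accuracy = n_acc / (n_acc + n_inacc)` (defined
#' only when at least one marker could be verified) and
#' `uncertainty = n_unc / (n_acc + n_inacc + n_unc)`. Per region, the mean
#' accuracy is the unweighted mean over assessments with defined accuracy
#' (an assessment whose markers in the region were all uncertain is excluded
#' from the mean), with the SEM over those contributing assessments.
#'
#' @param markersets A [marker_set] or list of marker sets.
#' @return A list of class `qc_scores` with data frames `assessments` (one
#'   row per region x assessment) and `regions` (one row per region with
#'   `mean_accuracy`, `sem`, `mean_uncertainty`, `n_assessments`).
#' @export
qc_score <- function(markersets) {
  if (inherits(markersets, "marker_set")) markersets <- list(markersets)
  if (!length(markersets)) stopf("at least one marker set is required")
  rows <- list()
  for (i in seq_along(markersets)) {
    m <- markersets[[i]]
    stopifnot(inherits(m, "marker_set"))
    on_section <- m$label %in% c("accurate", "inaccurate", "uncertain")
    mm <- m[on_section, , drop = FALSE]
    if (!nrow(mm)) next
    for (rid in sort(unique(mm$region_id))) {
      sub <- mm[mm$region_id == rid, , drop = FALSE]
      n_acc <- sum(sub$label == "accurate")
      n_inacc <- sum(sub$label == "inaccurate")
      n_unc <- sum(sub$label == "uncertain")
      rows[[length(rows) + 1L]] <- data.frame(
        assessment = i,
        brain = attr(m, "brain"), rater = attr(m, "rater"),
        region_id = rid, n_acc = n_acc, n_inacc = n_inacc, n_unc = n_unc,
        accuracy = if (n_acc + n_inacc > 0) n_acc / (n_acc + n_inacc) else NA_real_,
        uncertainty = n_unc / (n_acc + n_inacc + n_unc))
    }
  }
  assessments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(assessment = integer(0), brain = character(0),
               rater = character(0), region_id = integer(0),
               n_acc = integer(0), n_inacc = integer(0), n_unc = integer(0),
               accuracy = numeric(0), uncertainty = numeric(0))
  regions <- do.call(rbind, lapply(sort(unique(assessments$region_id)), function(rid) {
    sub <- assessments[assessments$region_id == rid, , drop = FALSE]
    def <- sub[!is.na(sub$accuracy), , drop = FALSE]
    n <- nrow(def)
    data.frame(
      region_id = rid,
      n_assessments = n,
      mean_accuracy = if (n) mean(def$accuracy) else NA_real_,
      sem = if (n > 1) stats::sd(def$accuracy) / sqrt(n) else NA_real_,
      mean_uncertainty = mean(sub$uncertainty))
  }))
  if (is.null(regions)) {
    regions <- data.frame(region_id = integer(0), n_assessments = integer(0),
                          mean_accuracy = numeric(0), sem = numeric(0),
                          mean_uncertainty = numeric(0))
  }
  structure(list(assessments = assessments, regions = regions),
            class = "qc_scores")
}

#' @export
print.qc_scores <- function(x, ...) {
  cat(sprintf("qc_scores: %d regions over %d assessment rows\n",
              nrow(x$regions), nrow(x$assessments)))
  print(utils::head(x$regions, 10))
  invisible(x)
}

#' Write a QC report TSV
#'
#' Columns: region_id, region_name, n_assessments, mean_accuracy, sem,
#' mean_uncertainty. [UNASSIGNED] is rendered as "Unassigned".
#'
#' @param scores A `qc_scores` object.
#' @param path Output path.
#' @param tree Optional [structure_tree] used to resolve region names.
#' @export
write_qc_report <- function(scores, path, tree = NULL) {
  df <- scores$regions
  nm <- as.character(df$region_id)
  nm[df$region_id == UNASSIGNED] <- "Unassigned"
  if (!is.null(tree)) {
    hit <- match(df$region_id, tree$id)
    nm[!is.na(hit)] <- tree$name[hit[!is.na(hit)]]
  }
  out <- cbind(region_id = df$region_id, region_name = nm,
               df[, c("n_assessments", "mean_accuracy", "sem", "mean_uncertainty")])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assess section damage and decide exclusion
#'
#' The damage fraction is `n_damage / (n_damage + n_intact)` over on-section
#' markers (markers labeled `"outside"` are ignored; `"accurate"` counts as
#' intact tissue in a damage markup). A section is excluded when its damage
#' fraction strictly exceeds 30%.
#'
#' @param m A [marker_set] from a damage markup (labels restricted to
#'   `"damage"`, `"accurate"` and `"outside"`).
#' @param threshold Exclusion threshold on the damage fraction (strict
#'   inequality); default 0.30.
#' @return A one-row data frame: `section`, `n_damage`, `n_total`,
#'   `damage_fraction`, `excluded`.
#' @export
assess_damage <- function(m, threshold = 0.30) {
  stopifnot(inherits(m, "marker_set"))
  bad <- setdiff(unique(m$label), c("damage", "accurate", "outside"))
  if (length(bad)) {
    stopf("damage markup may only contain damage/accurate/outside labels, got: %s",
          paste(bad, collapse = ", "))
  }
  n_damage <- sum(m$label == "damage")
  n_intact <- sum(m$label == "accurate")
  n_total <- n_damage + n_intact
  if (n_total == 0L) stopf("no on-section markers; cannot assess damage")
  frac <- n_damage / n_total
  data.frame(section = attr(m, "section"), n_damage = n_damage,
             n_total = n_total, damage_fraction = frac,
             excluded = frac > threshold)
}

#' Damage markup of a section from a boolean damage mask
#'
#' Places a systematic random sampling grid (default 5 px spacing) over the
#' section and labels each marker `"damage"` or `"accurate"` (intact)
#' according to the mask; pixels outside the section (background in the
#' optional region map) are labeled `"outside"`.
#'
#' @param damage_mask Logical matrix (TRUE = damaged tissue), image-indexed
#'   `[y + 1, x + 1]`.
#' @param map Optional [region_map]; markers on background pixels are marked
#'   `"outside"`.
#' @param spacing Grid spacing in pixels (default 5).
#' @param seed Seed for the grid offset.
#' @param section Provenance string.
#' @return A [marker_set] suitable for [assess_damage()].
#' @export
damage_markup <- function(damage_mask, map = NULL, spacing = 5, seed = NULL,
                          section = "") {
  grid <- make_grid(ncol(damage_mask), nrow(damage_mask), spacing, seed)
  px <- floor(grid[, 1]); py <- floor(grid[, 2])
  idx <- cbind(py + 1L, px + 1L)
  lab <- ifelse(damage_mask[idx], "damage", "accurate")
  region <- rep(0L, nrow(grid))
  if (!is.null(map)) {
    mlab <- map$labels[idx]
    lab[mlab == 0L] <- "outside"
    region <- mlab
  }
  marker_set(grid, region, lab, section = section, rater = "damage",
             spacing = spacing, seed = if (is.null(seed)) NA_integer_ else seed)
}
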