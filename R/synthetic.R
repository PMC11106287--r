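# Synthetic ground truth: a mini-atlas (Voronoi-tessellated labeled volume
# plus ontology), warped and damaged sections with recoverable true inverse
# anchors, per-region Bernoulli stain masks, and expression matrices with
# designed age-dependent / age-independent load correlations. Everything is a
# pure function of (parameters, seed).

#' Generate a synthetic mini-atlas
#'
#' Labels the volume by a 3D Voronoi tessellation of uniformly seeded sites
#' (irregular, contiguous regions of varied size) and builds a three-level
#' structure tree: one root, `n_parents` parent regions, and the leaf regions
#' assigned round-robin to parents. Leaf ids start at 101, parents at 2,
#' root is 1.
#'
#' @param shape Integer 3-vector of volume dimensions (voxels).
#' @param n_leaf_regions Number of Voronoi leaf regions.
#' @param n_parents Number of parent regions (<= n_leaf_regions).
#' @param voxel_size Voxel size in micrometres.
#' @param seed Integer seed.
#' @return List with `volume` ([annotation_volume]) and `tree`
#'   ([structure_tree]).
#' @export
generate_atlas <- function(shape = c(64, 64, 64), n_leaf_regions = 8,
                           n_parents = 2, voxel_size = 25, seed = 1) {
  if (n_leaf_regions < n_parents) stopf("n_leaf_regions must be >= n_parents")
  shape <- as.integer(shape)
  leaf_ids <- 100L + seq_len(n_leaf_regions)
  parent_ids <- 1L + seq_len(n_parents)
  sites <- with_seed(seed, matrix(stats::runif(3 * n_leaf_regions), ncol = 3)) *
    matrix(shape - 1L, n_leaf_regions, 3, byrow = TRUE)
  gx <- rep(seq_len(shape[1]) - 1L, times = shape[2] * shape[3])
  gy <- rep(rep(seq_len(shape[2]) - 1L, each = shape[1]), times = shape[3])
  gz <- rep(seq_len(shape[3]) - 1L, each = shape[1] * shape[2])
  best_d <- rep(Inf, length(gx))
  best_l <- integer(length(gx))
  for (i in seq_len(n_leaf_regions)) {
    d <- (gx - sites[i, 1])^2 + (gy - sites[i, 2])^2 + (gz - sites[i, 3])^2
    hit <- d < best_d
    best_d[hit] <- d[hit]
    best_l[hit] <- leaf_ids[i]
  }
  labels <- array(best_l, dim = shape)
  nodes <- data.frame(
    id = c(1L, parent_ids, leaf_ids),
    name = c("Brain", paste0("Parent-", seq_len(n_parents)),
             paste0("Region-", seq_len(n_leaf_regions))),
    acronym = c("BR", paste0("P", seq_len(n_parents)),
                paste0("R", seq_len(n_leaf_regions))),
    parent_id = c(NA_integer_, rep(1L, n_parents),
                  parent_ids[(seq_len(n_leaf_regions) - 1L) %% n_parents + 1L]))
  tree <- structure_tree(nodes)
  list(volume = annotation_volume(labels, voxel_size, tree), tree = tree)
}

# Smooth random in-plane warp: displacement is a sum of two low-order sine
# modes under a boundary envelope sin(pi x/W) sin(pi y/H), rescaled so the
# maximum displacement magnitude equals `amplitude`. Zero displacement on the
# image boundary keeps anchors in-frame and matches the deformation field's
# fixed frame.
generate_warp <- function(width, height, amplitude, seed = NULL) {
  if (amplitude < 0) stopf("warp amplitude must be >= 0")
  co <- with_seed(seed, stats::runif(4, -1, 1))
  warp <- list(width = width, height = height, amplitude = amplitude, co = co)
  if (amplitude > 0) {
    # normalize peak |d| to the amplitude on a probe grid
    qx <- rep(seq(0, width, length.out = 41), each = 41)
    qy <- rep(seq(0, height, length.out = 41), times = 41)
    d <- warp_displacement(warp, cbind(qx, qy), scale = 1)
    peak <- max(sqrt(rowSums(d^2)))
    warp$scale <- if (peak > 0) amplitude / peak else 0
  } else {
    warp$scale <- 0
  }
  warp
}

warp_displacement <- function(warp, q, scale = warp$scale) {
  env <- sin(pi * q[, 1] / warp$width) * sin(pi * q[, 2] / warp$height)
  m2 <- sin(2 * pi * q[, 1] / warp$width) * sin(pi * q[, 2] / warp$height)
  m3 <- sin(pi * q[, 1] / warp$width) * sin(2 * pi * q[, 2] / warp$height)
  dx <- env * warp$co[1] + m2 * warp$co[3] * 0.5
  dy <- env * warp$co[2] + m3 * warp$co[4] * 0.5
  cbind(dx, dy) * scale
}

warp_apply <- function(warp, q) {
  q + warp_displacement(warp, q)
}

#' Generate synthetic registered sections with known warps and damage
#'
#' For each section: an anchoring plane across the volume (coronal-like with
#' small random obliquity), the ground-truth region map obtained by slicing,
#' an "observed" region map emulating imperfect linear registration (the
#' truth resampled through a smooth random in-plane warp of the requested
#' amplitude), the true inverse anchor set that undoes the warp (for
#' refinement), and a contiguous-blob damage mask covering the requested
#' pixel fraction.
#'
#' @param atlas A list with `volume` and `tree`, from [generate_atlas()].
#' @param n_sections Number of sections.
#' @param warp_amplitude Peak warp displacement in pixels (0 = perfectly
#'   registered; observed equals truth).
#' @param damage_frac Fraction of section pixels to cover with damage blobs.
#' @param seed Integer seed.
#' @param px_per_voxel Section resolution relative to the volume (pixels per
#'   voxel in-plane).
#' @param anchor_grid Anchors per axis of the true inverse anchor lattice.
#' @return List of sections; each has `anchoring`, `truth` ([region_map]),
#'   `observed` ([region_map]), `anchors` (n x 4 matrix start/end),
#'   `damage_mask`, `warp`, and `name`.
#' @export
generate_sections <- function(atlas, n_sections = 6, warp_amplitude = 0,
                              damage_frac = 0, seed = 1, px_per_voxel = 2,
                              anchor_grid = 8) {
  if (warp_amplitude < 0) stopf("warp amplitude must be >= 0")
  if (damage_frac < 0 || damage_frac >= 1) stopf("damage_frac must be in [0, 1)")
  vol <- atlas$volume
  d <- dim(vol$labels)
  W <- as.integer(round(d[1] * px_per_voxel))
  H <- as.integer(round(d[2] * px_per_voxel))
  zs <- seq(0.25, 0.75, length.out = n_sections) * (d[3] - 1)
  tilts <- with_seed(seed, matrix(stats::runif(2 * n_sections, -2, 2),
                                  ncol = 2))
  sections <- vector("list", n_sections)
  for (k in seq_len(n_sections)) {
    a <- section_anchoring(o = c(0, 0, zs[k]),
                           u = c(d[1], 0, tilts[k, 1]),
                           v = c(0, d[2], tilts[k, 2]),
                           width = W, height = H)
    truth <- slice_annotation(vol, a)
    warp <- generate_warp(W, H, warp_amplitude, seed = seed + 1000L + k)
    if (warp_amplitude > 0) {
      qx <- rep(seq_len(W) - 0.5, each = H)
      qy <- rep(seq_len(H) - 0.5, times = W)
      src <- warp_apply(warp, cbind(qx, qy))
      sx <- pmin(pmax(floor(src[, 1]), 0), W - 1L)
      sy <- pmin(pmax(floor(src[, 2]), 0), H - 1L)
      observed <- region_map(matrix(truth$labels[cbind(sy + 1L, sx + 1L)], H, W),
                             "full")
      g <- as.matrix(expand.grid(
        x = seq_len(anchor_grid) / (anchor_grid + 1) * W,
        y = seq_len(anchor_grid) / (anchor_grid + 1) * H))
      ge <- warp_apply(warp, g)
      ge[, 1] <- pmin(pmax(ge[, 1], 0), W)
      ge[, 2] <- pmin(pmax(ge[, 2], 0), H)
      anchors <- cbind(g, ge)   # start = overlay position, end = on-section
      colnames(anchors) <- c("start_x", "start_y", "end_x", "end_y")
    } else {
      observed <- truth
      anchors <- matrix(numeric(0), ncol = 4,
                        dimnames = list(NULL, c("start_x", "start_y",
                                                "end_x", "end_y")))
    }
    damage_mask <- matrix(FALSE, H, W)
    if (damage_frac > 0) {
      damage_mask <- with_seed(seed + 2000L + k, {
        mask <- matrix(FALSE, H, W)
        r <- max(3, round(min(W, H) / 8))
        px <- rep(seq_len(W) - 0.5, each = H)
        py <- rep(seq_len(H) - 0.5, times = W)
        guard <- 0L
        while (mean(mask) < damage_frac && guard < 200L) {
          cx <- stats::runif(1, 0, W); cy <- stats::runif(1, 0, H)
          mask[(px - cx)^2 + (py - cy)^2 <= r^2] <- TRUE
          guard <- guard + 1L
        }
        mask
      })
    }
    sections[[k]] <- list(name = sprintf("section_%02d", k), anchoring = a,
                          truth = truth, observed = observed,
                          anchors = anchors, damage_mask = damage_mask,
                          warp = warp)
  }
  sections
}

#' Generate stain-positive masks with known per-region densities
#'
#' Every pixel of region `r` is stain-positive independently with probability
#' `densities[[as.character(r)]]`; background and unlisted regions are never
#' positive.
#'
#' @param map A [region_map] (the ground-truth map of a section).
#' @param densities Named numeric vector of per-region densities in `[0, 1]`,
#'   names are region ids.
#' @param stain Stain name recorded on the result.
#' @param seed Integer seed.
#' @return A [segmentation_image].
#' @export
generate_stains <- function(map, densities, stain = "synthetic", seed = 1) {
  if (any(densities < 0 | densities > 1)) stopf("densities must lie in [0, 1]")
  labs <- map$labels
  p <- rep(0, length(labs))
  hit <- match(as.character(labs), names(densities))
  p[!is.na(hit)] <- densities[hit[!is.na(hit)]]
  mask <- with_seed(seed, stats::runif(length(labs)) < p)
  segmentation_image(matrix(mask, nrow = nrow(labs)), stain)
}

#' Simulate a load cohort with an age-driven mean shift
#'
#' Per-sample regional loads for a two-age-group cohort: group mean load plus
#' Gaussian within-group variation (floored at 0). Defaults emulate a
#' strongly age-driven stain: mean load 2% at the younger age and 6% at the
#' older, within-group standard deviation 0.3%.
#'
#' @param n Total number of samples (split evenly across groups).
#' @param age_groups Group labels.
#' @param mean_loads Per-group mean loads (percent).
#' @param within_sd Within-group standard deviation (percent).
#' @param seed Integer seed.
#' @return Data frame with `sample`, `age_group`, `load`.
#' @export
simulate_load_cohort <- function(n = 200, age_groups = c("6m", "14m"),
                                 mean_loads = c(2, 6), within_sd = 0.3,
                                 seed = 1) {
  k <- length(age_groups)
  sizes <- rep(n %/% k, k)
  sizes[seq_len(n %% k)] <- sizes[seq_len(n %% k)] + 1L
  g <- rep(age_groups, sizes)
  mu <- rep(mean_loads, sizes)
  load <- with_seed(seed, pmax(0, stats::rnorm(n, mu, within_sd)))
  data.frame(sample = sprintf("S%03d", seq_len(n)), age_group = g, load = load)
}

#' Generate an expression matrix with designed load-correlation categories
#'
#' Negative-binomial counts whose log-mean tracks the between-age-group load
#' component (`age_dependent` genes), the within-group-centered load
#' (`age_independent` genes), both (`both`), or neither (`neither`). Effect
#' sizes are calibrated so the designed predictor correlates with log-scale
#' expression at approximately the requested `r`.
#'
#' @param load Per-sample load vector (percent).
#' @param age_group Per-sample age group.
#' @param n_per_category Named integer vector of gene counts per category.
#' @param r Target correlation magnitude for the designed component.
#' @param dispersion Negative-binomial dispersion (1/size).
#' @param base_mean Baseline mean count.
#' @param seed Integer seed.
#' @return List with `counts` (genes x samples integer matrix, gene ids in
#'   rownames), `truth` (data frame `gene_id`, `category`), `meta`.
#' @export
generate_expression <- function(load, age_group,
                                n_per_category = c(age_dependent = 500,
                                                   age_independent = 500,
                                                   both = 500, neither = 500),
                                r = 0.6, dispersion = 0.05, base_mean = 500,
                                seed = 1) {
  known <- c("age_dependent", "age_independent", "both", "neither")
  bad <- setdiff(names(n_per_category), known)
  if (length(bad)) stopf("unknown category: %s", paste(bad, collapse = ", "))
  n <- length(load)
  g <- as.character(age_group)
  x_b <- stats::ave(load, g)            # between-group (age-driven) component
  x_w <- load - x_b                     # within-group-centered component
  z <- function(x) if (stats::sd(x) > 0) (x - mean(x)) / stats::sd(x) else x * 0
  z_b <- z(x_b); z_w <- z(x_w)
  # log2-scale noise sd of NB counts around mean `base_mean`
  sigma <- sqrt(1 / base_mean + dispersion) / log(2)
  beta <- if (r > 0) sigma * r / sqrt(1 - r^2) else 0
  cats <- rep(names(n_per_category), n_per_category)
  n_genes <- length(cats)
  gene_id <- sprintf("gene%05d", seq_len(n_genes))
  signs <- with_seed(seed, sample(c(-1, 1), n_genes, replace = TRUE))
  counts <- with_seed(seed + 1L, {
    m <- matrix(0L, n_genes, n, dimnames = list(gene_id, NULL))
    for (i in seq_len(n_genes)) {
      lmu <- log2(base_mean) +
        (if (cats[i] %in% c("age_dependent", "both")) signs[i] * beta * z_b else 0) +
        (if (cats[i] %in% c("age_independent", "both")) signs[i] * beta * z_w else 0)
      m[i, ] <- stats::rnbinom(n, mu = 2^lmu, size = 1 / dispersion)
    }
    m
  })
  colnames(counts) <- if (!is.null(names(load))) names(load) else
    sprintf("S%03d", seq_len(n))
  list(counts = counts,
       truth = data.frame(gene_id = gene_id, category = cats),
       meta = data.frame(sample = colnames(counts), age_group = g,
                         load = load))
}

#' Emit a ready-to-run synthetic project directory
#'
#' Writes a complete on-disk project with known ground truth: the annotation
#' volume (raw + sidecar), hierarchy and custom-hierarchy files, linear
#' anchoring and deformation (true inverse anchor) records, per-section
#' segmentation and damage-mask PNGs, an expression counts/metadata pair, and
#' a `truth.json` recording the designed densities and categories.
#'
#' @param dir Output directory (created if missing).
#' @param shape,n_leaf_regions,n_parents Atlas parameters.
#' @param n_sections,warp_amplitude,damage_frac Section parameters.
#' @param densities Per-region stain densities; default recycles
#'   `c(0.02, 0.05, 0.1, 0.3)` over the leaf regions.
#' @param stain Stain name for the synthetic segmentations.
#' @param seed Master seed.
#' @return Invisibly, a list of the generated objects.
#' @export
simulate_project <- function(dir, shape = c(48, 48, 48), n_leaf_regions = 8,
                             n_parents = 2, n_sections = 6,
                             warp_amplitude = 0, damage_frac = 0,
                             densities = NULL, stain = "Iba1", seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  atlas <- generate_atlas(shape, n_leaf_regions, n_parents, seed = seed)
  leaf_ids <- setdiff(atlas$tree$id, c(1L, 1L + seq_len(n_parents)))
  if (is.null(densities)) {
    densities <- stats::setNames(rep(c(0.02, 0.05, 0.1, 0.3),
                                     length.out = n_leaf_regions),
                                 leaf_ids)
  }
  secs <- generate_sections(atlas, n_sections, warp_amplitude, damage_frac,
                            seed = seed)
  write_annotation_volume(atlas$volume, file.path(dir, "annotation.raw"))
  write_structure_tree(atlas$tree, file.path(dir, "hierarchy.json"))
  write_hierarchy_selection(leaf_ids, file.path(dir, "custom_hierarchy.json"))
  write_anchoring(stats::setNames(lapply(secs, `[[`, "anchoring"),
                                  vapply(secs, `[[`, "", "name")),
                  file.path(dir, "anchoring.json"))
  recs <- lapply(secs, function(s) {
    deformation_record(s$anchors, s$truth$width, s$truth$height)
  })
  write_deformation(stats::setNames(recs, vapply(secs, `[[`, "", "name")),
                    file.path(dir, "deformation.json"))
  dir.create(file.path(dir, "segmentations"), showWarnings = FALSE)
  dir.create(file.path(dir, "damage"), showWarnings = FALSE)
  segs <- list()
  for (k in seq_along(secs)) {
    seg <- generate_stains(secs[[k]]$truth, densities, stain,
                           seed = seed + 3000L + k)
    segs[[k]] <- seg
    write_mask_png(seg$mask,
                   file.path(dir, "segmentations",
                             paste0(secs[[k]]$name, ".png")))
    write_mask_png(secs[[k]]$damage_mask,
                   file.path(dir, "damage", paste0(secs[[k]]$name, ".png")))
  }
  cohort <- simulate_load_cohort(n = 40, seed = seed + 4000L)
  expr <- generate_expression(cohort$load, cohort$age_group,
                              n_per_category = c(age_dependent = 50,
                                                 age_independent = 50,
                                                 both = 50, neither = 50),
                              seed = seed + 5000L)
  write_counts(expr$counts, file.path(dir, "counts.tsv"))
  write_sample_meta(data.frame(sample = cohort$sample, brain = cohort$sample,
                               age_group = cohort$age_group,
                               strain = "synthetic"),
                    file.path(dir, "meta.tsv"))
  jsonlite::write_json(
    list(seed = seed, densities = as.list(densities),
         warp_amplitude = warp_amplitude, damage_frac = damage_frac,
         gene_categories = expr$truth),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(list(atlas = atlas, sections = secs, segmentations = segs,
                 densities = densities, cohort = cohort, expression = expr))
}
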