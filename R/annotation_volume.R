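# The 3D annotation volume (labeled voxel grid), section anchoring planes, and
# the 2D atlas plates (region maps) obtained by oblique slicing.
#
# Conventions (documented, QuickNII-style):
#   * voxels are 0-based, centers at integer coordinates;
#   * a section pixel (x, y) is 0-based with (0, 0) top-left, x rightwards;
#   * the anchoring stores full-extent vectors: o is the atlas position of the
#     plate origin, u spans the full image width, v the full image height;
#   * slicing samples the pixel center, o + u*(x+0.5)/width + v*(y+0.5)/height,
#     with nearest-neighbor label lookup (labels are never averaged);
#   * coordinates outside the volume yield background 0.

#' Construct an annotation volume
#'
#' @param labels 3D integer array of region labels, indexed `[x, y, z]`
#'   (0-based voxel `(i,j,k)` is `labels[i+1, j+1, k+1]`). 0 is background.
#' @param voxel_size Voxel edge length in micrometres (isotropic).
#' @param tree Optional [structure_tree]; when given, every nonzero label must
#'   be a region id present in the tree.
#' @return An object of class `annotation_volume`.
#' @export
annotation_volume <- function(labels, voxel_size = 25, tree = NULL) {
  if (!is.array(labels) || length(dim(labels)) != 3L) {
    stopf("labels must be a 3D array")
  }
  storage.mode(labels) <- "integer"
  if (!is.numeric(voxel_size) || voxel_size <= 0) stopf("voxel_size must be > 0")
  if (!is.null(tree)) {
    present <- setdiff(unique(as.vector(labels)), 0L)
    bad <- setdiff(present, tree$id)
    if (length(bad)) {
      stopf("volume labels not present in structure tree: %s",
            paste(bad, collapse = ", "))
    }
  }
  structure(list(labels = labels, voxel_size = voxel_size),
            class = "annotation_volume")
}

#' @export
print.annotation_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("annotation_volume: %d x %d x %d voxels @ %g um, %d labels\n",
              d[1], d[2], d[3], x$voxel_size,
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

#' Read / write an annotation volume
#'
#' On disk the volume is a raw little-endian integer array (16- or 32-bit,
#' x fastest) with a JSON sidecar `<path>.json` holding
#' `{"shape": [X, Y, Z], "voxel_size_um": ..., "bytes": 2|4}`. Multi-page TIFF
#' label stacks (one page per z) are also accepted by `read_annotation_volume`.
#'
#' @param path Path to the raw file (sidecar at `<path>.json`) or a
#'   `.tif`/`.tiff` stack.
#' @param voxel_size Voxel size in micrometres used when reading a TIFF stack
#'   (raw files carry it in the sidecar).
#' @return An `annotation_volume`.
#' @export
read_annotation_volume <- function(path, voxel_size = 25) {
  if (!file.exists(path)) stopf("volume file not found: %s", path)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    d <- dim(pages[[1]])
    # readTIFF returns row-major [y, x]; volume axis order is [x, y, z]
    labels <- array(0L, dim = c(d[2], d[1], length(pages)))
    for (k in seq_along(pages)) labels[, , k] <- t(pages[[k]])
    return(annotation_volume(labels, voxel_size))
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stopf("sidecar not found: %s", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  shape <- as.integer(meta$shape)
  bytes <- if (!is.null(meta$bytes)) as.integer(meta$bytes) else 4L
  n <- prod(shape)
  raw <- readBin(path, what = "integer", n = n, size = bytes,
                 endian = "little", signed = bytes > 2L)
  labels <- array(as.integer(raw), dim = shape)
  annotation_volume(labels, as.numeric(meta$voxel_size_um))
}

#' @rdname read_annotation_volume
#' @param vol An `annotation_volume`.
#' @param bytes Bytes per voxel (2 or 4) for the raw encoding.
#' @export
write_annotation_volume <- function(vol, path, bytes = 4L) {
  stopifnot(inherits(vol, "annotation_volume"))
  writeBin(as.integer(vol$labels), path, size = bytes, endian = "little")
  jsonlite::write_json(
    list(shape = dim(vol$labels), voxel_size_um = vol$voxel_size, bytes = bytes),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' Construct a section anchoring (linear plane placement)
#'
#' @param o Numeric 3-vector: atlas position (voxel units) of the plate origin,
#'   i.e. of section pixel (0, 0).
#' @param u Numeric 3-vector: atlas displacement across the full image width.
#' @param v Numeric 3-vector: atlas displacement down the full image height.
#' @param width,height Section image size in pixels.
#' @return An object of class `section_anchoring`.
#' @export
section_anchoring <- function(o, u, v, width, height) {
  o <- as.numeric(o); u <- as.numeric(u); v <- as.numeric(v)
  for (nm in c("o", "u", "v")) {
    val <- get(nm)
    if (length(val) != 3L || anyNA(val)) stopf("%s must be a numeric 3-vector", nm)
  }
  if (!is_count(width) || !is_count(height)) stopf("width and height must be >= 1")
  cr <- c(u[2] * v[3] - u[3] * v[2],
          u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (sqrt(sum(cr^2)) < 1e-9 * max(1, sqrt(sum(u^2)) * sqrt(sum(v^2)))) {
    stopf("degenerate anchoring: u and v are linearly dependent")
  }
  structure(list(o = o, u = u, v = v,
                 width = as.integer(width), height = as.integer(height)),
            class = "section_anchoring")
}

#' Construct a region map (2D atlas plate)
#'
#' @param labels Integer matrix of region labels indexed `[y + 1, x + 1]`
#'   (rows are image rows; pixel (0,0) is top-left). Values are region ids,
#'   [UNASSIGNED], or 0 for background/outside.
#' @param granularity `"full"` (raw atlas labels) or `"custom"` (compiled
#'   hierarchy labels).
#' @return An object of class `region_map`.
#' @export
region_map <- function(labels, granularity = c("full", "custom")) {
  granularity <- match.arg(granularity)
  if (!is.matrix(labels)) stopf("labels must be a matrix")
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, granularity = granularity,
                 width = ncol(labels), height = nrow(labels)),
            class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat(sprintf("region_map: %d x %d px (%s granularity), %d region labels\n",
              x$width, x$height, x$granularity,
              length(setdiff(unique(as.vector(x$labels)), c(0L, UNASSIGNED)))))
  invisible(x)
}

#' Slice the annotation volume into an atlas plate
#'
#' Samples the volume along the anchoring plane: output pixel (x, y) carries
#' the label of the voxel nearest to
#' `o + u*(x+0.5)/width + v*(y+0.5)/height`; sample points outside the volume
#' yield background 0.
#'
#' @param vol An [annotation_volume].
#' @param a A [section_anchoring].
#' @return A [region_map] at `"full"` granularity of size `width` x `height`.
#' @export
slice_annotation <- function(vol, a) {
  stopifnot(inherits(vol, "annotation_volume"), inherits(a, "section_anchoring"))
  d <- dim(vol$labels)
  W <- a$width; H <- a$height
  fx <- (seq_len(W) - 0.5) / W           # (x + 0.5)/width for x = 0..W-1
  fy <- (seq_len(H) - 0.5) / H
  # coordinate grids: pixel (x, y) -> row y+1, col x+1
  FX <- matrix(fx, nrow = H, ncol = W, byrow = TRUE)
  FY <- matrix(fy, nrow = H, ncol = W)
  out <- matrix(0L, nrow = H, ncol = W)
  cx <- round(a$o[1] + a$u[1] * FX + a$v[1] * FY)
  cy <- round(a$o[2] + a$u[2] * FX + a$v[2] * FY)
  cz <- round(a$o[3] + a$u[3] * FX + a$v[3] * FY)
  inb <- cx >= 0 & cx < d[1] & cy >= 0 & cy < d[2] & cz >= 0 & cz < d[3]
  if (any(inb)) {
    idx <- cbind(cx[inb] + 1L, cy[inb] + 1L, cz[inb] + 1L)
    out[inb] <- vol$labels[idx]
  }
  region_map(out, "full")
}

#' Relabel a full-granularity region map to a custom hierarchy level
#'
#' Every pixel label is replaced by its custom id under the mapping;
#' background 0 is unchanged. A label absent from the mapping signals a
#' tree/volume mismatch and is an error.
#'
#' @param map A [region_map] at `"full"` granularity.
#' @param h A `hierarchy_mapping` from [compile_hierarchy()].
#' @return A [region_map] at `"custom"` granularity.
#' @export
relabel <- function(map, h) {
  stopifnot(inherits(map, "region_map"), inherits(h, "hierarchy_mapping"))
  if (map$granularity != "full") stopf("relabel expects a full-granularity map")
  labs <- map$labels
  vals <- sort(unique(as.vector(labs)))
  lut <- hierarchy_lookup(h, vals)     # errors on unknown labels
  out <- matrix(lut[match(labs, vals)], nrow = nrow(labs))
  region_map(out, "custom")
}
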