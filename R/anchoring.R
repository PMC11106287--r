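# Linear anchoring I/O (QuickNII-compatible JSON dialect) and least-squares
# anchoring fits from pixel/atlas landmark pairs.

#' Read per-section linear anchoring records
#'
#' The anchoring file is JSON
#' `{"sections": [{"filename", "ox","oy","oz", "ux","uy","uz",
#' "vx","vy","vz", "width", "height"}, ...]}` with full-extent u and v
#' vectors. Section order is preserved.
#'
#' @param path Path to the anchoring JSON file.
#' @return A named list of [section_anchoring] objects (names are filenames).
#' @export
read_anchoring <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  secs <- obj$sections
  if (is.null(secs)) stopf("anchoring file %s has no sections field", path)
  out <- list()
  for (s in secs) {
    for (nm in c("ox", "oy", "oz", "ux", "uy", "uz", "vx", "vy", "vz")) {
      if (is.null(s[[nm]]) || length(s[[nm]]) != 1L || !is.numeric(s[[nm]])) {
        stopf("section %s: malformed anchoring component %s",
              if (is.null(s$filename)) "<unnamed>" else s$filename, nm)
      }
    }
    a <- section_anchoring(c(s$ox, s$oy, s$oz), c(s$ux, s$uy, s$uz),
                           c(s$vx, s$vy, s$vz), s$width, s$height)
    out[[length(out) + 1L]] <- a
    names(out)[length(out)] <- if (is.null(s$filename)) "" else s$filename
  }
  out
}

#' Write per-section linear anchoring records
#'
#' Round-trips with [read_anchoring()]: writing then reading returns
#' identical records in the same order.
#'
#' @param anchorings Named list of [section_anchoring] objects.
#' @param path Output path.
#' @export
write_anchoring <- function(anchorings, path) {
  secs <- lapply(seq_along(anchorings), function(i) {
    a <- anchorings[[i]]
    stopifnot(inherits(a, "section_anchoring"))
    nm <- names(anchorings)[i]
    list(filename = if (is.null(nm) || is.na(nm)) "" else nm,
         ox = a$o[1], oy = a$o[2], oz = a$o[3],
         ux = a$u[1], uy = a$u[2], uz = a$u[3],
         vx = a$v[1], vy = a$v[2], vz = a$v[3],
         width = a$width, height = a$height)
  })
  jsonlite::write_json(list(sections = secs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Fit a linear anchoring from landmark pairs
#'
#' Solves for `o`, `u`, `v` by least squares such that the pixel position
#' `(x, y)` maps to atlas coordinate `o + u*x/width + v*y/height` with minimal
#' summed squared atlas-space residual. Pixel positions are continuous image
#' coordinates (the image spans `[0, width] x [0, height]`), so e.g. the four
#' image corners are valid landmarks. Exact when the pairs are consistent.
#'
#' @param pixels n x 2 matrix of pixel positions (x, y).
#' @param voxels n x 3 matrix of the corresponding atlas voxel coordinates.
#' @param width,height Section image size in pixels.
#' @return A [section_anchoring].
#' @export
fit_anchoring <- function(pixels, voxels, width, height) {
  pixels <- as.matrix(pixels); voxels <- as.matrix(voxels)
  if (nrow(pixels) != nrow(voxels)) stopf("pixels and voxels must pair up")
  if (nrow(pixels) < 3L) stopf("at least 3 landmark pairs are required")
  X <- cbind(1, pixels[, 1] / width, pixels[, 2] / height)
  if (qr(X)$rank < 3L) stopf("landmark pixel positions are collinear")
  beta <- qr.solve(X, voxels)          # 3 x 3: rows o, u, v
  section_anchoring(beta[1, ], beta[2, ], beta[3, ], width, height)
}
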