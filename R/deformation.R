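# Nonlinear refinement: anchor-point displacement records and the continuous
# piecewise-affine deformation field they induce.
#
# The field is the pull-back from section pixel coordinates to source overlay
# coordinates, defined over a Delaunay triangulation of the anchor end-points
# augmented with a fixed boundary frame (4 corners + 4 edge midpoints, zero
# displacement). Within each triangle the map is the affine (barycentric)
# transfer onto the corresponding start-point triangle, so it is continuous
# across edges, exact at anchors, and the identity when all displacements are
# zero.

#' Construct an anchor-point displacement record
#'
#' Each anchor has a `start` position (where the point sat on the linearly
#' registered overlay) and an `end` position (where it was dragged to on the
#' section image). All positions are continuous pixel coordinates in
#' `[0, width] x [0, height]`.
#'
#' @param anchors n x 4 numeric matrix with columns `start_x, start_y,
#'   end_x, end_y` (may have 0 rows).
#' @param width,height Section image size in pixels.
#' @return An object of class `deformation_record`.
#' @export
deformation_record <- function(anchors, width, height) {
  if (is.null(anchors) || length(anchors) == 0L) {
    anchors <- matrix(numeric(0), ncol = 4)
  }
  anchors <- as.matrix(anchors)
  if (ncol(anchors) != 4L) stopf("anchors must have 4 columns (sx, sy, ex, ey)")
  colnames(anchors) <- c("start_x", "start_y", "end_x", "end_y")
  if (nrow(anchors)) {
    inx <- anchors[, c(1, 3)] >= 0 & anchors[, c(1, 3)] <= width
    iny <- anchors[, c(2, 4)] >= 0 & anchors[, c(2, 4)] <= height
    if (!all(inx) || !all(iny)) stopf("anchor outside image bounds")
    if (anyDuplicated(anchors[, 1:2, drop = FALSE])) stopf("start points must be distinct")
    if (anyDuplicated(anchors[, 3:4, drop = FALSE])) stopf("end points must be distinct")
  }
  structure(list(anchors = anchors, width = as.integer(width),
                 height = as.integer(height)),
            class = "deformation_record")
}

#' Read / write deformation records (VisuAlign-like markup dialect)
#'
#' File format: JSON `{"sections": [{"filename",
#' "anchors": [[sx, sy, ex, ey], ...], "width", "height"}, ...]}`.
#'
#' @param path File path.
#' @return A named list of [deformation_record] objects.
#' @export
read_deformation <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  secs <- obj$sections
  if (is.null(secs)) stopf("deformation file %s has no sections field", path)
  out <- list()
  for (s in secs) {
    anc <- s$anchors
    if (length(anc)) {
      bad <- any(vapply(anc, function(a) length(a) != 4L, logical(1)))
      if (bad) stopf("malformed anchor (expected 4 components) in %s", path)
      anc <- do.call(rbind, lapply(anc, as.numeric))
    } else anc <- NULL
    rec <- deformation_record(anc, s$width, s$height)
    out[[length(out) + 1L]] <- rec
    names(out)[length(out)] <- if (is.null(s$filename)) "" else s$filename
  }
  out
}

#' @rdname read_deformation
#' @param records Named list of [deformation_record] objects.
#' @export
write_deformation <- function(records, path) {
  secs <- lapply(seq_along(records), function(i) {
    r <- records[[i]]
    nm <- names(records)[i]
    list(filename = if (is.null(nm) || is.na(nm)) "" else nm,
         width = r$width, height = r$height,
         anchors = lapply(seq_len(nrow(r$anchors)),
                          function(i) unname(as.numeric(r$anchors[i, ]))))
  })
  jsonlite::write_json(list(sections = secs), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# --- Delaunay triangulation (Bowyer-Watson) -------------------------------
# Pure-R incremental construction; point sets here are small (anchors plus an
# 8-point frame). Degenerate configurations (cocircular / collinear points,
# common for gridded anchors) are broken by an infinitesimal deterministic
# perturbation used for the topology only; the affine transfer always uses the
# exact input coordinates.

circumcircle <- function(p, tri_idx) {
  a <- p[tri_idx[1], ]; b <- p[tri_idx[2], ]; c <- p[tri_idx[3], ]
  d <- 2 * (a[1] * (b[2] - c[2]) + b[1] * (c[2] - a[2]) + c[1] * (a[2] - b[2]))
  if (abs(d) < 1e-12) return(c(Inf, Inf, Inf))
  a2 <- sum(a^2); b2 <- sum(b^2); c2 <- sum(c^2)
  ux <- (a2 * (b[2] - c[2]) + b2 * (c[2] - a[2]) + c2 * (a[2] - b[2])) / d
  uy <- (a2 * (c[1] - b[1]) + b2 * (a[1] - c[1]) + c2 * (b[1] - a[1])) / d
  c(ux, uy, (a[1] - ux)^2 + (a[2] - uy)^2)
}

delaunay_triangulate <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) stopf("triangulation needs at least 3 points")
  scale <- max(diff(range(pts[, 1])), diff(range(pts[, 2])), 1)
  # deterministic symbolic perturbation to break cocircular ties
  jit <- cbind(sin(seq_len(n) * 12.9898), cos(seq_len(n) * 78.233)) * scale * 1e-7
  p <- pts + jit
  # super-triangle well outside the data
  cx <- mean(range(p[, 1])); cy <- mean(range(p[, 2]))
  R <- scale * 20
  p <- rbind(p, c(cx - 2 * R, cy - R), c(cx + 2 * R, cy - R), c(cx, cy + 2 * R))
  sup <- n + 1:3
  tris <- matrix(sup, ncol = 3)
  cc <- matrix(circumcircle(p, tris[1, ]), ncol = 3)
  for (i in seq_len(n)) {
    px <- p[i, 1]; py <- p[i, 2]
    bad <- (px - cc[, 1])^2 + (py - cc[, 2])^2 < cc[, 3] * (1 + 1e-12)
    if (!any(bad)) { # numerical safety: force nearest triangle open
      d2 <- (px - cc[, 1])^2 + (py - cc[, 2])^2 - cc[, 3]
      bad[which.min(d2)] <- TRUE
    }
    hole <- tris[bad, , drop = FALSE]
    tris <- tris[!bad, , drop = FALSE]
    cc <- cc[!bad, , drop = FALSE]
    # boundary edges: edges of the hole that occur exactly once
    edges <- rbind(hole[, c(1, 2), drop = FALSE],
                   hole[, c(2, 3), drop = FALSE],
                   hole[, c(3, 1), drop = FALSE])
    key <- paste(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    keep <- edges[key %in% names(which(table(key) == 1L)), , drop = FALSE]
    if (nrow(keep)) {
      newt <- cbind(keep, i)
      tris <- rbind(tris, newt)
      cc <- rbind(cc, t(apply(newt, 1, function(t3) circumcircle(p, t3))))
    }
  }
  keep <- !apply(tris, 1, function(t3) any(t3 %in% sup))
  tris <- tris[keep, , drop = FALSE]
  # canonical, deterministic ordering
  tris <- t(apply(tris, 1, sort))
  tris[order(tris[, 1], tris[, 2], tris[, 3]), , drop = FALSE]
}

#' Build the piecewise-affine deformation field for one section
#'
#' Triangulates the anchor end-points together with a fixed boundary frame
#' (four image corners and four edge midpoints, zero displacement) and maps
#' each triangle affinely onto the corresponding start-point triangle. The
#' resulting field is continuous, maps every anchor end exactly to its start,
#' and is the identity when all displacements are zero. Fold-overs (crossing
#' anchors) are permitted; point location on the end triangulation decides,
#' ties broken by lowest triangle index.
#'
#' @param rec A [deformation_record] (or an n x 4 anchor matrix).
#' @param width,height Image size in pixels; taken from `rec` when omitted.
#' @return An object of class `deformation_field`.
#' @export
build_deformation <- function(rec, width = NULL, height = NULL) {
  if (!inherits(rec, "deformation_record")) {
    rec <- deformation_record(rec, width, height)
  }
  W <- rec$width; H <- rec$height
  frame <- cbind(c(0, W, W, 0, W / 2, W, W / 2, 0),
                 c(0, 0, H, H, 0, H / 2, H, H / 2))
  anc <- rec$anchors
  if (nrow(anc)) {
    dup <- apply(frame, 1, function(f) {
      any(abs(anc[, 3] - f[1]) < 1e-9 & abs(anc[, 4] - f[2]) < 1e-9)
    })
    frame <- frame[!dup, , drop = FALSE]
  }
  ends <- rbind(anc[, 3:4, drop = FALSE], frame)
  starts <- rbind(anc[, 1:2, drop = FALSE], frame)
  tris <- delaunay_triangulate(ends)
  structure(list(tris = tris, ends = unname(ends), starts = unname(starts),
                 record = rec, width = W, height = H),
            class = "deformation_field")
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf("deformation_field: %d anchors, %d triangles over %d x %d px\n",
              nrow(x$record$anchors), nrow(x$tris), x$width, x$height))
  invisible(x)
}

#' Evaluate the deformation field at section coordinates
#'
#' Maps section pixel coordinates to source overlay coordinates (the
#' pull-back). Points outside every triangle (numerically outside the frame)
#' return `NA` coordinates.
#'
#' @param field A `deformation_field`.
#' @param q n x 2 matrix of section coordinates.
#' @return n x 2 matrix of overlay coordinates.
#' @export
evaluate_deformation <- function(field, q) {
  q <- matrix(as.numeric(q), ncol = 2)
  n <- nrow(q)
  out <- matrix(NA_real_, n, 2)
  done <- rep(FALSE, n)
  tol <- 1e-9 * max(field$width, field$height)
  for (t in seq_len(nrow(field$tris))) {
    if (all(done)) break
    v <- field$tris[t, ]
    A <- field$ends[v[1], ]; B <- field$ends[v[2], ]; C <- field$ends[v[3], ]
    todo <- which(!done)
    # bounding-box prefilter
    bb <- q[todo, 1] >= min(A[1], B[1], C[1]) - tol &
      q[todo, 1] <= max(A[1], B[1], C[1]) + tol &
      q[todo, 2] >= min(A[2], B[2], C[2]) - tol &
      q[todo, 2] <= max(A[2], B[2], C[2]) + tol
    todo <- todo[bb]
    if (!length(todo)) next
    det <- (B[1] - A[1]) * (C[2] - A[2]) - (C[1] - A[1]) * (B[2] - A[2])
    if (abs(det) < 1e-12) next
    l1 <- ((B[2] - C[2]) * (q[todo, 1] - C[1]) +
             (C[1] - B[1]) * (q[todo, 2] - C[2])) / det
    l2 <- ((C[2] - A[2]) * (q[todo, 1] - C[1]) +
             (A[1] - C[1]) * (q[todo, 2] - C[2])) / det
    l3 <- 1 - l1 - l2
    inside <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    hit <- todo[inside]
    if (!length(hit)) next
    sA <- field$starts[v[1], ]; sB <- field$starts[v[2], ]; sC <- field$starts[v[3], ]
    out[hit, 1] <- l1[inside] * sA[1] + l2[inside] * sB[1] + l3[inside] * sC[1]
    out[hit, 2] <- l1[inside] * sA[2] + l2[inside] * sB[2] + l3[inside] * sC[2]
    done[hit] <- TRUE
  }
  out
}

#' Apply a deformation field to a region map
#'
#' Resamples the region map through the pull-back field: output pixel `q`
#' receives the label of the input pixel containing `f(q)` (nearest-neighbor;
#' labels are never averaged). Pull-back coordinates outside the frame yield
#' background 0. The output label set is a subset of the input label set plus
#' background.
#'
#' @param map A [region_map].
#' @param field A `deformation_field` with matching dimensions.
#' @return A [region_map] with the same granularity as the input.
#' @export
apply_deformation <- function(map, field) {
  stopifnot(inherits(map, "region_map"), inherits(field, "deformation_field"))
  if (map$width != field$width || map$height != field$height) {
    stopf("dimension mismatch: map is %d x %d, field is %d x %d",
          map$width, map$height, field$width, field$height)
  }
  W <- map$width; H <- map$height
  # pixel centers of the output image
  qx <- rep(seq_len(W) - 0.5, each = H)
  qy <- rep(seq_len(H) - 0.5, times = W)
  src <- evaluate_deformation(field, cbind(qx, qy))
  sx <- floor(src[, 1]); sy <- floor(src[, 2])
  ok <- !is.na(sx) & sx >= 0 & sx < W & sy >= 0 & sy < H
  vals <- integer(length(qx))
  vals[ok] <- map$labels[cbind(sy[ok] + 1L, sx[ok] + 1L)]
  out <- matrix(vals, nrow = H, ncol = W)
  region_map(out, map$granularity)
}

#' Refine a linearly registered region map with anchor displacements
#'
#' Convenience wrapper: builds the deformation field from the record and
#' applies it to the map.
#'
#' @param map A [region_map] (the linearly registered atlas plate).
#' @param rec A [deformation_record] or n x 4 anchor matrix.
#' @return The refined [region_map].
#' @export
refine_section <- function(map, rec) {
  if (!inherits(rec, "deformation_record")) {
    rec <- deformation_record(rec, map$width, map$height)
  }
  apply_deformation(map, build_deformation(rec))
}
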