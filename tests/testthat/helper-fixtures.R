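# Shared in-code fixtures: a 5-node ontology, tiny labeled volumes, and a
# brute-force plane sampler used as the independent oracle for slicing.

five_node_tree <- function() {
  structure_tree(data.frame(
    id = c(1L, 2L, 3L, 4L, 5L),
    name = c("R", "A", "B", "a1", "a2"),
    acronym = c("R", "A", "B", "a1", "a2"),
    parent_id = c(NA, 1L, 1L, 2L, 2L)))
}

constant_volume <- function(label = 7L, n = 8L, voxel_size = 25) {
  annotation_volume(array(label, dim = c(n, n, n)), voxel_size)
}

# two labels split at z = K (label lo for z < K, hi otherwise)
split_volume <- function(n = 10L, K = 5L, lo = 4L, hi = 5L) {
  lab <- array(lo, dim = c(n, n, n))
  lab[, , (K + 1):n] <- hi
  annotation_volume(lab, 25)
}

# independent per-pixel plane sampler: same stated contract as
# slice_annotation but written as an explicit scalar loop
brute_force_slice <- function(vol, a) {
  d <- dim(vol$labels)
  out <- matrix(0L, a$height, a$width)
  for (y in seq_len(a$height) - 1L) {
    for (x in seq_len(a$width) - 1L) {
      p <- a$o + a$u * (x + 0.5) / a$width + a$v * (y + 0.5) / a$height
      v <- round(p)
      if (all(v >= 0) && all(v < d)) {
        out[y + 1L, x + 1L] <- vol$labels[v[1] + 1L, v[2] + 1L, v[3] + 1L]
      }
    }
  }
  out
}

# brute-force Pearson r and two-sided p via the covariance formula
brute_force_pearson <- function(x, y, df = length(x) - 2L) {
  n <- length(x)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  r <- sxy / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tt <- r * sqrt(df / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(tt), df, lower.tail = FALSE))
}

# hand-coded Benjamini-Hochberg step-up
brute_force_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(n)
  out[o] <- q
  out
}

small_marker_set <- function(n_acc, n_inacc, n_unc, region = 101L,
                             rater = "r1", brain = "b1") {
  labs <- c(rep("accurate", n_acc), rep("inaccurate", n_inacc),
            rep("uncertain", n_unc))
  n <- length(labs)
  marker_set(cbind(seq_len(n), seq_len(n)), rep(region, n), labs,
             brain = brain, rater = rater, spacing = 15)
}
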