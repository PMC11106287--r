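test_that("systematic random sampling grids have the lattice count", {
  # 100x100 at spacing 10: exactly 100 points for every offset
  for (seed in c(1, 2, 77, 1234)) {
    g <- make_grid(100, 100, 10, seed = seed)
    expect_equal(nrow(g), 100L)
    off <- attr(g, "offset")
    expect_true(all(off >= 0 & off < 10))
  }
  # spacing larger than the image: only the offset point fits
  expect_equal(nrow(make_grid(100, 100, 150, seed = 3)), 1L)
  # determinism per seed
  expect_identical(make_grid(80, 60, 15, seed = 42),
                   make_grid(80, 60, 15, seed = 42))
  expect_error(make_grid(10, 10, 0), "spacing")
})

test_that("oracle rater applies the accurate/inaccurate/uncertain rules", {
  # two-band fixture: truth split in half, refined shifted by one band width
  truth <- region_map(rbind(matrix(101L, 10, 20), matrix(102L, 10, 20)),
                      "custom")
  refined_same <- truth
  grid <- make_grid(20, 20, 2, seed = 1)
  ms <- oracle_assess(refined_same, truth, grid)
  expect_true(all(ms$label == "accurate"))

  # shifted: the whole map reads 102 where truth says 101 in the top band
  refined_shift <- region_map(matrix(102L, 20, 20), "custom")
  ms2 <- oracle_assess(refined_shift, truth, grid)
  top <- ms2$y < 10
  expect_true(all(ms2$label[top] == "inaccurate"))
  expect_true(all(ms2$label[!top] == "accurate"))

  # background in truth makes a marker uncertain
  truth_bg <- region_map(matrix(0L, 20, 20), "custom")
  ms3 <- oracle_assess(refined_shift, truth_bg, grid)
  expect_true(all(ms3$label == "uncertain"))

  expect_error(oracle_assess(region_map(matrix(1L, 5, 5), "custom"),
                             truth, grid), "mismatch")
})

test_that("oracle accuracy is non-increasing with registration shift", {
  at <- generate_atlas(c(40, 40, 40), 6, 2, seed = 9)
  a <- section_anchoring(c(0, 0, 20), c(40, 0, 0), c(0, 40, 0), 80, 80)
  truth <- slice_annotation(at$volume, a)
  grid <- make_grid(80, 80, 5, seed = 4)
  global_acc <- function(shift) {
    labs <- truth$labels
    if (shift > 0) {
      shifted <- matrix(0L, nrow(labs), ncol(labs))
      shifted[, (shift + 1):ncol(labs)] <- labs[, 1:(ncol(labs) - shift)]
    } else shifted <- labs
    ms <- oracle_assess(region_map(shifted, "full"), truth, grid)
    sum(ms$label == "accurate") /
      sum(ms$label %in% c("accurate", "inaccurate"))
  }
  accs <- vapply(c(0, 2, 4, 8), global_acc, numeric(1))
  expect_equal(accs[1], 1)
  expect_true(all(diff(accs) <= 0))
})

test_that("marker files round-trip and reject unknown labels", {
  m <- marker_set(cbind(c(1.5, 8, 3), c(2, 4.5, 9)), c(101L, 101L, 102L),
                  c("accurate", "uncertain", "damage"),
                  brain = "b1", section = "s2", rater = "r3",
                  spacing = 15, seed = 7L)
  path <- withr::local_tempfile(fileext = ".json")
  save_markers(m, path)
  rt <- load_markers(path)
  expect_equal(rt$x, m$x)
  expect_equal(rt$label, m$label)
  expect_equal(attr(rt, "rater"), "r3")
  expect_equal(attr(rt, "spacing"), 15)

  writeLines(jsonlite::toJSON(list(brain = "b", markers = list(
    list(1, 2, 101, "bogus"))), auto_unbox = TRUE), path)
  expect_error(load_markers(path), "unknown marker label")
  # empty marker list round-trips
  save_markers(marker_set(NULL, integer(0), character(0)), path)
  expect_equal(nrow(load_markers(path)), 0)
})

test_that("accuracy and uncertainty scores follow the counting formulas", {
  s <- qc_score(small_marker_set(9, 1, 0))
  expect_equal(s$assessments$accuracy, 0.90)
  expect_equal(s$assessments$uncertainty, 0)

  # all-uncertain assessment: accuracy undefined, excluded from the mean
  s2 <- qc_score(list(small_marker_set(9, 1, 0, rater = "r1"),
                      small_marker_set(0, 0, 5, rater = "r2")))
  expect_true(is.na(s2$assessments$accuracy[2]))
  expect_equal(s2$assessments$uncertainty[2], 1)
  expect_equal(s2$regions$n_assessments, 1L)
  expect_equal(s2$regions$mean_accuracy, 0.90)

  # mean over assessments is unweighted
  s3 <- qc_score(list(small_marker_set(5, 0, 0, rater = "r1"),
                      small_marker_set(8, 2, 0, rater = "r2")))
  expect_equal(s3$regions$mean_accuracy, 0.9)
  expect_equal(s3$regions$n_assessments, 2L)
  expect_equal(s3$regions$sem, stats::sd(c(1, 0.8)) / sqrt(2))
})

test_that("scores round-trip to counts and partition the markers", {
  set.seed(11)
  ms <- lapply(1:4, function(i) {
    small_marker_set(sample(0:20, 1), sample(0:5, 1), sample(0:5, 1),
                     rater = paste0("r", i))
  })
  s <- qc_score(ms)
  a <- s$assessments
  # n_acc + n_inacc + n_unc equals on-section marker count per assessment
  for (i in seq_along(ms)) {
    row <- a[a$assessment == i, ]
    if (!nrow(row)) next
    expect_equal(row$n_acc + row$n_inacc + row$n_unc, nrow(ms[[i]]))
    # accuracy * (n_acc + n_inacc) recovers the integer count
    if (!is.na(row$accuracy)) {
      expect_equal(row$accuracy * (row$n_acc + row$n_inacc), row$n_acc)
    }
  }
})

test_that("damage fractions respect the strict 30 percent rule", {
  mk <- function(n_damage, n_intact) {
    labs <- c(rep("damage", n_damage), rep("accurate", n_intact))
    marker_set(cbind(seq_along(labs), rep(1, length(labs))),
               rep(0L, length(labs)), labs, section = "s")
  }
  d31 <- assess_damage(mk(31, 69))
  expect_equal(d31$damage_fraction, 0.31)
  expect_true(d31$excluded)
  d30 <- assess_damage(mk(30, 70))
  expect_equal(d30$damage_fraction, 0.30)
  expect_false(d30$excluded)  # strictly more than 30% excludes
  d0 <- assess_damage(mk(0, 50))
  expect_equal(d0$damage_fraction, 0)
  expect_false(d0$excluded)
  expect_error(assess_damage(mk(0, 0)), "no on-section")
  expect_error(assess_damage(small_marker_set(1, 1, 0)), "damage markup")
})

test_that("damage markup over a mask reproduces the mask fraction", {
  mask <- matrix(FALSE, 60, 60)
  mask[1:30, ] <- TRUE  # top half damaged
  m <- damage_markup(mask, spacing = 5, seed = 2)
  rep <- assess_damage(m)
  expect_equal(rep$damage_fraction, 0.5, tolerance = 0.1)
  expect_true(rep$excluded)
})

test_that("QC reports render unassigned regions and region names", {
  tr <- five_node_tree()
  ms <- list(small_marker_set(4, 1, 0, region = 2L),
             small_marker_set(3, 0, 2, region = UNASSIGNED))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_qc_report(qc_score(ms), path, tree = tr)
  rep <- utils::read.delim(path)
  expect_true("Unassigned" %in% rep$region_name)
  expect_true("A" %in% rep$region_name)
})
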