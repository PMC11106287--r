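test_that("downscaling is area-preserving and sizes correctly", {
  img <- matrix(runif(100 * 100), 100, 100)
  expect_equal(downscale(img, 1), img)
  out <- downscale(img, 0.4)
  expect_equal(dim(out), c(40, 40))
  # area interpolation preserves mean intensity
  expect_equal(mean(out), mean(img), tolerance = 0.01)
  # stain-specific defaults
  expect_equal(dim(downscale(img, stain = "AB1-42")), c(20, 20))
  expect_error(downscale(img, 0), "factor")
  expect_error(downscale(img, 1.5), "factor")
})

test_that("threshold segmentation recovers planted blobs", {
  img <- matrix(0.1, 50, 50)
  expect_true(!any(threshold_segment(img, 0.5)$mask))
  expect_true(all(threshold_segment(img, 0.05)$mask))
  blob <- matrix(FALSE, 50, 50)
  blob[10:20, 30:40] <- TRUE
  img[blob] <- 0.9
  expect_identical(threshold_segment(img, 0.5)$mask, blob)
  # invert flag for dark-on-light stains
  expect_identical(threshold_segment(img, 0.5, invert = TRUE)$mask, !blob)
})

test_that("section loads follow the percent-coverage formula", {
  labs <- matrix(0L, 20, 20)
  labs[1:10, 1:20] <- 101L   # 200 px region
  mask <- matrix(FALSE, 20, 20)
  mask[1:5, 1:10] <- TRUE    # 50 stained px inside region 101
  sl <- section_load(region_map(labs, "custom"), segmentation_image(mask))
  expect_equal(sl$region_id, 101L)
  expect_equal(sl$region_pixels, 200L)
  expect_equal(sl$stained_pixels, 50L)
  expect_equal(sl$load, 25.0)
  # excluding the whole region removes it from the output
  excl <- matrix(FALSE, 20, 20); excl[1:10, ] <- TRUE
  expect_equal(nrow(section_load(region_map(labs, "custom"),
                                 segmentation_image(mask), excl)), 0)
  expect_error(section_load(region_map(labs, "custom"),
                            segmentation_image(matrix(FALSE, 5, 5))),
               "mismatch")
})

test_that("section loads match a per-pixel brute-force tally", {
  set.seed(21)
  labs <- matrix(sample(c(0L, UNASSIGNED, 101L, 102L, 103L), 900, TRUE), 30, 30)
  mask <- matrix(runif(900) < 0.3, 30, 30)
  excl <- matrix(runif(900) < 0.2, 30, 30)
  sl <- section_load(region_map(labs, "custom"), segmentation_image(mask), excl)
  for (rid in c(101L, 102L, 103L)) {
    px <- labs == rid & !excl
    expect_equal(sl$region_pixels[sl$region_id == rid], sum(px))
    expect_equal(sl$stained_pixels[sl$region_id == rid], sum(mask & px))
  }
  # conservation: counted + background/unassigned/excluded = image pixels
  counted <- sum(sl$region_pixels)
  rest <- sum(labs == 0L | labs == UNASSIGNED | excl)
  expect_equal(counted + rest, 900L)
})

test_that("brain loads pool pixel counts across retained sections", {
  s1 <- data.frame(region_id = 101L, region_pixels = 100L,
                   stained_pixels = 10L, load = 10)
  s2 <- data.frame(region_id = 101L, region_pixels = 300L,
                   stained_pixels = 90L, load = 30)
  bl <- brain_load(list(s1, s2), brain = "b1", stain = "Iba1")
  expect_equal(bl$load, 25.0)  # pooled, not the 20.0 mean of section loads
  expect_equal(brain_load(list(s1))$load, 10.0)
  # damage exclusion drops the section from the pool
  expect_equal(brain_load(list(s1, s2), excluded = c(FALSE, TRUE))$load, 10.0)
  expect_error(brain_load(list(s1, s2), excluded = c(TRUE, TRUE)),
               "all sections excluded")
})

test_that("load differences subtract per matching row and antisymmetrize", {
  refined <- data.frame(brain = "b1", stain = "Iba1", region_id = c(101L, 102L),
                        region_pixels = c(10L, 10L), stained_pixels = c(1L, 2L),
                        load = c(12, 7))
  linear <- refined
  linear$load <- c(10, 9)
  d <- load_difference(refined, linear)
  expect_equal(d$difference, c(2, -2))
  expect_equal(load_difference(refined, refined)$difference, c(0, 0))
  expect_equal(load_difference(linear, refined)$difference, -d$difference)
  bad <- linear[1, , drop = FALSE]
  expect_error(load_difference(refined, bad), "same")
})

test_that("loads are invariant to section and region ordering", {
  set.seed(3)
  secs <- lapply(1:4, function(i) {
    data.frame(region_id = sample(c(101L, 102L, 103L)),
               region_pixels = sample(50:150, 3),
               stained_pixels = sample(0:40, 3), load = NA)
  })
  a <- brain_load(secs)
  b <- brain_load(rev(secs))
  expect_equal(a, b)
})

test_that("group comparison detects a planted age shift and applies FDR", {
  set.seed(17)
  brains <- sprintf("b%02d", 1:20)
  meta <- data.frame(brain = brains,
                     age_group = rep(c("6m", "14m"), each = 10),
                     strain = rep(c("s1", "s2", "s3", "s4", "s5"), 4))
  # region 101: age shift of 3 sd; region 102: null
  loads <- do.call(rbind, lapply(c(101L, 102L), function(rid) {
    mu <- if (rid == 101L) ifelse(meta$age_group == "14m", 8, 5) else 5
    data.frame(brain = brains, stain = "GFAP", region_id = rid,
               region_pixels = 1000L, stained_pixels = 0L,
               load = rnorm(20, mu, 1))
  }))
  res <- compare_groups(loads, meta)
  expect_lt(res$p_age_group[res$region_id == 101L], 0.01)
  expect_gt(res$p_age_group[res$region_id == 102L], 0.01)
  # single region: FDR-corrected p equals the raw p
  one <- compare_groups(loads[loads$region_id == 101L, ], meta)
  expect_equal(one$q_age_group, one$p_age_group)
  # degenerate factor
  meta_one <- meta; meta_one$age_group <- "6m"
  expect_error(compare_groups(loads, meta_one), "fewer than two levels")
})

test_that("paired method comparison flags shifted regions only", {
  set.seed(8)
  base <- data.frame(brain = sprintf("b%02d", 1:12), stain = "NeuN",
                     region_id = 101L, region_pixels = 100L,
                     stained_pixels = 10L, load = rnorm(12, 10, 1))
  shifted <- base; shifted$load <- base$load + 1.5
  same2 <- base; same2$region_id <- 102L
  ref <- rbind(shifted, same2)
  lin <- rbind(base, same2)
  res <- compare_methods(ref, lin)
  expect_lt(res$p[res$region_id == 101L], 0.05)
  expect_equal(res$p[res$region_id == 102L], 1)
})

test_that("masks round-trip through PNG", {
  mask <- matrix(runif(40 * 30) > 0.5, 30, 40)
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(mask, path)
  expect_identical(read_mask_png(path), mask)
})

test_that("load tables round-trip through the report TSV", {
  bl <- data.frame(brain = "b1", stain = "Iba1", region_id = c(101L, UNASSIGNED),
                   region_pixels = c(200L, 50L), stained_pixels = c(50L, 5L),
                   load = c(25, 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_load_table(bl, path)
  rt <- read_load_table(path)
  expect_equal(rt$load, bl$load)
  expect_equal(rt$region_id, bl$region_id)
})
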