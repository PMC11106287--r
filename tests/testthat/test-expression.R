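test_that("ERC filtering applies both strict inequalities", {
  counts <- rbind(g1 = c(11, 11, 0, 0),    # exactly 50% -> fails (strict)
                  g2 = c(11, 11, 11, 0),   # 75% -> passes
                  g3 = c(10, 10, 10, 10),  # never exceeds 10 -> fails
                  g4 = c(11, 11, 11, 11))
  kept <- filter_genes(counts)
  expect_setequal(rownames(kept), c("g2", "g4"))
  expect_error(filter_genes(matrix(numeric(0), 0, 0)), "empty")
  expect_error(filter_genes(matrix(-1, 1, 2)), "non-negative")
})

test_that("median-of-ratios size factors have the closed form", {
  counts <- rbind(g1 = c(10, 20), g2 = c(30, 60), g3 = c(5, 10))
  norm <- normalize_counts(counts, log = FALSE)
  sf <- attr(norm, "size_factors")
  # sample 2 = 2x sample 1: size factors in ratio 2, normalized equal
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(unname(norm[, 1]), unname(norm[, 2]))
  # all-equal matrix: size factors all 1
  eq <- matrix(7, 3, 4, dimnames = list(paste0("g", 1:3), NULL))
  expect_equal(unname(attr(normalize_counts(eq), "size_factors")),
               rep(1, 4))
  # invariance to gene order
  set.seed(5)
  m <- matrix(rpois(60, 50) + 1, 10, 6)
  perm <- m[sample(10), ]
  expect_equal(attr(normalize_counts(m), "size_factors"),
               attr(normalize_counts(perm), "size_factors"))
  expect_error(normalize_counts(rbind(c(0, 1), c(2, 0))), "all-positive")
})

test_that("size factors agree with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  counts <- matrix(rnbinom(200 * 8, mu = 100, size = 10), 200, 8,
                   dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:8)))
  ours <- attr(normalize_counts(counts), "size_factors")
  dds <- DESeq2::DESeqDataSetFromMatrix(
    counts, data.frame(row.names = colnames(counts), g = factor(rep(1, 8))), ~1)
  ref <- DESeq2::sizeFactors(DESeq2::estimateSizeFactors(dds))
  expect_equal(unname(ours), unname(ref), tolerance = 1e-10)
})

test_that("plain correlations match the covariance-formula oracle", {
  set.seed(31)
  load <- rnorm(10)
  vals <- matrix(rnorm(100), 10, 10,
                 dimnames = list(paste0("g", 1:10), NULL))
  res <- correlate_load(load, vals)
  for (i in 1:10) {
    o <- brute_force_pearson(load, vals[i, ])
    expect_equal(res$r[i], o$r, tolerance = 1e-12)
    expect_equal(res$p[i], o$p, tolerance = 1e-12)
  }
  # exact linearity and degenerate genes
  vals2 <- rbind(lin = 2 * load + 1, const = rep(3, 10))
  res2 <- correlate_load(load, vals2)
  expect_equal(res2$r[1], 1)
  expect_true(is.na(res2$r[2]))
  expect_false(res2$defined[2])
  expect_error(correlate_load(load[1:2], vals[, 1:2]), "at least 3")
  expect_error(correlate_load(rep(1, 10), vals), "variance")
})

test_that("age adjustment centers within groups with n - k - 1 df", {
  # opposed group means: within each group gene tracks load exactly,
  # but the group means are offset in opposite directions
  load <- c(1, 2, 3, 4, 11, 12, 13, 14)
  grp <- rep(c("6m", "14m"), each = 4)
  gene <- c(1, 2, 3, 4, 1, 2, 3, 4)  # within-group identical to load
  vals <- rbind(g = gene)
  adj <- correlate_load_adjusted(load, vals, grp)
  un <- correlate_load(load, vals)
  expect_equal(adj$r[1], 1)
  expect_lt(un$r[1], 1)
  # df = n - k - 1
  expect_equal(adj$n, 8)
  expect_equal(adj$k, 2)
  # oracle: centered Pearson with adjusted df
  xc <- load - ave(load, grp)
  yc <- gene - ave(gene, grp)
  o <- brute_force_pearson(xc, yc, df = 8 - 2 - 1)
  expect_equal(adj$r[1], o$r, tolerance = 1e-12)
  expect_equal(adj$p[1], o$p, tolerance = 1e-12)
})

test_that("age-adjusted correlations match the brute-force oracle", {
  set.seed(13)
  load <- rnorm(10)
  grp <- rep(c("a", "b"), each = 5)
  vals <- matrix(rnorm(50), 5, 10, dimnames = list(paste0("g", 1:5), NULL))
  res <- correlate_load_adjusted(load, vals, grp)
  for (i in 1:5) {
    xc <- load - ave(load, grp)
    yc <- vals[i, ] - ave(vals[i, ], grp)
    o <- brute_force_pearson(xc, yc, df = 10 - 2 - 1)
    expect_equal(res$r[i], o$r, tolerance = 1e-12)
    expect_equal(res$p[i], o$p, tolerance = 1e-12)
  }
})

test_that("one age group reduces to plain Pearson with n - 2 df", {
  set.seed(14)
  load <- rnorm(12)
  vals <- matrix(rnorm(36), 3, 12, dimnames = list(paste0("g", 1:3), NULL))
  adj <- correlate_load_adjusted(load, vals, rep("6m", 12))
  un <- correlate_load(load, vals)
  expect_equal(adj$r, un$r, tolerance = 1e-12)
  expect_equal(adj$p, un$p, tolerance = 1e-12)  # df = n - 1 - 1 = n - 2
})

test_that("groups with identical means make both correlation paths agree", {
  set.seed(15)
  g <- rep(c("a", "b"), each = 10)
  load <- rnorm(20)
  load <- load - ave(load, g) + mean(load)      # equal group means
  vals <- matrix(rnorm(60), 3, 20, dimnames = list(paste0("g", 1:3), NULL))
  vals <- vals - t(apply(vals, 1, function(y) ave(y, g) - mean(y)))
  adj <- correlate_load_adjusted(load, vals, g)
  un <- correlate_load(load, vals)
  expect_equal(adj$r, un$r, tolerance = 1e-12)
})

test_that("within-group independence breaks spurious between-group correlation", {
  set.seed(16)
  n <- 200
  g <- rep(c("6m", "14m"), each = n / 2)
  shift <- ifelse(g == "14m", 5, 0)
  load <- shift + rnorm(n, sd = 0.5)
  gene <- shift + rnorm(n, sd = 0.5)   # driven by the group shift only
  vals <- rbind(g1 = gene)
  un <- correlate_load(load, vals)
  adj <- correlate_load_adjusted(load, vals, g)
  expect_gt(un$r[1], 0.8)
  expect_lt(abs(adj$r[1]), 0.1)
})

test_that("small age groups are dropped with a warning", {
  load <- c(1, 2, 3, 4, 9)
  vals <- matrix(rnorm(10), 2, 5, dimnames = list(c("g1", "g2"), NULL))
  expect_warning(res <- correlate_load_adjusted(load, vals,
                                                c("a", "a", "a", "a", "b")),
                 "dropping")
  expect_equal(res$n[1], 4)
})

test_that("BH adjustment matches the hand step-up and its properties", {
  p <- c(0.01, 0.02, 0.03, 0.04, 0.05)
  expect_equal(fdr_adjust(p), rep(0.05, 5))
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(rep(0.2, 4)), rep(0.2, 4))
  expect_error(fdr_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(19)
  for (i in 1:50) {
    pv <- runif(sample(2:40, 1))
    q <- fdr_adjust(pv)
    expect_equal(q, brute_force_bh(pv), tolerance = 1e-12)
    expect_true(all(q >= pv))                       # never decreases p
    o <- order(pv)
    expect_true(all(diff(q[o]) >= -1e-12))          # monotone in sorted order
    # BH rejections are a superset of Bonferroni rejections
    bonf <- pv * length(pv) < 0.05
    expect_true(all(!bonf | (q < 0.05)))
  }
})

test_that("genes are categorized by exclusive significance", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d", "e"),
                    p_unadj = c(0.01, 0.20, 0.01, 0.30, 0.01),
                    p_adj = c(0.20, 0.01, 0.01, 0.40, NA),
                    defined = c(TRUE, TRUE, TRUE, TRUE, FALSE))
  out <- categorize_correlations(rec)
  expect_equal(out$category,
               c("age_dependent", "age_independent", "both", "neither",
                 "neither"))
  pct <- attr(out, "category_pct")
  expect_equal(sum(pct), 100)
  expect_equal(unname(pct["neither"]), 40)
})

test_that("rankings export sorted and drop undefined coefficients", {
  rec <- data.frame(gene_id = c("a", "b", "c", "d"),
                    r_unadj = c(0.2, NA, 0.9, -0.5),
                    r_adj = c(0.1, 0.2, 0.3, 0.4))
  path <- withr::local_tempfile(fileext = ".tsv")
  export_ranking(rec, "r_unadj", path)
  rt <- utils::read.delim(path)
  expect_equal(rt$gene_id, c("c", "a", "d"))
  expect_equal(rt$coefficient, c(0.9, 0.2, -0.5))
})

test_that("counts and metadata TSVs round-trip", {
  counts <- matrix(5:16, 3, 4,
                   dimnames = list(c("g1", "g2", "g3"), paste0("s", 1:4)))
  storage.mode(counts) <- "integer"
  cpath <- withr::local_tempfile(fileext = ".tsv")
  write_counts(counts, cpath)
  expect_identical(read_counts(cpath), counts)
  meta <- data.frame(sample = paste0("s", 1:4), brain = paste0("b", 1:4),
                     age_group = c("6m", "6m", "14m", "14m"),
                     strain = "BXD1")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_sample_meta(meta, mpath)
  expect_equal(read_sample_meta(mpath), meta)
})
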