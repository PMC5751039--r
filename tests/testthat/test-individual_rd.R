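test_that("read centers are counted into both covering windows", {
  grid <- make_grid(10)           # chr1, 800/400, seqlength 4400
  sam <- tempfile(fileext = ".sam")
  # 100-bp read on [350,450): center 400 -> windows [0,800) and [400,1200)
  write_test_sam(sam, c(chr1 = 4400L), list(
    list(name = "r1", flag = 0L, chrom = "chr1", pos = 351L, cigar = "100M")))
  p <- count_raw_depth(sam, grid)
  expect_equal(p$depths, c(1, 1, rep(0, 8)))
  expect_equal(p$stage, "raw")

  # a center in the first half-window hits only window 1
  write_test_sam(sam, c(chr1 = 4400L), list(
    list(name = "r1", flag = 0L, chrom = "chr1", pos = 101L, cigar = "100M")))
  expect_equal(count_raw_depth(sam, grid)$depths[1:3], c(1, 0, 0))
})

test_that("the 0x504 flag mask removes unmapped/secondary/duplicate reads", {
  grid <- make_grid(10)
  sam <- tempfile(fileext = ".sam")
  write_test_sam(sam, c(chr1 = 4400L), list(
    list(name = "ok",  flag = 0L,    chrom = "chr1", pos = 1001L, cigar = "100M"),
    list(name = "sec", flag = 256L,  chrom = "chr1", pos = 1001L, cigar = "100M"),
    list(name = "dup", flag = 1024L, chrom = "chr1", pos = 1001L, cigar = "100M"),
    list(name = "p1",  flag = 99L,   chrom = "chr1", pos = 1001L, cigar = "100M"),
    list(name = "p2",  flag = 147L,  chrom = "chr1", pos = 1201L, cigar = "100M")))
  p <- count_raw_depth(sam, grid)
  # ok + both mates of the proper pair count; secondary and duplicate do not
  expect_equal(sum(p$depths), 3 * 2)   # each center falls in 2 windows

  write_test_sam(sam, c(chr1 = 4400L), list(
    list(name = "sec", flag = 256L, chrom = "chr1", pos = 1001L, cigar = "100M")))
  expect_error(count_raw_depth(sam, grid), "no usable reads")
})

test_that("absolute correction sums depths over linked windows", {
  grid <- make_grid(6)
  p <- make_profile(c(3, 5, 7, 2, 2, 2), grid, stage = "raw")
  rec <- structure(list(links = list(c(1L, 2L), c(1L, 2L), 3L,
                                     c(4L, 5L, 6L), c(4L, 5L, 6L), c(4L, 5L, 6L)),
                        window_size = 800L, similarity_threshold = 0.97,
                        max_hits = 20L, grid_index = grid$index),
                   class = "dup_record")
  a <- absolute_correction(p, rec)
  expect_equal(a$depths, c(8, 8, 7, 6, 6, 6))
  expect_equal(a$stage, "absolute")
  # conservation: sum over a link group = t * raw group sum
  expect_equal(sum(a$depths[1:2]), 2 * sum(p$depths[1:2]))
  expect_equal(sum(a$depths[4:6]), 3 * sum(p$depths[4:6]))
  # stage ordering is enforced
  expect_error(absolute_correction(a, rec), "raw")
})

test_that("GC correction applies the reference-bin ratio and fixes 40% windows", {
  grid <- make_grid(30)
  grid$gc <- rep(c(0.30, 0.40, 0.50), each = 10)
  p <- make_profile(rep(c(8, 12, 16), each = 10), grid, stage = "absolute")
  out <- gc_correction(p, grid, min_bin_windows = 5)
  # factor = mean(40% bin) / mean(own bin): 12/8, 1, 12/16
  expect_equal(out$depths, rep(12, 30))
  expect_equal(out$stage, "gc_corrected")
  expect_equal(out$gc_model$rd_reference, 12)
  # 40%-GC windows are fixed points
  expect_equal(out$depths[11:20], p$depths[11:20] * 1)

  # direct substitution: window of depth 4 in a bin with mean 7.6 is scaled
  # by RD40 / RDgc = 12 / 7.6
  p2 <- make_profile(c(4, rep(8, 9), rep(12, 20)), grid, stage = "absolute")
  out2 <- gc_correction(p2, grid, min_bin_windows = 5)
  expect_equal(out2$depths[1], 4 * 12 / 7.6)
})

test_that("a planted multiplicative GC bias is flattened within 2%", {
  set.seed(31)
  n <- 3000
  grid <- make_grid(n)
  grid$gc <- sample(seq(0.25, 0.55, by = 0.01), n, replace = TRUE)
  bias <- function(gc) 1 - 1.5 * (gc - 0.4)^2 * 10   # smooth unimodal, peak at 0.4
  lambda <- 160
  depths <- rpois(n, lambda * bias(grid$gc))
  p <- make_profile(depths, grid, stage = "absolute")
  out <- gc_correction(p, grid, min_bin_windows = 30)
  bins <- round(grid$gc * 100)
  bin_means <- tapply(out$depths, bins, mean)
  ref_mean <- mean(out$depths[bins == 40])
  expect_true(all(abs(bin_means / ref_mean - 1) < 0.02))
})

test_that("sex correction doubles heterogametic sex-chromosome depth", {
  # grid with two chromosomes and one scaffold
  step <- 400L
  n1 <- 20L; nx <- 10L; ns <- 4L
  df <- data.frame(
    index = 1:(n1 + nx + ns),
    chrom = rep(c("chr1", "X", "scaf1"), c(n1, nx, ns)),
    start = c((0:(n1 - 1)) * step, (0:(nx - 1)) * step, (0:(ns - 1)) * step),
    gc = 0.4, gap = 0)
  df$end <- df$start + 800L
  grid <- structure(df[, c("index", "chrom", "start", "end", "gc", "gap")],
                    window_size = 800L, step = step,
                    seqlengths = c(chr1 = (n1 + 1) * step, X = (nx + 1) * step,
                                   scaf1 = (ns + 1) * step),
                    class = c("window_grid", "data.frame"))
  d <- c(rep(10, n1), rep(5, nx), rep(10, ns))
  p <- make_profile(d, grid, stage = "gc_corrected")
  out <- sex_correction(p, grid, "X", placed = c("chr1", "X"))
  expect_equal(out$sex, "heterogametic")
  expect_equal(out$depths[grid$chrom == "X"], rep(10, nx))
  expect_equal(out$depths[grid$chrom == "scaf1"], rep(10, ns))

  # ratio 1.0: homogametic, unchanged
  p2 <- make_profile(rep(10, n1 + nx + ns), grid, stage = "gc_corrected")
  out2 <- sex_correction(p2, grid, "X", placed = c("chr1", "X"))
  expect_equal(out2$sex, "homogametic")
  expect_equal(out2$depths, p2$depths)

  # ratio exactly 0.6 is not below the threshold
  d3 <- c(rep(10, n1), rep(6, nx), rep(10, ns))
  p3 <- make_profile(d3, grid, stage = "gc_corrected")
  out3 <- sex_correction(p3, grid, "X", placed = c("chr1", "X"))
  expect_equal(out3$sex, "homogametic")
  expect_equal(out3$depths[grid$chrom == "X"], rep(6, nx))

  expect_error(sex_correction(p, grid, "chrZ"), "available")
})

test_that("normalization divides by the global median", {
  grid <- make_grid(3)
  p <- make_profile(c(8, 16, 4), grid, stage = "gc_corrected")
  out <- normalize_depth(p)
  expect_equal(out$depths, c(1, 2, 0.5))
  expect_equal(out$stage, "normalized")

  p2 <- make_profile(rep(7, 3), grid, stage = "gc_corrected")
  expect_equal(normalize_depth(p2)$depths, rep(1, 3))

  p0 <- make_profile(rep(0, 3), grid, stage = "gc_corrected")
  expect_error(normalize_depth(p0), "median")
})

test_that("normalized diploid coverage concentrates near 1", {
  set.seed(32)
  grid <- make_grid(2000)
  lambda <- 20 * 800 / 100
  p <- make_profile(rpois(2000, lambda), grid, stage = "gc_corrected")
  out <- normalize_depth(p)
  expect_true(abs(median(out$depths) - 1) <= 1e-6)
  expect_gt(mean(out$depths >= 0.75 & out$depths <= 1.25), 0.95)
})

test_that("the intermediate profile file round-trips losslessly", {
  grid <- make_grid(50)
  set.seed(33)
  p <- make_profile(rpois(50, 160) / 157.3, grid, id = "ind7")
  p$sex <- "heterogametic"
  path <- tempfile(fileext = ".rd.tsv")
  write_profile(p, grid, path)
  q <- read_profile(path, grid)
  expect_identical(q$depths, p$depths)    # bitwise
  expect_equal(q$sample_id, "ind7")
  expect_equal(q$sex, "heterogametic")
  expect_equal(q$stage, "normalized")

  grid400 <- make_grid(50, window = 400L)
  expect_error(read_profile(path, grid400), "window_size")
})

test_that("depth smearing over an assembled duplication is undone by correction", {
  # two identical assembly copies: reads split between them (~half depth each);
  # a collapsed locus (one assembly copy, two real copies) doubles instead
  set.seed(34)
  n <- 400
  grid <- make_grid(n)
  lambda <- 160
  d <- rpois(n, lambda)
  smeared <- 101:110; smeared2 <- 201:210   # the two assembly copies
  collapsed <- 301:310
  d[c(smeared, smeared2)] <- rpois(20, lambda / 2)   # truth CN 2, split
  d[collapsed] <- rpois(10, 2 * lambda)              # truth CN 4, piled up
  p <- make_profile(d, grid, stage = "raw")
  links <- as.list(seq_len(n))
  for (k in seq_along(smeared)) {
    links[[smeared[k]]] <- c(smeared[k], smeared2[k])
    links[[smeared2[k]]] <- c(smeared[k], smeared2[k])
  }
  rec <- structure(list(links = links, window_size = 800L,
                        similarity_threshold = 0.97, max_hits = 20L,
                        grid_index = grid$index), class = "dup_record")
  raw_norm <- normalize_depth(make_profile(d, grid, stage = "gc_corrected"))
  corr <- normalize_depth(absolute_correction(p, rec))
  # before correction the assembled copies sit near 0.5; after, near 1
  expect_lt(mean(raw_norm$depths[smeared]), 0.65)
  expect_gt(mean(corr$depths[smeared]), 0.85)
  expect_lt(abs(mean(corr$depths[smeared]) - 1), 0.15)
  # the collapsed locus reads ~2 with or without correction
  expect_lt(abs(mean(corr$depths[collapsed]) - 2), 0.3)
})
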