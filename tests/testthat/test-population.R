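test_that("matrix assembly records per-sample statistics and rejects mismatches", {
  grid <- make_grid(20)
  set.seed(41)
  depth <- matrix(rpois(5 * 20, 160) / 160, nrow = 5)
  pm <- make_pm(depth, grid)
  expect_equal(dim(pm$depth), c(5L, 20L))
  # summary statistics equal brute-force recomputation
  for (i in 1:5) {
    expect_equal(unname(pm$mean[i]), mean(depth[i, ]))
    expect_equal(unname(pm$sd[i]), sd(depth[i, ]))
  }
  # identical profiles give identical rows
  pm2 <- make_pm(matrix(rep(depth[1, ], 3), nrow = 3, byrow = TRUE), grid)
  expect_true(all(pm2$depth[1, ] == pm2$depth[2, ]))

  p_short <- make_profile(rep(1, 10), make_grid(10), id = "odd")
  expect_error(assemble_matrix(list(make_profile(depth[1, ], grid), p_short),
                               grid), "odd")
  expect_error(assemble_matrix(list(make_profile(depth[1, ], grid)), grid),
               "at least 2")
})

test_that("individual candidate flags follow both the SD and empirical bounds", {
  grid50 <- make_grid(50)
  probe <- function(depth_val, mode = "outbred") {
    set.seed(42)
    d <- rnorm(50, 1, 0.1)       # sample mean ~1, sd ~0.1
    d[25] <- depth_val
    pm <- make_pm(rbind(d, rep(1, 50)), grid50, mode = mode)
    unname(pm$flags[1, 25])
  }
  expect_equal(probe(0.50), -1L)   # < mean-2sd and < 0.65
  expect_equal(probe(1.30), 0L)    # passes the sd rule but not 1.35
  expect_equal(probe(0.10), -2L)   # hom loss in both modes
  expect_equal(probe(0.10, "selfbred"), -2L)
  expect_equal(probe(1.90), 2L)    # hom gain
  expect_equal(probe(1.50), 1L)    # het gain
  expect_equal(probe(0.50, "selfbred"), 0L)  # 0.65 bound raised to 0.25
  expect_equal(probe(0.66), 0L)    # above the empirical bound
})

test_that("flags are monotone in depth", {
  grid <- make_grid(40)
  set.seed(43)
  d <- rnorm(40, 1, 0.08)
  pm <- make_pm(rbind(d, rep(1, 40)), grid)
  f0 <- pm$flags[1, ]
  for (delta in c(0.05, 0.2, 0.6)) {
    pm2 <- make_pm(rbind(d + delta, rep(1, 40)), grid)
    expect_true(all(pm2$flags[1, ] >= f0))
  }
})

test_that("population window selection follows allele frequency and hom counts", {
  grid <- make_grid(100)
  n <- 100
  # window 1: 5 het carriers (AF 0.025); window 2: 10 het (AF 0.05);
  # window 3: 2 hom gains; window 4: 1 het
  set.seed(40)
  depth <- matrix(rnorm(n * 100, 1, 0.01), n, 100)
  depth[1:5, 1] <- 0.4
  depth[1:10, 2] <- 0.4
  depth[1:2, 3] <- 1.9
  depth[1, 4] <- 0.4
  pm <- make_pm(depth, grid)
  pm <- select_population_windows(pm)
  expect_equal(unname(pm$af[1:4]), c(5 / 200, 10 / 200, 4 / 200, 1 / 200))
  expect_equal(unname(pm$candidate[1:4]), c(FALSE, TRUE, TRUE, FALSE))
  expect_false(any(pm$candidate[5:100]))
  pm2 <- select_population_windows(pm, keep_all_het = TRUE)
  expect_true(all(pm2$candidate[1:4]))
})

test_that("adjacent-window correlation uses the Student t test", {
  grid <- make_grid(10)
  set.seed(44)
  n <- 12
  x <- rnorm(n, 1, 0.2)
  depth <- matrix(rnorm(n * 10, 1, 0.001), n, 10)
  depth[, 3] <- x
  depth[, 5] <- x                      # identical nonoverlapping columns
  pm <- make_pm(depth, grid)
  res <- adjacent_correlation(pm, 3, 5)
  expect_equal(res$r, 1)
  expect_true(res$significant)

  # closed form: r = 0.9, n = 12 -> t ~ 6.53, p << 0.01
  y <- x * 0.9 + sqrt(1 - 0.81) * rnorm(n, 0, 0.2)
  r <- cor(x, y)
  t_exp <- r * sqrt(n - 2) / sqrt(1 - r^2)
  p_exp <- 2 * pt(-abs(t_exp), n - 2)
  depth[, 7] <- y
  pm <- make_pm(depth, grid)
  res2 <- adjacent_correlation(pm, 3, 7)
  expect_equal(res2$r, r)
  expect_equal(res2$p, p_exp)
  # cross-check against the standard test
  expect_equal(res2$p, cor.test(x, y)$p.value, tolerance = 1e-12)

  # constant column: undefined r, not significant by convention
  depth[, 9] <- 1
  pm <- make_pm(depth, grid)
  expect_false(adjacent_correlation(pm, 3, 9)$significant)
  expect_true(is.na(adjacent_correlation(pm, 3, 9)$r))

  expect_error(adjacent_correlation(make_pm(depth[1:3, ], grid), 3, 5), ">= 4")
  expect_error(adjacent_correlation(pm, 3, 4), "overlap")
})

test_that("region definition enforces the run and skip rules", {
  nw <- 200
  grid <- make_grid(nw)
  n <- 10
  mk_pm_runs <- function(cand_cols, carrier_depth = 0.4) {
    depth <- matrix(1, n, nw)
    set.seed(45)
    depth <- depth + matrix(rnorm(n * nw, 0, 0.01), n, nw)
    # same 4 carriers in every candidate window -> correlated columns
    for (j in cand_cols) depth[1:4, j] <- carrier_depth
    pm <- make_pm(depth, grid)
    select_population_windows(pm, min_af = 0.05)
  }
  # 5 consecutive candidates -> one call with 5 members
  pm <- mk_pm_runs(6:10)
  cs <- define_cnvrs(pm)
  expect_equal(nrow(cs$calls), 1L)
  expect_equal(cs$calls$n_windows, 5L)
  expect_equal(cs$calls$type, "loss")
  expect_equal(c(cs$calls$start, cs$calls$end),
               c(grid$start[6], grid$end[10]))

  # C,C,N,C,C: one call, 4 members, the skipped window excluded from depth
  pm2 <- mk_pm_runs(c(6, 7, 9, 10))
  cs2 <- define_cnvrs(pm2)
  expect_equal(nrow(cs2$calls), 1L)
  expect_equal(cs2$calls$n_windows, 4L)
  expect_equal(cs2$members[[1]], c(6L, 7L, 9L, 10L))
  expect_equal(unname(cs2$depth[1, 1]),
               median(pm2$depth[1, c(6, 7, 9, 10)]))

  # C,C,N,N,C,C: two fragments below the run rule -> nothing
  pm3 <- mk_pm_runs(c(5, 6, 9, 10))
  expect_equal(nrow(define_cnvrs(pm3)$calls), 0L)

  # two skips must be at least 4 windows apart
  pm4 <- mk_pm_runs(c(4, 5, 7, 8, 10, 11, 12))   # skips at 6 and 9: too close
  cs4 <- define_cnvrs(pm4)
  expect_true(all(cs4$calls$n_windows < 7L))
})

test_that("region definition is invariant to sample order and merge is idempotent", {
  grid <- make_grid(200)
  set.seed(46)
  n <- 12
  depth <- 1 + matrix(rnorm(n * 200, 0, 0.02), n, 200)
  depth[1:5, 8:14] <- 0.45
  depth[1:5, 20:26] <- 1.8
  pm <- select_population_windows(
    flag_individual_candidates(make_pm(depth, grid)))
  cs <- define_cnvrs(pm)
  perm <- sample(n)
  pm_perm <- select_population_windows(
    flag_individual_candidates(make_pm(depth[perm, ], grid)))
  cs_perm <- define_cnvrs(pm_perm)
  expect_equal(cs$calls[, c("chrom", "start", "end", "type", "n_windows", "af")],
               cs_perm$calls[, c("chrom", "start", "end", "type", "n_windows", "af")])

  m1 <- merge_adjacent_cnvrs(cs, pm)
  m2 <- merge_adjacent_cnvrs(m1, pm)
  expect_equal(m1$calls, m2$calls)
})

test_that("adjacent calls merge only when close and correlated", {
  grid <- make_grid(300)
  n <- 12
  build <- function(second_block_depths = NULL) {
    set.seed(47)
    depth <- 1 + matrix(rnorm(n * 300, 0, 0.01), n, 300)
    depth[1:5, 10:19] <- 0.45          # call A: [3600,8000), 4400 bp
    if (is.null(second_block_depths)) depth[1:5, 25:34] <- 0.45
    else depth[, 25:34] <- second_block_depths
    pm <- select_population_windows(
      flag_individual_candidates(make_pm(depth, grid)))
    pm
  }
  # gap between [3600,8000) and [9600,14000) is 1600 < 0.2 * 8800 = 1760,
  # carriers shared -> merged into one region
  pm <- build()
  cs <- define_cnvrs(pm)
  expect_equal(nrow(cs$calls), 2L)
  m <- merge_adjacent_cnvrs(cs, pm)
  expect_equal(nrow(m$calls), 1L)
  expect_equal(c(m$calls$start, m$calls$end), c(3600L, 14000L))

  # same geometry but uncorrelated second block -> no merge
  set.seed(48)
  other <- matrix(1, n, 10); other[6:10, ] <- 0.45   # different carriers
  pm2 <- build(other)
  cs2 <- define_cnvrs(pm2)
  m2 <- merge_adjacent_cnvrs(cs2, pm2)
  expect_equal(nrow(m2$calls), 2L)
})

test_that("the gap distance threshold is respected at the boundary", {
  grid <- make_grid(300)
  n <- 12
  set.seed(49)
  depth <- 1 + matrix(rnorm(n * 300, 0, 0.01), n, 300)
  # two 4000-bp regions separated by exactly 20% of their combined length:
  # the strict < rule blocks the merge however correlated they are
  depth[1:5, 11:19] <- 0.45            # [4000,8000)
  depth[1:5, 25:33] <- 0.45            # [9600,13600): gap 1600 == 0.2*8000
  pm <- select_population_windows(
    flag_individual_candidates(make_pm(depth, grid)))
  cs <- define_cnvrs(pm)
  expect_equal(nrow(cs$calls), 2L)
  m <- merge_adjacent_cnvrs(cs, pm)
  expect_equal(nrow(m$calls), 2L)      # distance rule blocks the merge
})
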