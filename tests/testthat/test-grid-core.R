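test_that("equipartition honours the remainder-first-bins convention", {
  p <- equipartition(c(3, 1, 4, 1.5, 9, 2.6), 3)
  expect_equal(diff(c(0, p$cuts, 6)), c(2, 2, 2))
  p <- equipartition(c(7, 3, 1, 4, 1.5, 9, 2.6), 3)
  expect_equal(diff(c(0, p$cuts, 7)), c(3, 2, 2))
})

test_that("equipartition snaps boundaries out of tie runs, merging bins", {
  p <- equipartition(c(1, 1, 1, 1, 2, 2), 3)
  expect_equal(p$cuts, 4L)
  expect_equal(p$n_bins, 2L)
  # enumeration: the only admissible cut is after rank 4
  expect_error(equipartition(rep(1, 5), 2), "all tied")
  expect_error(equipartition(1:6, 1), "invalid bin count")
  expect_error(equipartition(1:6, 7), "invalid bin count")
})

test_that("axis_partition validates its cuts", {
  expect_error(axis_partition(c(3, 2), 5), "strictly increasing")
  expect_error(axis_partition(5, 5), "cut < n")
  expect_silent(axis_partition(integer(0), 5))
})

test_that("build_grid counts points per cell and conserves the total", {
  p <- mic_pair(1:4, 1:4)
  g <- grid_table(p, axis_partition(2, 4), axis_partition(2, 4))
  expect_equal(g$counts, rbind(c(2, 0), c(0, 2)))
  expect_equal(g$total, 4)
  g1 <- grid_table(p, axis_partition(integer(0), 4),
                   axis_partition(integer(0), 4))
  expect_equal(as.vector(g1$counts), 4)
  expect_error(grid_table(p, axis_partition(2, 5), axis_partition(2, 4)),
               "inconsistent partition")
})

test_that("square-boundary cuts on the I-type pattern give the 13-square table", {
  p <- gen_itype(40, 0, seed = 99)
  # boundaries: x at 2 and 5-2 (ranks 160, 360), y at 1 and 4 (ranks 200, 320)
  g <- grid_table(p, axis_partition(c(160, 360), 520),
                  axis_partition(c(200, 320), 520))
  expect_equal(g$counts,
               rbind(c(80, 40, 80), c(0, 120, 0), c(80, 40, 80)))
  expect_equal(g$row_margins, c(200, 120, 200))
})

test_that("mutual information matches hand values and the summation oracle", {
  expect_equal(mutual_information(rbind(c(10, 0), c(0, 10))), 1.0)
  expect_equal(mutual_information(rbind(c(5, 5), c(5, 5))), 0.0)
  ch <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) if ((i + j) %% 2 == 0) ch[i, j] <- 40
  expect_equal(round(mutual_information(ch) / log2(5), 4), 0.3835)
  expect_error(mutual_information(matrix(0, 2, 2)), "degenerate")
  set.seed(31)
  for (r in 1:50) {
    m <- matrix(rpois(6, 3), nrow = sample(2:3, 1))
    if (sum(m) == 0) next
    expect_lt(abs(mutual_information(m) - oracle_mi(m)), 1e-12)
  }
})

test_that("normalized score reproduces the ideal block-pattern values", {
  it <- rbind(c(80, 40, 80), c(0, 120, 0), c(80, 40, 80))
  expect_equal(round(normalized_score(it, "min"), 4), 0.2561)
  expect_equal(normalized_score(rbind(c(10, 0), c(0, 10)), "min"), 1.0)
  expect_error(normalized_score(matrix(1:4, 1), "min"), "degenerate grid")
  expect_error(normalized_score(it, "equ"), "n_equ")
  expect_equal(normalized_score(it, "equ", n_equ = 3),
               normalized_score(it, "min"))
})

test_that("grid totals are conserved for random pairs and partitions", {
  set.seed(11)
  for (r in 1:25) {
    n <- sample(10:60, 1)
    p <- random_pair(n, tie_prob = 0.3)
    ax <- sample(2:4, 1)
    ay <- sample(2:4, 1)
    g <- grid_table(p, equipartition(p$x, ax), equipartition(p$y, ay))
    expect_equal(g$total, n)
    expect_equal(sum(g$counts), n)
    expect_equal(rowSums(g$counts), g$row_margins)
    expect_equal(colSums(g$counts), g$col_margins)
  }
})

test_that("grids are invariant under strictly increasing transforms", {
  set.seed(12)
  for (r in 1:10) {
    p <- random_pair(40)
    q <- mic_pair(exp(3 * p$x), p$y^3 + 2 * p$y)
    xp <- equipartition(p$x, 3)
    yp <- equipartition(p$y, 4)
    expect_identical(grid_table(p, xp, yp)$counts,
                     grid_table(q, xp, yp)$counts)
  }
})

test_that("adding a cut never decreases mutual information", {
  set.seed(13)
  for (r in 1:30) {
    p <- random_pair(sample(12:40, 1))
    admissible <- which(diff(sort(p$x)) != 0)
    k <- sample(2:3, 1)
    xp <- equipartition(p$x, k)
    yp <- equipartition(p$y, sample(2:3, 1))
    free <- setdiff(admissible, xp$cuts)
    if (!length(free)) next
    xp2 <- axis_partition(sort(c(xp$cuts, sample(free, 1))), p$n)
    i1 <- mutual_information(grid_table(p, xp, yp))
    i2 <- mutual_information(grid_table(p, xp2, yp))
    expect_gte(i2, i1 - 1e-12)
  }
})
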