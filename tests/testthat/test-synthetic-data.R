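test_that("generators are bit-for-bit reproducible under a seed", {
  expect_identical(gen_function_pair("cubic", 50, 0.3, seed = 9),
                   gen_function_pair("cubic", 50, 0.3, seed = 9))
  expect_identical(gen_independent_pair(50, seed = 9),
                   gen_independent_pair(50, seed = 9))
  expect_identical(gen_itype(10, 0.2, seed = 9), gen_itype(10, 0.2, seed = 9))
  expect_identical(gen_chequerboard(10, 0, seed = 9),
                   gen_chequerboard(10, 0, seed = 9))
  s1 <- gen_power_suite(30, n_amplitudes = 3, seed = 9)
  s2 <- gen_power_suite(30, n_amplitudes = 3, seed = 9)
  expect_identical(s1, s2)
})

test_that("functional generators honour their domains and formulas", {
  p <- gen_function_pair("parabolic", 200, seed = 4)
  expect_true(all(p$x >= -0.5 & p$x <= 0.5))
  expect_equal(p$y, 4 * p$x^2)
  p2 <- gen_function_pair("linear + period freq [medium]", 200, seed = 4)
  expect_equal(p2$y, sin(10 * pi * p2$x) + p2$x)
  p3 <- gen_function_pair("exponential", 200, seed = 4)
  expect_true(all(p3$x >= 0 & p3$x <= 10))
  expect_equal(p3$y, 2^p3$x)
  expect_error(gen_function_pair("nope", 100), "valid names")
  expect_length(mic_function_names(), 13)
})

test_that("noise models follow the stated forms", {
  p <- gen_function_pair("line", 2000, noise_level = 0.4, seed = 5)
  eps <- p$y - p$x
  expect_true(all(abs(eps) <= 0.4))
  expect_gt(max(abs(eps)), 0.3) # actually fills the band
  g <- gen_function_pair("line", 400, noise_level = 0.4, noise = "gaussian",
                         seed = 5)
  expect_gt(max(abs(g$y - g$x)), 0.4) # unbounded support
})

test_that("the I-type layout reproduces its ideal grid exactly", {
  p <- gen_itype(40, 0, seed = 21)
  expect_equal(p$n, 520)
  g <- grid_table(p, axis_partition(c(160, 360), 520),
                  axis_partition(c(200, 320), 520))
  expect_equal(g$counts, rbind(c(80, 40, 80), c(0, 120, 0), c(80, 40, 80)))
  expect_equal(round(normalized_score(g$counts, "min"), 4), 0.2561)
  expect_equal(gen_itype(1, 0, seed = 3)$n, 13)
})

test_that("the chequerboard occupies the 13 parity cells", {
  p <- gen_chequerboard(40, 0, seed = 22)
  expect_equal(p$n, 520)
  cells <- unique(cbind(floor(p$x), floor(p$y)))
  expect_equal(nrow(cells), 13)
  expect_true(all((cells[, 1] + cells[, 2]) %% 2 == 0))
  # unit-square boundaries in rank space: occupied-cell counts per row/column
  # alternate 120 / 80
  cuts <- cumsum(c(120, 80, 120, 80))
  g <- grid_table(p, axis_partition(cuts, 520), axis_partition(cuts, 520))
  expect_equal(sort(unique(as.vector(g$counts))), c(0, 40))
  expect_equal(sum(g$counts == 40), 13)
  # closed form for the ideal 13-cell table agrees with the table itself
  I <- (9 / 13) * log2(13 / 9) + (4 / 13) * log2(13 / 4)
  expect_equal(mutual_information(g), I, tolerance = 1e-12)
  expect_equal(round(I / log2(5), 4), 0.3835)
})

test_that("block-pattern points stay inside their squares", {
  for (gen in list(gen_itype, gen_chequerboard)) {
    p <- gen(5, 0, seed = 8)
    expect_true(all(p$x >= 0 & p$x <= 5))
    expect_true(all(p$y >= 0 & p$y <= 5))
  }
})

test_that("the power suite spans the stated amplitude grid", {
  s <- gen_power_suite(40, n_amplitudes = 25, seed = 6)
  amps <- sort(unique(vapply(s, `[[`, numeric(1), "amplitude")))
  expect_length(amps, 25)
  expect_equal(amps[1], 1)
  expect_equal(amps[25], 10)
  expect_equal(diff(log(amps)), rep(log(10) / 24, 24), tolerance = 1e-12)
  expect_setequal(unique(vapply(s, `[[`, character(1), "pattern")),
                  c("itype", "chequerboard", "linear", "parabolic",
                    "sinusoidal"))
  rec <- s[[1]]
  expect_s3_class(rec$dep, "mic_pair")
  expect_s3_class(rec$null, "mic_pair")
  # the null keeps the dependent marginals but breaks the link
  expect_equal(rec$null$n, 40)
})

test_that("independent-pair marginals pass a uniformity check", {
  set.seed(61)
  pv <- replicate(40, {
    p <- gen_independent_pair(100)
    min(stats::ks.test(p$x, "punif")$p.value,
        stats::ks.test(p$y, "punif")$p.value)
  })
  expect_gt(mean(pv > 0.01), 0.85)
})

test_that("equitability series carry realized R-squared tags", {
  e <- gen_equitability_series("line", n = 120, seed = 14)
  expect_length(e$series, 301)
  expect_equal(e$series[[1]]$b, 0)
  expect_equal(e$series[[1]]$r_squared, 1)
  b <- vapply(e$series, `[[`, numeric(1), "b")
  r2 <- vapply(e$series, `[[`, numeric(1), "r_squared")
  expect_lt(cor(b, r2), -0.8) # noise degrades R^2
})
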