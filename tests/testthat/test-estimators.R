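test_that("gated search refines a noiseless monotone pair", {
  p <- mic_pair(1:40, (1:40)^2)
  xp <- chi_gated_search(p, equipartition(p$y, 2), "x")
  expect_gte(xp$n_bins, 2)
  g <- grid_table(p, axis_partition(xp$cuts[1], 40), equipartition(p$y, 2))
  expect_equal(mutual_information(g), 1.0)
})

test_that("gated search returns a single bin when nothing passes the gate", {
  # perfectly balanced alternation: every x cut splits y evenly
  p <- mic_pair(1:12, rep(c(1, 2), 6))
  xp <- chi_gated_search(p, equipartition(p$y, 2), "x")
  expect_equal(xp$n_bins, 1L)
  # all-tied searched axis: no admissible candidate
  p2 <- mic_pair(rep(1, 10), 1:10)
  expect_equal(chi_gated_search(p2, equipartition(p2$y, 2), "x")$n_bins, 1L)
})

test_that("noiseless functional relationships score 1", {
  for (fn in c("line", "parabolic", "exponential", "non-Fourier freq [low]")) {
    p <- gen_function_pair(fn, 500, seed = 7 + nchar(fn))
    expect_equal(backmic(p)$score, 1.0, tolerance = 1e-9)
    expect_equal(chimic(p)$score, 1.0, tolerance = 1e-9)
    expect_equal(appmic(p)$score, 1.0, tolerance = 1e-9)
  }
})

test_that("estimators recover the I-type block structure", {
  p <- gen_itype(40, 0, seed = 2)
  b <- backmic(p)
  expect_equal(b$n_x, 3)
  expect_gte(b$score, 0.24)
  expect_lte(b$score, 0.31)
  cm <- chimic(p)
  expect_gte(cm$score, 0.14)
  expect_lte(cm$score, 0.22)
})

test_that("degenerate input yields score 0 with a warning", {
  expect_warning(r <- backmic(rep(2, 10), 1:10), "degenerate")
  expect_equal(r$score, 0)
  expect_equal(c(r$n_x, r$n_y), c(1L, 1L))
})

test_that("scores are symmetric in the two variables", {
  set.seed(51)
  for (r in 1:15) {
    p <- random_pair(sample(30:80, 1), tie_prob = 0.2)
    expect_equal(backmic(p$x, p$y)$score, backmic(p$y, p$x)$score,
                 tolerance = 1e-12)
    expect_equal(chimic(p$x, p$y)$score, chimic(p$y, p$x)$score,
                 tolerance = 1e-12)
  }
})

test_that("scores are invariant under strictly increasing transforms", {
  set.seed(52)
  for (r in 1:10) {
    p <- random_pair(60)
    s1 <- backmic(p$x, p$y)$score
    s2 <- backmic(exp(2 * p$x), atan(p$y) + p$y^3)$score
    expect_equal(s1, s2, tolerance = 1e-12)
    expect_equal(appmic(p$x, p$y)$score,
                 appmic(exp(2 * p$x), atan(p$y) + p$y^3)$score,
                 tolerance = 1e-12)
  }
})

test_that("all estimators stay within [0, 1] on varied inputs", {
  set.seed(53)
  for (r in 1:60) {
    n <- sample(20:120, 1)
    p <- switch(sample(3, 1),
                random_pair(n, tie_prob = 0.4),
                gen_function_pair("sinusoidal", n, noise_level = runif(1, 0, 2)),
                gen_independent_pair(n))
    for (m in c("backmic", "chimic", "appmic")) {
      s <- mic_estimate(p, method = m)$score
      expect_gte(s, 0)
      expect_lte(s, 1)
    }
  }
})

test_that("the back-search beats the equipartition on two-cluster structure", {
  set.seed(54)
  wins <- 0
  for (r in 1:100) {
    p <- fig8_config(60, frac = 0.3)
    tr <- attr(backmic(p, details = TRUE), "trace")
    row <- tr[tr$orientation == "y" & tr$n_equ == 2, ]
    expect_gte(row$back_score, row$m_score - 1e-9)
    if (row$back_score > row$m_score + 1e-9) wins <- wins + 1
  }
  expect_gt(wins, 50)
})

test_that("backmic dominates chimic on noisy linear data", {
  set.seed(55)
  b <- c <- numeric(100)
  for (r in 1:100) {
    p <- gen_function_pair("line", 500, noise_level = 0.35)
    b[r] <- backmic(p)$score
    c[r] <- chimic(p)$score
  }
  expect_gte(mean(b), mean(c))
})

test_that("appmic score increases weakly with alpha, unlike backmic", {
  set.seed(56)
  d_app <- d_back <- numeric(15)
  for (r in 1:15) {
    p <- gen_function_pair("parabolic", 300, noise_level = 0.35)
    d_app[r] <- appmic(p, config = search_config(alpha = 0.8))$score -
      appmic(p, config = search_config(alpha = 0.45))$score
    d_back[r] <- backmic(p, config = search_config(alpha = 0.8))$score -
      backmic(p, config = search_config(alpha = 0.45))$score
  }
  expect_gt(mean(d_app), 0)
  expect_lt(abs(mean(d_back)), abs(mean(d_app)))
})

test_that("the exhaustive oracle bounds the estimators on tiny samples", {
  expect_equal(exhaustive_mic_oracle(1:4, 1:4, max_bins = 2), 1.0)
  expect_equal(exhaustive_mic_oracle(1:8, rep(1, 8)), 0)
  expect_error(exhaustive_mic_oracle(1:20, 1:20), "refused")
  set.seed(57)
  checked <- 0
  for (r in 1:60) {
    p <- random_pair(sample(8:12, 1))
    b <- backmic(p, config = search_config(max_equ_bins = 4))
    if (max(b$n_x, b$n_y) > 4) next
    checked <- checked + 1
    expect_lte(b$score, exhaustive_mic_oracle(p, max_bins = 4) + 1e-9)
  }
  expect_gt(checked, 50)
})

test_that("estimators are deterministic for fixed input", {
  p <- gen_function_pair("sinusoidal", 200, noise_level = 0.5, seed = 3)
  expect_identical(backmic(p)$score, backmic(p)$score)
  expect_identical(appmic(p)$score, appmic(p)$score)
  r1 <- backmic(p)
  expect_identical(r1$x_partition$cuts, backmic(p)$x_partition$cuts)
})
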