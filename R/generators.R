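# Synthetic-data generators for every simulation design used in the
# benchmarks: the 13 noiseless functional relationships, independent pairs,
# the 'I'-type and chequerboard patterns, the five-pattern power suite, and
# the equitability noise series.

function_registry <- function() {
  list(
    "line" = list(domain = c(0, 1), f = function(x) x),
    "parabolic" = list(domain = c(-0.5, 0.5), f = function(x) 4 * x^2),
    "cubic" = list(domain = c(-1.3, 1.1),
                   f = function(x) 4 * x^3 + x^2 - 4 * x),
    "exponential" = list(domain = c(0, 10), f = function(x) 2^x),
    "non-Fourier freq [low]" = list(domain = c(0, 1),
                                    f = function(x) cos(4 * pi * x)),
    "non-Fourier freq [medium]" = list(domain = c(0, 1),
                                       f = function(x) cos(8 * pi * x)),
    "non-Fourier freq [high]" = list(domain = c(0, 1),
                                     f = function(x) cos(12 * pi * x)),
    "linear + period freq [low]" = list(
      domain = c(0, 1),
      f = function(x) sin(4 * (2 * x - 1)) / 5 + 11 * (2 * x - 1) / 10),
    "linear + period freq [medium]" = list(
      domain = c(0, 1), f = function(x) sin(10 * pi * x) + x),
    "linear + period freq [high]" = list(
      domain = c(0, 1),
      f = function(x) sin(10.6 * (2 * x - 1)) / 10 + 11 * (2 * x - 1) / 10),
    "varying freq [low]" = list(domain = c(0, 1),
                                f = function(x) cos(4 * pi * x * (1 + x))),
    "varying freq [medium]" = list(domain = c(0, 1),
                                   f = function(x) cos(8 * pi * x * (1 + x))),
    "varying freq [high]" = list(domain = c(0, 1),
                                 f = function(x) cos(12 * pi * x * (1 + x))),
    # extra benchmark function used by the noisy-correlation figures
    "sinusoidal" = list(domain = c(0, 1), f = function(x) sin(4 * pi * x))
  )
}

#' Names of the 13 benchmark functional relationships
#'
#' @param all If `TRUE`, include the extra `"sinusoidal"` benchmark function
#'   used by the noisy-correlation and robustness designs.
#' @return Character vector of names accepted by [gen_function_pair()].
#' @export
mic_function_names <- function(all = FALSE) {
  nm <- names(function_registry())
  if (all) nm else nm[nm != "sinusoidal"]
}

#' Generate a functional variable pair
#'
#' Draws `X` uniformly from the function's domain and sets
#' `Y = f(X) + noise`, where uniform noise is
#' `noise_level * (2 * runif(n) - 1)` and gaussian noise is
#' `noise_level * rnorm(n)`.
#'
#' @param name One of [mic_function_names()].
#' @param n Sample size (at least 4).
#' @param noise_level Noise amplitude (0 for noiseless).
#' @param noise `"uniform"` (symmetric on `[-level, level]`) or `"gaussian"`.
#' @param seed Optional integer seed for reproducibility.
#' @return A [mic_pair()].
#' @examples
#' gen_function_pair("parabolic", 100, seed = 1)
#' @export
gen_function_pair <- function(name, n, noise_level = 0,
                              noise = c("uniform", "gaussian"), seed = NULL) {
  noise <- match.arg(noise)
  reg <- function_registry()
  if (!name %in% names(reg))
    stop("unknown function `", name, "`; valid names: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  spec <- reg[[name]]
  local_seed(seed, {
    x <- runif(n, spec$domain[1], spec$domain[2])
    eps <- if (noise_level > 0) {
      if (noise == "uniform") noise_level * (2 * runif(n) - 1)
      else noise_level * rnorm(n)
    } else 0
    mic_pair(x, spec$f(x) + eps)
  })
}

#' Generate an independent uniform pair
#'
#' @param n Sample size (at least 4).
#' @param seed Optional integer seed.
#' @return A [mic_pair()] of two independent `uniform(0, 1)` draws.
#' @export
gen_independent_pair <- function(n, seed = NULL) {
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  local_seed(seed, mic_pair(runif(n), runif(n)))
}

# unit squares (lower-left corners) of the two block patterns
itype_squares <- function() {
  rbind(cbind(0:4, 0),          # bottom bar, 5 squares
        cbind(2, 1:3),          # central stem, 3 stacked squares
        cbind(0:4, 4))          # top bar, 5 squares
}

chequerboard_squares <- function() {
  sq <- expand.grid(x = 0:4, y = 0:4)
  sq <- sq[(sq$x + sq$y) %% 2 == 0, ]
  as.matrix(sq)
}

gen_square_pattern <- function(squares, points_per_square, noise_amp, seed) {
  if (points_per_square < 1)
    stop("`points_per_square` must be >= 1", call. = FALSE)
  local_seed(seed, {
    k <- nrow(squares)
    m <- points_per_square
    x <- rep(squares[, 1], each = m) + runif(k * m)
    y <- rep(squares[, 2], each = m) + runif(k * m)
    if (noise_amp > 0) y <- y + noise_amp * rnorm(k * m)
    mic_pair(x, y)
  })
}

#' Generate the 'I'-type block pattern
#'
#' 13 unit squares arranged as an I-beam (bottom bar of 5, central stem of 3
#' stacked squares, top bar of 5), each holding exactly `points_per_square`
#' uniform points; the ideal 3x3 grid on the square boundaries has row-wise
#' counts `(80, 40, 80), (0, 120, 0), (80, 40, 80)` at 40 points per square
#' and normalized mutual information 0.2561.
#'
#' @param points_per_square Points per square (40 gives n = 520).
#' @param noise_amp Gaussian noise amplitude `a` added to `Y` (`a * N(0,1)`).
#' @param seed Optional integer seed.
#' @return A [mic_pair()].
#' @export
gen_itype <- function(points_per_square = 40, noise_amp = 0, seed = NULL) {
  gen_square_pattern(itype_squares(), points_per_square, noise_amp, seed)
}

#' Generate the 5 x 5 chequerboard block pattern
#'
#' The 13 parity-occupied cells of a 5 x 5 board (corners occupied), each
#' with `points_per_square` uniform points; the ideal 5x5 grid normalizes to
#' 0.3835.
#'
#' @inheritParams gen_itype
#' @return A [mic_pair()].
#' @export
gen_chequerboard <- function(points_per_square = 40, noise_amp = 0,
                             seed = NULL) {
  gen_square_pattern(chequerboard_squares(), points_per_square, noise_amp,
                     seed)
}

# one draw of a power-suite pattern at noise amplitude a:
# block patterns sample squares uniformly (arbitrary n); the functional
# patterns use X = xi ~ N(0,1) and gaussian noise a * eta.
gen_pattern_pair <- function(pattern, n, a) {
  if (pattern %in% c("itype", "chequerboard")) {
    squares <- if (pattern == "itype") itype_squares()
               else chequerboard_squares()
    idx <- sample.int(nrow(squares), n, replace = TRUE)
    x <- squares[idx, 1] + runif(n)
    y <- squares[idx, 2] + runif(n)
  } else {
    x <- rnorm(n)
    y <- switch(pattern,
                linear = x,
                parabolic = 4 * (x - 0.5)^2,
                sinusoidal = sin(4 * pi * x),
                stop("unknown pattern `", pattern, "`", call. = FALSE))
  }
  if (a > 0) y <- y + a * rnorm(n)
  mic_pair(x, y)
}

power_patterns <- function() {
  c("itype", "chequerboard", "linear", "parabolic", "sinusoidal")
}

#' Generate the statistical-power simulation suite
#'
#' For each of the five dependence patterns ('I'-type, chequerboard, linear,
#' parabolic, sinusoidal) and each of `n_amplitudes` noise amplitudes spaced
#' logarithmically from 1 to 10, emits one dependent pair and one matched
#' independent null pair (a fresh dependent draw with `Y` permuted, so both
#' marginals are preserved).
#'
#' @param n Sample size per pair.
#' @param n_amplitudes Number of log-spaced amplitudes in `[1, 10]`.
#' @param seed Optional integer seed.
#' @param patterns Subset of the five pattern names.
#' @return A list with one element per (pattern, amplitude): fields
#'   `pattern`, `amplitude`, `dep`, `null`.
#' @export
gen_power_suite <- function(n, n_amplitudes = 25, seed = NULL,
                            patterns = power_patterns()) {
  if (n < 4) stop("`n` must be at least 4", call. = FALSE)
  patterns <- match.arg(patterns, power_patterns(), several.ok = TRUE)
  amplitudes <- 10 ^ seq(0, 1, length.out = n_amplitudes)
  local_seed(seed, {
    out <- list()
    for (pattern in patterns) {
      for (a in amplitudes) {
        dep <- gen_pattern_pair(pattern, n, a)
        nul <- gen_pattern_pair(pattern, n, a)
        nul <- mic_pair(nul$x, sample(nul$y))
        out[[length(out) + 1L]] <- list(pattern = pattern, amplitude = a,
                                        dep = dep, null = nul)
      }
    }
    out
  })
}

#' Generate an equitability noise series for one function
#'
#' One noiseless series plus 301 noisy series `Y = f(X) + eps`,
#' `eps ~ uniform(-b, b)` for `b = 0, 0.01, ..., 3`, each tagged with the
#' realized squared Pearson correlation between `f(X)` and `Y`.
#'
#' @param name One of [mic_function_names()].
#' @param n Sample size (default 500).
#' @param b_values Noise levels (default `seq(0, 3, by = 0.01)`).
#' @param seed Optional integer seed.
#' @return A list: `noiseless` (a [mic_pair()]) and `series`, a list of
#'   `(b, r_squared, pair)` records.
#' @export
gen_equitability_series <- function(name, n = 500,
                                    b_values = seq(0, 3, by = 0.01),
                                    seed = NULL) {
  reg <- function_registry()
  if (!name %in% names(reg))
    stop("unknown function `", name, "`; valid names: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  spec <- reg[[name]]
  local_seed(seed, {
    noiseless <- {
      x <- runif(n, spec$domain[1], spec$domain[2])
      mic_pair(x, spec$f(x))
    }
    series <- lapply(b_values, function(b) {
      x <- runif(n, spec$domain[1], spec$domain[2])
      fx <- spec$f(x)
      y <- fx + if (b > 0) runif(n, -b, b) else 0
      r2 <- if (stats::sd(y) == 0 || stats::sd(fx) == 0) 1
            else cor(fx, y)^2
      list(b = b, r_squared = r2, pair = mic_pair(x, y))
    })
    list(noiseless = noiseless, series = series)
  })
}
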