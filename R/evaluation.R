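# The comparison experiments as reusable, seed-reproducible procedures.

#' Statistical power against an empirical null
#'
#' The detection threshold is the `(1 - level)` empirical quantile of the
#' null scores (order statistic at `ceiling((1 - level) * m)`); power is the
#' fraction of dependent-pair scores strictly above it.
#'
#' @param dep_scores Scores on dependent pairs.
#' @param null_scores Scores on independent pairs.
#' @param level Significance level (default 0.05).
#' @return Power in `[0, 1]`.
#' @export
statistical_power <- function(dep_scores, null_scores, level = 0.05) {
  if (!length(dep_scores) || !length(null_scores))
    stop("`dep_scores` and `null_scores` must be nonempty", call. = FALSE)
  thr <- sort(null_scores)[ceiling((1 - level) * length(null_scores))]
  mean(dep_scores > thr)
}

#' Run the statistical-power experiment
#'
#' For each pattern and amplitude, scores `reps` dependent and `reps` matched
#' null pairs with the chosen estimator and computes [statistical_power()].
#'
#' @param method `"backmic"`, `"chimic"` or `"appmic"`.
#' @param n Sample size per pair (default 500).
#' @param reps Replicates per cell (default 500).
#' @param n_amplitudes Log-spaced amplitudes in `[1, 10]` (default 25).
#' @param patterns Subset of the five dependence patterns.
#' @param level Significance level (default 0.05).
#' @param config A [search_config()].
#' @param seed Integer seed.
#' @param amplitudes Optional explicit amplitude vector overriding
#'   `n_amplitudes` (for reduced desk-scale sweeps).
#' @return A data frame with columns `pattern`, `amplitude`, `power`, `reps`,
#'   `level`.
#' @export
run_power_experiment <- function(method = c("backmic", "chimic", "appmic"),
                                 n = 500, reps = 500, n_amplitudes = 25,
                                 patterns = power_patterns(), level = 0.05,
                                 config = search_config(), seed = NULL,
                                 amplitudes = NULL) {
  method <- match.arg(method)
  patterns <- match.arg(patterns, power_patterns(), several.ok = TRUE)
  amplitudes <- amplitudes %||% 10 ^ seq(0, 1, length.out = n_amplitudes)
  local_seed(seed, {
    rows <- list()
    for (pattern in patterns) {
      for (a in amplitudes) {
        dep <- numeric(reps)
        nul <- numeric(reps)
        for (r in seq_len(reps)) {
          dp <- gen_pattern_pair(pattern, n, a)
          np <- gen_pattern_pair(pattern, n, a)
          np <- mic_pair(np$x, sample(np$y))
          dep[r] <- mic_estimate(dp, method = method, config = config)$score
          nul[r] <- mic_estimate(np, method = method, config = config)$score
        }
        rows[[length(rows) + 1L]] <-
          data.frame(pattern = pattern, amplitude = a,
                     power = statistical_power(dep, nul, level),
                     reps = reps, level = level)
      }
    }
    do.call(rbind, rows)
  })
}

#' Run the equitability experiment
#'
#' For each function and noise level `b`, draws `reps` series
#' `Y = f(X) + uniform(-b, b)`, scores them, and records the mean realized
#' `R^2` between `f(X)` and `Y` together with the mean score.
#'
#' @inheritParams run_power_experiment
#' @param functions Subset of [mic_function_names()].
#' @param b_values Noise levels (default the full `seq(0, 3, 0.01)` grid).
#' @return A data frame with columns `fun`, `b`, `r_squared`, `score`.
#' @export
run_equitability_experiment <- function(method = c("backmic", "chimic",
                                                   "appmic"),
                                        functions = mic_function_names(),
                                        n = 500, reps = 10,
                                        b_values = seq(0, 3, by = 0.01),
                                        config = search_config(),
                                        seed = NULL) {
  method <- match.arg(method)
  reg <- function_registry()
  stopifnot(all(functions %in% names(reg)))
  local_seed(seed, {
    rows <- list()
    for (fn in functions) {
      spec <- reg[[fn]]
      for (b in b_values) {
        r2 <- numeric(reps)
        sc <- numeric(reps)
        for (r in seq_len(reps)) {
          x <- runif(n, spec$domain[1], spec$domain[2])
          fx <- spec$f(x)
          y <- fx + if (b > 0) runif(n, -b, b) else 0
          r2[r] <- if (stats::sd(y) == 0) 1 else cor(fx, y)^2
          sc[r] <- mic_estimate(x, y, method = method, config = config)$score
        }
        rows[[length(rows) + 1L]] <-
          data.frame(fun = fn, b = b, r_squared = mean(r2),
                     score = mean(sc))
      }
    }
    do.call(rbind, rows)
  })
}

#' Grid-shape frequency over independent replicates
#'
#' Histogram of the argmax grid shapes returned by an estimator on
#' independent uniform pairs.
#'
#' @inheritParams run_power_experiment
#' @param n Sample size (default 100).
#' @param reps Replicates (default 1000).
#' @return A data frame with columns `n_x`, `n_y`, `freq` (summing to
#'   `reps`), with attribute `reps`.
#' @export
grid_frequency <- function(method = c("backmic", "chimic", "appmic"),
                           n = 100, reps = 1000,
                           config = search_config(), seed = NULL) {
  method <- match.arg(method)
  local_seed(seed, {
    shapes <- vapply(seq_len(reps), function(r) {
      res <- mic_estimate(gen_independent_pair(n), method = method,
                          config = config)
      c(res$n_x, res$n_y)
    }, integer(2))
    tab <- as.data.frame(table(n_x = shapes[1, ], n_y = shapes[2, ]),
                         stringsAsFactors = FALSE)
    tab <- tab[tab$Freq > 0, ]
    out <- data.frame(n_x = as.integer(tab$n_x), n_y = as.integer(tab$n_y),
                      freq = tab$Freq)
    out <- out[order(-out$freq), ]
    rownames(out) <- NULL
    attr(out, "reps") <- reps
    out
  })
}

#' Robustness of the score to the grid-size cap exponent
#'
#' Scores the *same* noisy samples under every `alpha`, so differences across
#' a row isolate the effect of the cap `B(n, alpha) = n^alpha`.
#' Designs follow the robustness benchmark: `Y = f(X) + noise_level *
#' (2 * runif(n) - 1)` with `X ~ uniform(0, 1)` and noise levels 0.2 / 0.35 /
#' 0.5 for the linear and parabolic functions, 0.6 / 0.9 / 1.2 for the
#' sinusoidal one.
#'
#' @inheritParams run_power_experiment
#' @param patterns Functions to sweep (`"line"`, `"parabolic"`,
#'   `"sinusoidal"`).
#' @param noise_levels Named list of per-pattern noise levels.
#' @param alphas Cap exponents (default `c(0.4, 0.5, 0.6, 0.7, 0.8)`).
#' @return A data frame with columns `pattern`, `noise_level`, `alpha`,
#'   `score` (mean over `reps`).
#' @export
alpha_sweep <- function(method = c("backmic", "chimic", "appmic"),
                        patterns = c("line", "parabolic", "sinusoidal"),
                        noise_levels = list(line = c(0.2, 0.35, 0.5),
                                            parabolic = c(0.2, 0.35, 0.5),
                                            sinusoidal = c(0.6, 0.9, 1.2)),
                        alphas = c(0.4, 0.5, 0.6, 0.7, 0.8),
                        n = 500, reps = 500,
                        config = search_config(), seed = NULL) {
  method <- match.arg(method)
  stopifnot(all(alphas > 0), all(alphas < 1))
  local_seed(seed, {
    rows <- list()
    for (pattern in patterns) {
      for (lev in noise_levels[[pattern]]) {
        pairs <- lapply(seq_len(reps), function(r)
          gen_function_pair(pattern, n, noise_level = lev))
        for (alpha in alphas) {
          cfg <- search_config(alpha = alpha,
                               chi2_threshold = config$chi2_threshold,
                               max_equ_bins = config$max_equ_bins,
                               patience = config$patience,
                               clump_factor = config$clump_factor)
          sc <- vapply(pairs, function(p)
            mic_estimate(p, method = method, config = cfg)$score, numeric(1))
          rows[[length(rows) + 1L]] <-
            data.frame(pattern = pattern, noise_level = lev, alpha = alpha,
                       score = mean(sc))
        }
      }
    }
    do.call(rbind, rows)
  })
}
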