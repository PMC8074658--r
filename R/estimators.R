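# The two chi-squared-gated estimators share one driver: for each
# orientation (equipartitioned axis A = y then A = x) and each n_equ, (i)
# equipartition A, (ii) greedily refine the other axis B under the gate
# (first cut structural: a characteristic-matrix grid needs two bins per
# axis); ChiMIC scores this grid by I / log2(n_equ) and maximizes over
# orientations and n_equ. BackMIC additionally (iii) fixes the learned B
# partition and re-searches A from scratch (the back-search), committing
# cuts that pass the gate *and* raise I / log2(min(nx, ny)); only these
# fully searched grids — no axis left equipartitioned — enter BackMIC's
# maximum, with the min-normalizer.

mic_result <- function(score, method, pair, x_cuts, y_cuts, orientation,
                       norm_mode, mi, n_equ, config) {
  structure(list(score = score,
                 method = method,
                 n_x = length(x_cuts) + 1L,
                 n_y = length(y_cuts) + 1L,
                 x_partition = axis_partition(x_cuts, pair$n),
                 y_partition = axis_partition(y_cuts, pair$n),
                 orientation = orientation,
                 norm_mode = norm_mode,
                 mutual_information = mi,
                 n_equ = n_equ,
                 n = pair$n,
                 alpha = config$alpha,
                 chi2_threshold = config$chi2_threshold),
            class = "mic_result")
}

#' @export
print.mic_result <- function(x, ...) {
  cat(sprintf("<mic_result> %s = %.4f  grid %d x %d  (I = %.4f bits, n = %d)\n",
              x$method, x$score, x$n_x, x$n_y, x$mutual_information, x$n))
  if (!is.na(x$orientation))
    cat("  equipartitioned axis:", x$orientation, " n_equ:", x$n_equ,
        " norm:", x$norm_mode, "\n")
  invisible(x)
}

degenerate_result <- function(pair, method, norm_mode, config) {
  warning("degenerate input: one variable is constant; MIC is 0",
          call. = FALSE)
  mic_result(0, method, pair, integer(0), integer(0), NA_character_,
             norm_mode, 0, NA_integer_, config)
}

est_chi_gated <- function(pair, config, back_search, norm_mode, method,
                          details = FALSE) {
  ix <- axis_info(pair$x)
  iy <- axis_info(pair$y)
  if (!length(ix$admissible) || !length(iy$admissible))
    return(degenerate_result(pair, method, norm_mode, config))
  cap <- equ_cap(pair$n, config)
  best <- list(score = 0, x_cuts = integer(0), y_cuts = integer(0),
               orientation = NA_character_, mi = 0, n_equ = NA_integer_)
  trace <- if (details) vector("list", 0L)
  for (orientation in c("y", "x")) {
    A <- if (orientation == "y") iy else ix
    B <- if (orientation == "y") ix else iy
    o_cap <- min(cap, length(A$admissible) + 1L)
    if (o_cap < 2) next
    best_orient <- 0
    stale <- 0L
    for (n_equ in 2:o_cap) {
      cuts_a <- equipartition_cuts(A, n_equ)
      m_a <- length(cuts_a) + 1L
      if (m_a < 2) next
      bins_a <- bin_of(A$rank, cuts_a)
      cuts_b <- cpp_gated_search(bins_a[B$ord], m_a, B$admissible,
                                 config$chi2_threshold)
      m_b <- length(cuts_b) + 1L
      bins_b <- bin_of(B$rank, cuts_b)
      I <- mi_counts(cross_counts(bins_a, m_a, bins_b, m_b))
      m_score <- if (norm_mode == "equ") I / log2(m_a)
                 else if (min(m_a, m_b) >= 2) I / log2(min(m_a, m_b)) else 0
      if (!back_search && m_score > best$score) {
        best <- list(score = m_score,
                     x_cuts = if (orientation == "y") cuts_b else cuts_a,
                     y_cuts = if (orientation == "y") cuts_a else cuts_b,
                     orientation = orientation, mi = I, n_equ = n_equ)
      }
      back_score <- 0
      if (back_search && m_b >= 2) {
        cuts_a2 <- cpp_gated_search(bins_b[A$ord], m_b, A$admissible,
                                    config$chi2_threshold, free_cuts = 1L,
                                    require_gain = TRUE)
        m_a2 <- length(cuts_a2) + 1L
        if (m_a2 >= 2) {
          bins_a2 <- bin_of(A$rank, cuts_a2)
          I2 <- mi_counts(cross_counts(bins_a2, m_a2, bins_b, m_b))
          back_score <- I2 / log2(min(m_a2, m_b))
          if (back_score > best$score) {
            best <- list(score = back_score,
                         x_cuts = if (orientation == "y") cuts_b else cuts_a2,
                         y_cuts = if (orientation == "y") cuts_a2 else cuts_b,
                         orientation = orientation, mi = I2, n_equ = n_equ)
          }
        }
      }
      if (details)
        trace[[length(trace) + 1L]] <-
          data.frame(orientation = orientation, n_equ = n_equ,
                     m_score = m_score, back_score = back_score)
      val <- if (back_search) back_score else m_score
      if (val > best_orient + 1e-12) {
        best_orient <- val
        stale <- 0L
      } else {
        stale <- stale + 1L
      }
      if (stale >= config$patience) break
    }
  }
  out <- mic_result(best$score, method, pair, best$x_cuts, best$y_cuts,
                    best$orientation, norm_mode, best$mi, best$n_equ, config)
  if (details) attr(out, "trace") <- do.call(rbind, trace)
  out
}

#' BackMIC: chi-squared-gated MIC with a back-search on the equipartitioned axis
#'
#' For each orientation and each equipartition size, one axis is
#' equipartitioned, the other is refined by the gated greedy search, and then
#' the originally equipartitioned axis is re-searched from scratch with the
#' learned partition held fixed, so both axes of the candidate grid end up
#' chi-squared-controlled. The back-searched grids are scored by
#' `I / log2(min(n_x, n_y))` and the maximum over orientations and
#' equipartition sizes is returned.
#'
#' @param x,y Numeric vectors, or a [mic_pair()] as `x`.
#' @param config A [search_config()].
#' @param details If `TRUE`, attach a per-`n_equ` trace of the forward and
#'   back-search scores as attribute `"trace"`.
#' @return A `mic_result` with the score, the winning grid shape and
#'   partitions, the orientation, and the mutual information in bits.
#' @examples
#' x <- seq(0, 1, length.out = 100)
#' backmic(x, x)$score # 1: noiseless functional dependence
#' @export
backmic <- function(x, y = NULL, config = search_config(), details = FALSE) {
  pair <- as_mic_pair(x, y)
  est_chi_gated(pair, config, back_search = TRUE, norm_mode = "min",
                method = "backmic", details = details)
}

#' ChiMIC baseline: gated search with the log2(n_equ) normalizer
#'
#' As [backmic()] but without the back-search phase; scores are normalized by
#' `log2(n_equ)`, the bin count of the equipartitioned axis.
#'
#' @inheritParams backmic
#' @return A `mic_result`.
#' @export
chimic <- function(x, y = NULL, config = search_config(), details = FALSE) {
  pair <- as_mic_pair(x, y)
  est_chi_gated(pair, config, back_search = FALSE, norm_mode = "equ",
                method = "chimic", details = details)
}

#' Estimate MIC by a named method
#'
#' Dispatcher over the three estimators.
#'
#' @inheritParams backmic
#' @param method `"backmic"`, `"chimic"` or `"appmic"`.
#' @return A `mic_result`.
#' @export
mic_estimate <- function(x, y = NULL,
                         method = c("backmic", "chimic", "appmic"),
                         config = search_config()) {
  method <- match.arg(method)
  switch(method,
         backmic = backmic(x, y, config),
         chimic = chimic(x, y, config),
         appmic = appmic(x, y, config))
}
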