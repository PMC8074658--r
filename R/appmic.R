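# ApproxMaxMI baseline: the characteristic-matrix maximization of the
# original MIC definition. For every equipartition size n_equ on one axis
# (both orientations) the other axis is partitioned by dynamic programming
# into l = 2..floor(B/n_equ) columns maximizing mutual information, with
# column boundaries restricted to clump endpoints (maximal runs of
# consecutive points sharing a row bin; an optimal partition never splits
# one) coarsened to at most clump_factor * l superclumps. Scores are
# I / log2(min(l, n_equ)); the estimate is the maximum over the whole matrix
# subject to l * n_equ <= B(n, alpha) = n^alpha.

# DP column boundaries: clump endpoints on the searched axis, coarsened to
# ~k_hat superclumps by snapping equipartition targets onto them.
superclump_bounds <- function(rb, admissible, n, k_hat) {
  chg <- admissible[rb[admissible] != rb[admissible + 1L]]
  if (length(chg) + 1L > k_hat && k_hat >= 2L) {
    targets <- unique(round(seq_len(k_hat - 1L) * n / k_hat))
    idx <- findInterval(targets, chg)
    lo <- ifelse(idx >= 1L, chg[pmax(idx, 1L)], 0L)
    hi <- ifelse(idx < length(chg), chg[pmin(idx + 1L, length(chg))], n)
    snap <- ifelse(targets - lo <= hi - targets, lo, hi)
    chg <- sort(unique(snap[snap > 0L & snap < n]))
  }
  as.integer(c(chg, n))
}

appmic_scan <- function(pair, config, ix, iy, want = NULL) {
  B <- pair$n ^ config$alpha
  best <- list(score = 0, orientation = NA_character_, n_equ = NA_integer_,
               l = NA_integer_, mi = 0)
  for (orientation in c("y", "x")) {
    A <- if (orientation == "y") iy else ix
    B_ax <- if (orientation == "y") ix else iy
    top <- floor(B / 2)
    if (top < 2) next
    for (n_equ in 2:top) {
      L <- floor(B / n_equ)
      if (L < 2) break
      if (n_equ > length(A$admissible) + 1L) break
      cuts_a <- equipartition_cuts(A, n_equ)
      m_a <- length(cuts_a) + 1L
      if (m_a < 2) next
      bins_a <- bin_of(A$rank, cuts_a)
      rb <- bins_a[B_ax$ord]
      bounds <- superclump_bounds(rb, B_ax$admissible, pair$n,
                                  config$clump_factor * L)
      if (length(bounds) < 2) next
      opt <- cpp_optimize_axis(rb, m_a, bounds, L)
      h_row <- -sum(plogp(tabulate(bins_a, m_a) / pair$n))
      for (l in 2:L) {
        G <- opt$G[l]
        if (is.na(G)) next
        I <- max(h_row + G / pair$n, 0)
        score <- I / log2(min(l, m_a))
        if (score > best$score) {
          best <- list(score = score, orientation = orientation,
                       n_equ = n_equ, l = l, mi = I)
        }
        if (!is.null(want) && identical(want$orientation, orientation) &&
            want$n_equ == n_equ && want$l == l) {
          # reconstruct the argmax column boundaries for this cell
          pos <- c(0L, bounds)
          t <- length(bounds)
          path <- integer(0)
          for (ll in seq(l, 2)) {
            s <- opt$choice[ll + 1L, t + 1L]
            path <- c(pos[s + 1L], path)
            t <- s
          }
          best$cuts_a <- cuts_a
          best$cuts_b <- path
        }
      }
    }
  }
  best
}

#' ApproxMaxMI baseline estimator
#'
#' The original dynamic-programming MIC approximation: one axis is
#' equipartitioned, the other optimized by dynamic programming, over every
#' grid shape with `n_x * n_y <= n^alpha`, both orientations.
#'
#' @inheritParams backmic
#' @return A `mic_result` (norm mode `"min"`).
#' @examples
#' x <- runif(100)
#' appmic(x, x)$score
#' @export
appmic <- function(x, y = NULL, config = search_config(), details = FALSE) {
  pair <- as_mic_pair(x, y)
  ix <- axis_info(pair$x)
  iy <- axis_info(pair$y)
  if (!length(ix$admissible) || !length(iy$admissible))
    return(degenerate_result(pair, "appmic", "min", config))
  scan <- appmic_scan(pair, config, ix, iy)
  if (!is.finite(scan$score) || scan$score <= 0 || is.na(scan$orientation)) {
    return(mic_result(0, "appmic", pair, integer(0), integer(0),
                      NA_character_, "min", 0, NA_integer_, config))
  }
  # second pass to recover the winning partition
  full <- appmic_scan(pair, config, ix, iy,
                      want = scan[c("orientation", "n_equ", "l")])
  x_cuts <- if (full$orientation == "y") full$cuts_b else full$cuts_a
  y_cuts <- if (full$orientation == "y") full$cuts_a else full$cuts_b
  out <- mic_result(full$score, "appmic", pair, x_cuts, y_cuts,
                    full$orientation, "min", full$mi, full$n_equ, config)
  out
}
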