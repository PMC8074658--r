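#' Detection area of a candidate segment point
#'
#' The chi-squared gate evaluates a candidate cut on the two columns it would
#' create inside the bracketing interval, crossed with every bin of the other
#' axis. Because the committed grid cannot be split below its own resolution,
#' the area is built from point-level assignments: `row_bins` gives each
#' point's bin on the fixed axis and `col_ranks` its rank on the searched
#' axis.
#'
#' @param row_bins Integer vector, bin index of each point on the fixed axis.
#' @param col_ranks Integer vector of ranks (1..n) on the searched axis.
#' @param new_cut Candidate cut position (rank index).
#' @param flank_lo,flank_hi Nearest existing cuts (or axis ends `0` and `n`)
#'   bracketing the candidate: `flank_lo < new_cut < flank_hi`.
#' @return An `n_rows x 2` count matrix: column 1 holds ranks in
#'   `(flank_lo, new_cut]`, column 2 ranks in `(new_cut, flank_hi]`.
#' @examples
#' detection_area(c(1, 1, 2, 2), 1:4, 2, 0, 4) # perfect 2x2 diagonal
#' @export
detection_area <- function(row_bins, col_ranks, new_cut, flank_lo = 0L,
                           flank_hi = length(col_ranks)) {
  if (length(row_bins) != length(col_ranks))
    stop("`row_bins` and `col_ranks` must have the same length", call. = FALSE)
  if (new_cut <= flank_lo || new_cut >= flank_hi)
    stop("invalid cut: need flank_lo < new_cut < flank_hi (candidate must ",
         "not coincide with an existing cut)", call. = FALSE)
  keep <- col_ranks > flank_lo & col_ranks <= flank_hi
  side <- ifelse(col_ranks[keep] <= new_cut, 1L, 2L)
  nr <- max(row_bins)
  area <- matrix(tabulate((side - 1L) * nr + row_bins[keep], nbins = 2L * nr),
                 nrow = nr)
  area
}

#' Chi-squared test of a candidate segment point
#'
#' Pearson chi-squared statistic on the detection area, with expected counts
#' from the margins. All-zero rows are dropped first; when exactly two rows
#' remain the continuity-corrected form `sum((|O - E| - 0.5)^2 / E)` is used.
#' Degrees of freedom are `rows - 1`. The candidate is accepted when the
#' upper-tail p-value falls below `threshold`.
#'
#' @param area Detection area: an `n_rows x 2` nonnegative count matrix.
#' @param threshold Significance threshold for acceptance (default 0.01).
#' @return An object of class `gate_decision`: `statistic`, `p_value`, `df`,
#'   `accepted`.
#' @examples
#' chi2_segment_test(rbind(c(10, 0), c(0, 10))) # statistic 16.2, accepted
#' @export
chi2_segment_test <- function(area, threshold = 0.01) {
  area <- as_count_matrix(area)
  if (ncol(area) != 2L)
    stop("a detection area has exactly 2 columns", call. = FALSE)
  if (sum(area) <= 0)
    stop("degenerate area: no points", call. = FALSE)
  res <- cpp_chi2_area(area)
  structure(list(statistic = res$statistic,
                 p_value = res$p_value,
                 df = res$df,
                 accepted = res$p_value < threshold,
                 threshold = threshold),
            class = "gate_decision")
}

#' @export
print.gate_decision <- function(x, ...) {
  cat(sprintf("<gate_decision> X2 = %.4f, df = %d, p = %.4g -> %s\n",
              x$statistic, x$df, x$p_value,
              if (x$accepted) "accept cut" else "reject cut"))
  invisible(x)
}
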