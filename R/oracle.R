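#' Exhaustive grid oracle for tiny samples
#'
#' Brute-force maximum of `I / log2(min(n_x, n_y))` over *all* pairs of
#' admissible axis partitions with at most `max_bins` bins per axis. Intended
#' as an independent upper bound in tests; guarded against combinatorial
#' explosion.
#'
#' @inheritParams backmic
#' @param max_bins Per-axis bin budget, at most 4.
#' @return The maximal normalized score (0 when no grid with
#'   `min(n_x, n_y) >= 2` exists).
#' @examples
#' exhaustive_mic_oracle(1:4, 1:4, max_bins = 2) # 1
#' @export
exhaustive_mic_oracle <- function(x, y = NULL, max_bins = 4) {
  pair <- as_mic_pair(x, y)
  if (pair$n > 14 || max_bins > 4)
    stop("refused: the exhaustive oracle is limited to n <= 14 and ",
         "max_bins <= 4", call. = FALSE)
  ix <- axis_info(pair$x)
  iy <- axis_info(pair$y)
  px <- all_bin_assignments(ix, max_bins)
  py <- all_bin_assignments(iy, max_bins)
  cpp_exhaustive_best(px$bins, py$bins, px$n_bins, py$n_bins)
}

# every admissible partition with <= max_bins bins, as an n x P matrix of
# bin assignments plus the bin count of each
all_bin_assignments <- function(info, max_bins) {
  adm <- info$admissible
  cut_sets <- list(integer(0))
  for (k in seq_len(max_bins - 1L)) {
    if (length(adm) < k) break
    sets <- combn(adm, k, simplify = FALSE)
    cut_sets <- c(cut_sets, sets)
  }
  bins <- vapply(cut_sets, function(cs) bin_of(info$rank, cs),
                 integer(info$n))
  if (is.null(dim(bins))) bins <- matrix(bins, nrow = info$n)
  list(bins = bins,
       n_bins = vapply(cut_sets, function(cs) length(cs) + 1L, integer(1)))
}
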