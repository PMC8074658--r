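#' Search configuration for the MIC estimators
#'
#' @param alpha Exponent of the grid-size cap `B(n, alpha) = n^alpha` used by
#'   ApproxMaxMI and by the outer equipartition loop of the gated estimators
#'   (default 0.6, the value used throughout the benchmarks).
#' @param chi2_threshold Significance threshold of the segment-point gate
#'   (default 0.01).
#' @param max_equ_bins Optional override of the outer-loop cap on the number
#'   of equipartition bins; the default is `max(4, ceiling(n^alpha / 2))`.
#' @param patience Consecutive non-improving equipartition sizes before the
#'   outer loop stops early (default 3).
#' @param clump_factor Superclump coarsening factor of the ApproxMaxMI column
#'   optimisation (default 15).
#' @return A list of class `search_config`.
#' @export
search_config <- function(alpha = 0.6, chi2_threshold = 0.01,
                          max_equ_bins = NULL, patience = 3L,
                          clump_factor = 15L) {
  if (alpha <= 0 || alpha >= 1) stop("`alpha` must be in (0, 1)", call. = FALSE)
  if (chi2_threshold <= 0 || chi2_threshold >= 1)
    stop("`chi2_threshold` must be in (0, 1)", call. = FALSE)
  if (patience < 1) stop("`patience` must be >= 1", call. = FALSE)
  if (clump_factor < 1) stop("`clump_factor` must be >= 1", call. = FALSE)
  structure(list(alpha = alpha, chi2_threshold = chi2_threshold,
                 max_equ_bins = max_equ_bins, patience = as.integer(patience),
                 clump_factor = as.integer(clump_factor)),
            class = "search_config")
}

equ_cap <- function(n, config) {
  as.integer(config$max_equ_bins %||% max(4, ceiling(n ^ config$alpha / 2)))
}

#' Chi-squared-gated greedy refinement of one axis
#'
#' Starting from a single bin, repeatedly evaluates every admissible candidate
#' cut on the searched axis, picks the one that maximizes the mutual
#' information of the resulting grid (smallest rank on ties), and commits it
#' if the chi-squared test on its detection area accepts; the first rejection
#' stops the search.
#'
#' @param pair A [mic_pair()] (or two vectors via `mic_pair`).
#' @param fixed An [axis_partition()] with at least 2 bins on the *other*
#'   axis.
#' @param search_axis Which axis to refine, `"x"` or `"y"`.
#' @param config A [search_config()].
#' @param structural_first If `TRUE`, the first cut is committed without a
#'   test (a grid needs two bins per axis before the characteristic matrix is
#'   defined); the estimators use this. The default gates every cut, so the
#'   search can return a single bin.
#' @return The committed [axis_partition()] on the searched axis (possibly a
#'   single bin when no candidate passes the gate or all values are tied).
#' @examples
#' p <- mic_pair(1:40, 1:40)
#' chi_gated_search(p, equipartition(p$y, 2), "x")
#' @export
chi_gated_search <- function(pair, fixed, search_axis = c("x", "y"),
                             config = search_config(),
                             structural_first = FALSE) {
  pair <- as_mic_pair(pair)
  search_axis <- match.arg(search_axis)
  if (!inherits(fixed, "axis_partition"))
    stop("`fixed` must be an `axis_partition`", call. = FALSE)
  if (fixed$n != pair$n)
    stop("`fixed` is defined for n = ", fixed$n, ", pair has n = ", pair$n,
         call. = FALSE)
  if (fixed$n_bins < 2)
    stop("`fixed` must have at least 2 bins", call. = FALSE)
  info_fixed <- axis_info(if (search_axis == "x") pair$y else pair$x)
  info_search <- axis_info(if (search_axis == "x") pair$x else pair$y)
  cuts <- gated_cuts(info_fixed, fixed$cuts, info_search,
                     config$chi2_threshold,
                     free_cuts = if (structural_first) 1L else 0L)
  axis_partition(cuts, pair$n)
}

# core wrapper around the compiled greedy search, on precomputed axis_info
gated_cuts <- function(info_fixed, fixed_cuts, info_search, threshold,
                       free_cuts = 1L, require_gain = FALSE) {
  bins_fixed <- bin_of(info_fixed$rank, fixed_cuts)
  rb <- bins_fixed[info_search$ord]
  cpp_gated_search(rb, length(fixed_cuts) + 1L, info_search$admissible,
                   threshold, free_cuts = free_cuts,
                   require_gain = require_gain)
}
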