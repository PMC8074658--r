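#' Construct an axis partition
#'
#' A partition of one axis into bins, stored as rank-index cut positions: a
#' cut at index `i` separates order statistics `1..i` from `i+1..n`, so bin
#' `j` holds the ranks in the half-open interval `(cut[j-1], cut[j]]`.
#'
#' @param cuts Integer vector of cut positions, strictly increasing, each in
#'   `1..(n-1)`. May be empty (single bin).
#' @param n Sample size the partition refers to.
#' @return An object of class `axis_partition` with fields `cuts`, `n`,
#'   `n_bins`.
#' @export
axis_partition <- function(cuts, n) {
  n <- as.integer(n)
  cuts <- as.integer(cuts)
  if (length(cuts)) {
    if (is.unsorted(cuts, strictly = TRUE))
      stop("`cuts` must be strictly increasing", call. = FALSE)
    if (min(cuts) < 1L || max(cuts) >= n)
      stop("every cut must satisfy 1 <= cut < n", call. = FALSE)
  }
  structure(list(cuts = cuts, n = n, n_bins = length(cuts) + 1L),
            class = "axis_partition")
}

#' @export
print.axis_partition <- function(x, ...) {
  cat("<axis_partition>", x$n_bins, "bins on n =", x$n,
      if (length(x$cuts)) paste0("(cuts at ", paste(x$cuts, collapse = ", "), ")")
      else "(no cuts)", "\n")
  invisible(x)
}

#' Equipartition an axis
#'
#' Splits the values into `k` bins of as nearly equal counts as ties permit.
#' Bin sizes are `floor(n/k)` or `ceiling(n/k)` with the remainder assigned to
#' the first `n %% k` bins. A nominal boundary falling inside a run of tied
#' values snaps to the nearer end of the run (the lower end on an exact tie),
#' so the result can have fewer than `k` bins when ties force merges.
#'
#' @param values Numeric vector to partition (not all tied).
#' @param k Requested bin count, `2 <= k <= length(values)`.
#' @return An [axis_partition()].
#' @examples
#' equipartition(c(1, 1, 1, 1, 2, 2), 3) # ties force 2 bins of sizes 4, 2
#' @export
equipartition <- function(values, k) {
  info <- axis_info(values)
  if (length(info$admissible) < 1L)
    stop("invalid bin count: the values are all tied, no cut is admissible",
         call. = FALSE)
  if (k < 2 || k > info$n)
    stop("invalid bin count: `k` must be between 2 and n (", info$n,
         "), got ", k, call. = FALSE)
  axis_partition(equipartition_cuts(info, as.integer(k)), info$n)
}

# equipartition on a precomputed axis_info; returns the integer cut vector
equipartition_cuts <- function(info, k) {
  n <- info$n
  base <- n %/% k
  sizes <- rep.int(base, k)
  rem <- n %% k
  if (rem > 0L) sizes[seq_len(rem)] <- base + 1L
  nominal <- cumsum(sizes)[-k]
  allowed <- c(0L, info$admissible, n)
  snapped <- vapply(nominal, function(b) {
    if (any(info$admissible == b)) return(as.integer(b))
    lo <- max(allowed[allowed < b])
    hi <- min(allowed[allowed > b])
    if (b - lo <= hi - b) lo else hi
  }, integer(1))
  snapped <- snapped[snapped > 0L & snapped < n]
  sort(unique(snapped))
}

# bin index per point from ranks and integer cuts
bin_of <- function(rnk, cuts) {
  if (!length(cuts)) return(rep.int(1L, length(rnk)))
  findInterval(rnk - 1L, cuts) + 1L
}
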