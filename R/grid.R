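#' Build the contingency table induced by two axis partitions
#'
#' Counts the points of a paired sample in each cell of the grid defined by a
#' partition of the x-axis and a partition of the y-axis. Rows index y bins
#' (lowest ranks first), columns index x bins.
#'
#' @param pair A [mic_pair()] (or anything coercible via `mic_pair(x, y)`).
#' @param x_partition,y_partition [axis_partition()]s on the ranks of
#'   `pair$x` and `pair$y`.
#' @return An object of class `grid_table` with fields `counts`
#'   (`n_y x n_x` integer matrix), `row_margins`, `col_margins`, `total`.
#' @examples
#' p <- mic_pair(1:4, 1:4)
#' grid_table(p, axis_partition(2, 4), axis_partition(2, 4))$counts
#' @export
grid_table <- function(pair, x_partition, y_partition) {
  pair <- as_mic_pair(pair)
  for (p in list(x_partition, y_partition)) {
    if (!inherits(p, "axis_partition"))
      stop("partitions must be `axis_partition` objects", call. = FALSE)
    if (p$n != pair$n)
      stop("inconsistent partition: defined for n = ", p$n,
           " but the pair has n = ", pair$n, call. = FALSE)
  }
  ix <- axis_info(pair$x)
  iy <- axis_info(pair$y)
  bx <- bin_of(ix$rank, x_partition$cuts)
  by <- bin_of(iy$rank, y_partition$cuts)
  nx <- x_partition$n_bins
  ny <- y_partition$n_bins
  counts <- matrix(tabulate((bx - 1L) * ny + by, nbins = nx * ny), nrow = ny)
  structure(list(counts = counts,
                 row_margins = rowSums(counts),
                 col_margins = colSums(counts),
                 total = pair$n),
            class = "grid_table")
}

#' @export
print.grid_table <- function(x, ...) {
  cat("<grid_table>", nrow(x$counts), "x", ncol(x$counts),
      "(rows = y bins), n =", x$total, "\n")
  print(x$counts)
  invisible(x)
}

as_count_matrix <- function(table) {
  m <- if (inherits(table, "grid_table")) table$counts else as.matrix(table)
  if (!is.numeric(m) || any(m < 0))
    stop("counts must be a nonnegative numeric matrix", call. = FALSE)
  m
}

#' Mutual information of a contingency table, in bits
#'
#' Plug-in estimate `I = sum p_ij log2(p_ij / (p_i. p_.j))` with the usual
#' `0 log 0 = 0` convention.
#'
#' @param table A [grid_table()] or a plain nonnegative count matrix.
#' @return Mutual information in bits (nonnegative scalar).
#' @examples
#' mutual_information(rbind(c(10, 0), c(0, 10))) # 1 bit
#' @export
mutual_information <- function(table) {
  m <- as_count_matrix(table)
  n <- sum(m)
  if (n <= 0)
    stop("degenerate input: empty contingency table", call. = FALSE)
  I <- (plogp(n) + sum(plogp(m)) - sum(plogp(rowSums(m))) -
          sum(plogp(colSums(m)))) / n
  max(I, 0)
}

#' Normalized mutual information of a grid
#'
#' Divides the mutual information of the table by `log2(min(n_x, n_y))`
#' (`norm_mode = "min"`, the MIC normalizer) or by `log2(n_equ)`
#' (`norm_mode = "equ"`, the ChiMIC normalizer, where `n_equ` is the bin count
#' of the equipartitioned axis).
#'
#' @param table A [grid_table()] or count matrix (rows = y bins).
#' @param norm_mode `"min"` or `"equ"`.
#' @param n_equ Equipartitioned-axis bin count, required for `"equ"`.
#' @return Normalized score in `[0, 1]`.
#' @examples
#' it <- rbind(c(80, 40, 80), c(0, 120, 0), c(80, 40, 80))
#' normalized_score(it) # 0.2561
#' @export
normalized_score <- function(table, norm_mode = c("min", "equ"), n_equ = NULL) {
  norm_mode <- match.arg(norm_mode)
  m <- as_count_matrix(table)
  I <- mutual_information(m)
  if (norm_mode == "min") {
    mn <- min(dim(m))
    if (mn < 2)
      stop("degenerate grid: min(n_x, n_y) = 1 gives a zero normalizer",
           call. = FALSE)
    I / log2(mn)
  } else {
    if (is.null(n_equ) || n_equ < 2)
      stop("`norm_mode = \"equ\"` requires `n_equ >= 2`", call. = FALSE)
    I / log2(n_equ)
  }
}

# mutual information straight from count matrix (no class dispatch), in bits
mi_counts <- function(m) {
  n <- sum(m)
  I <- (plogp(n) + sum(plogp(m)) - sum(plogp(rowSums(m))) -
          sum(plogp(colSums(m)))) / n
  max(I, 0)
}

# joint counts from two bin-assignment vectors: rows = bins of `ba`,
# columns = bins of `bb`
cross_counts <- function(ba, nb_a, bb, nb_b) {
  matrix(tabulate((bb - 1L) * nb_a + ba, nbins = nb_a * nb_b), nrow = nb_a)
}
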