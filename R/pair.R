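#' Construct a paired sample
#'
#' Bundles two equal-length numeric vectors into the paired-variable object
#' all estimators operate on.
#'
#' @param x,y Numeric vectors of equal length (at least 2), all values finite.
#' @return An object of class `mic_pair` with fields `x`, `y`, `n`.
#' @examples
#' p <- mic_pair(1:10, (1:10)^2)
#' p$n
#' @export
mic_pair <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y))
    stop("`x` and `y` must have the same length (", length(x), " vs ",
         length(y), ")", call. = FALSE)
  if (length(x) < 2)
    stop("a paired sample needs at least 2 observations", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("all values in `x` and `y` must be finite", call. = FALSE)
  structure(list(x = x, y = y, n = length(x)), class = "mic_pair")
}

as_mic_pair <- function(x, y = NULL) {
  if (inherits(x, "mic_pair")) {
    if (!is.null(y))
      stop("`y` must be NULL when `x` is already a mic_pair ",
           "(did you mean to pass `config = ` by name?)", call. = FALSE)
    return(x)
  }
  if (is.null(y) && is.list(x) && !is.null(x$x) && !is.null(x$y))
    return(mic_pair(x$x, x$y))
  mic_pair(x, y)
}

#' @export
print.mic_pair <- function(x, ...) {
  cat("<mic_pair> n =", x$n, "\n")
  invisible(x)
}

# Rank bookkeeping for one axis: ranks (ties broken by position, which is
# immaterial because cuts never sit inside a tie run), the sorting order, and
# the admissible cut positions (rank indices strictly between distinct
# values).
axis_info <- function(values) {
  n <- length(values)
  ord <- order(values)
  rnk <- integer(n)
  rnk[ord] <- seq_len(n)
  sv <- values[ord]
  admissible <- which(diff(sv) != 0)
  list(rank = rnk, ord = ord, admissible = as.integer(admissible), n = n)
}
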