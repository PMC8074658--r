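# K-means clustering of samples under the (1 - MIC) distance, with the
# purity and Rand-index criteria.

#' Keep the genes with the largest variance
#'
#' @param m Numeric matrix, genes in rows, samples in columns.
#' @param k Number of genes to keep (default 1000).
#' @return The submatrix of the `k` most variable rows, original order
#'   preserved.
#' @export
top_variance_filter <- function(m, k = 1000) {
  m <- as.matrix(m)
  if (k > nrow(m))
    stop("`k` (", k, ") exceeds the number of genes (", nrow(m), ")",
         call. = FALSE)
  v <- apply(m, 1, var)
  keep <- sort(order(v, decreasing = TRUE)[seq_len(k)])
  m[keep, , drop = FALSE]
}

#' (1 - MIC) distance between two expression profiles
#'
#' @param s1,s2 Numeric vectors of equal length (at least 4).
#' @param method MIC estimator to use.
#' @param config A [search_config()].
#' @return Distance in `[0, 1]` (0 for a monotone relationship, near 1 for
#'   independent profiles; 1 with a warning for degenerate input).
#' @export
mic_distance <- function(s1, s2, method = "backmic",
                         config = search_config()) {
  if (length(s1) != length(s2) || length(s1) < 4)
    stop("profiles must have equal length >= 4", call. = FALSE)
  if (length(unique(s1)) < 2 || length(unique(s2)) < 2) {
    warning("degenerate profile (constant); distance set to 1", call. = FALSE)
    return(1)
  }
  1 - mic_estimate(s1, s2, method = method, config = config)$score
}

dist_to_centre <- function(m, centre, distance, method, config) {
  if (distance == "euclidean") {
    sqrt(colSums((m - centre)^2))
  } else {
    apply(m, 2, function(s) {
      if (length(unique(s)) < 2 || length(unique(centre)) < 2) 1
      else 1 - mic_estimate(s, centre, method = method,
                            config = config)$score
    })
  }
}

#' K-means clustering of samples with a (1 - MIC) distance
#'
#' Lloyd-style iteration over the columns of an expression matrix: centres
#' are initialized as `K` random samples, each sample is assigned to the
#' nearest centre under the chosen distance, and centres are updated as the
#' coordinate-wise mean of their members (`centres = "medoid"` instead picks
#' the member minimizing the within-cluster distance sum). An emptied
#' cluster is re-seeded from the sample farthest from its centre. The best
#' of `restarts` runs by within-cluster distance sum is returned.
#'
#' @param m Numeric matrix, genes in rows, samples (to be clustered) in
#'   columns.
#' @param K Number of clusters (default 2).
#' @param method MIC estimator for the distance (`"backmic"`, `"chimic"`,
#'   `"appmic"`).
#' @param distance `"mic"` for (1 - MIC), or `"euclidean"`.
#' @param centres `"mean"` or `"medoid"`.
#' @param restarts Random restarts (default 10).
#' @param max_iter Iteration cap per restart (default 100).
#' @param config A [search_config()].
#' @param seed Integer seed (required for reproducibility of the random
#'   initializations).
#' @return An object of class `mic_clustering`: `labels` (one id in `1..K`
#'   per sample), `K`, `within`, `distance`, `iterations`.
#' @export
kmeans_mic <- function(m, K = 2, method = "backmic",
                       distance = c("mic", "euclidean"),
                       centres = c("mean", "medoid"), restarts = 10,
                       max_iter = 100, config = search_config(),
                       seed = NULL) {
  distance <- match.arg(distance)
  centres <- match.arg(centres)
  m <- as.matrix(m)
  M <- ncol(m)
  if (M < K) stop("need at least K samples", call. = FALSE)
  if (K < 2) stop("`K` must be at least 2", call. = FALSE)
  local_seed(seed, {
    best <- NULL
    for (run in seq_len(restarts)) {
      cent <- m[, sample.int(M, K), drop = FALSE]
      labels <- integer(M)
      dmin <- numeric(M)
      iter <- 0L
      repeat {
        iter <- iter + 1L
        dmat <- vapply(seq_len(K), function(k)
          dist_to_centre(m, cent[, k], distance, method, config),
          numeric(M))
        if (M == 1) dmat <- matrix(dmat, nrow = 1)
        new_labels <- max.col(-dmat, ties.method = "first")
        dmin <- dmat[cbind(seq_len(M), new_labels)]
        for (k in seq_len(K)) {
          if (!any(new_labels == k)) {
            far <- which.max(dmin)
            new_labels[far] <- k
            dmin[far] <- 0
          }
        }
        if (identical(new_labels, labels) || iter >= max_iter) {
          labels <- new_labels
          break
        }
        labels <- new_labels
        for (k in seq_len(K)) {
          members <- which(labels == k)
          cent[, k] <- if (centres == "mean") {
            rowMeans(m[, members, drop = FALSE])
          } else {
            sub <- m[, members, drop = FALSE]
            tot <- vapply(seq_along(members), function(i)
              sum(dist_to_centre(sub, sub[, i], distance, method, config)),
              numeric(1))
            sub[, which.min(tot)]
          }
        }
      }
      within <- sum(dmin)
      if (is.null(best) || within < best$within)
        best <- list(labels = labels, within = within, iterations = iter)
    }
    structure(list(labels = best$labels, K = as.integer(K),
                   within = best$within, distance = distance,
                   method = method, iterations = best$iterations,
                   restarts = restarts),
              class = "mic_clustering")
  })
}

#' @export
print.mic_clustering <- function(x, ...) {
  cat("<mic_clustering> K =", x$K, " distance =", x$distance,
      " within-cluster sum =", format(x$within, digits = 4), "\n")
  cat("  sizes:", paste(tabulate(x$labels, x$K), collapse = ", "), "\n")
  invisible(x)
}

cluster_labels <- function(c) {
  if (inherits(c, "mic_clustering")) c$labels else as.integer(as.factor(c))
}

#' Purity of a clustering against true classes
#'
#' The fraction of samples assigned to the majority true class of their
#' cluster: `(1/M) * sum_clusters max_class |cluster intersect class|`.
#'
#' @param c Predicted clustering (label vector or [kmeans_mic()] result).
#' @param truth True class labels.
#' @return Purity in `[0, 1]`.
#' @export
purity <- function(c, truth) {
  cl <- cluster_labels(c)
  tr <- cluster_labels(truth)
  if (length(cl) != length(tr))
    stop("clusterings must label the same samples", call. = FALSE)
  tab <- table(cl, tr)
  sum(apply(tab, 1, max)) / length(cl)
}

#' Rand index of a clustering against true classes
#'
#' `(A + B) / choose(M, 2)` where `A` counts sample pairs co-clustered in
#' both partitions and `B` pairs separated in both.
#'
#' @inheritParams purity
#' @return Rand index in `[0, 1]`.
#' @export
rand_index <- function(c, truth) {
  cl <- cluster_labels(c)
  tr <- cluster_labels(truth)
  if (length(cl) != length(tr))
    stop("clusterings must label the same samples", call. = FALSE)
  M <- length(cl)
  if (M < 2) stop("need at least 2 samples", call. = FALSE)
  tab <- table(cl, tr)
  A <- sum(choose(tab, 2))
  B <- choose(M, 2) - sum(choose(rowSums(tab), 2)) -
    sum(choose(colSums(tab), 2)) + A
  (A + B) / choose(M, 2)
}
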