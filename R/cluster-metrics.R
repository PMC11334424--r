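# Partition-quality scores: mean silhouette (Euclidean) and the adjusted
# Rand index.

#' @noRd
.silhouetteFromDist <- function(D, labels) {
  f <- factor(labels)
  if (nlevels(f) < 2L)
    stop("silhouette is undefined for a single cluster", call. = FALSE)
  n <- nrow(D)
  counts <- as.numeric(table(f))
  S <- t(rowsum(D, f, reorder = TRUE))            # n x g distance sums
  M <- sweep(S, 2L, counts, "/")                  # mean distance to each cluster
  own <- as.integer(f)
  nOwn <- counts[own]
  a <- S[cbind(seq_len(n), own)] / pmax(nOwn - 1, 1)
  M[cbind(seq_len(n), own)] <- Inf
  b <- do.call(pmin, as.data.frame(M))
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s)] <- 0                            # coincident points: a = b = 0
  s[nOwn == 1] <- 0                                # singleton convention
  s
}

#' Mean silhouette score of a partition
#'
#' Per point, `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a` the mean
#' Euclidean distance to the point's own cluster (excluding itself) and `b`
#' the smallest mean distance to any other cluster; singleton clusters score
#' 0. Returns the mean over all points.
#'
#' @param x `KOSet` with a `clr` assay or a samples-by-features matrix.
#' @param labels cluster assignment, one per sample (>= 2 clusters).
#' @return mean silhouette in \[-1, 1\].
#' @export
silhouetteMean <- function(x, labels) {
  X <- .sampleMatrix(x)
  if (length(labels) != nrow(X))
    stop("'labels' must have one entry per sample", call. = FALSE)
  mean(.silhouetteFromDist(.pairwiseDist(X), labels))
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples:
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones. Degenerate identical partitions (both all-singletons or both
#' single-cluster) score 1 by convention.
#'
#' @param labelsA,labelsB label vectors of equal length.
#' @return the adjusted Rand index (<= 1).
#' @export
adjustedRand <- function(labelsA, labelsB) {
  if (length(labelsA) != length(labelsB))
    stop("label vectors must have equal length", call. = FALSE)
  n <- length(labelsA)
  tab <- table(labelsA, labelsB)
  sumij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  E <- ai * bj / choose(n, 2)
  M <- (ai + bj) / 2
  if (!is.finite(E) || abs(M - E) < .Machine$double.xmin) return(1)
  (sumij - E) / (M - E)
}
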