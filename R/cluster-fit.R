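# Clustering of normalized profiles. Both fitters operate on Euclidean
# distance in the full CLR space (samples as points). k-means is Lloyd's
# algorithm with k-means++ initialization and restarts; Ward is the
# Lance-Williams recurrence on squared Euclidean distances.

#' @noRd
.kmeansPP <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(0, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k > 1L) {
    d2 <- .rowDist2(X, centers[1L, , drop = FALSE])[, 1L]
    for (c in 2L:k) {
      tot <- sum(d2)
      pick <- if (tot <= 0) sample.int(n, 1L) else sample.int(n, 1L, prob = d2 / tot)
      centers[c, ] <- X[pick, ]
      d2 <- pmin(d2, .rowDist2(X, centers[c, , drop = FALSE])[, 1L])
    }
  }
  centers
}

# One Lloyd run from given starting centers. Returns labels, centers, the
# per-iteration WCSS trace (non-increasing by construction) and final WCSS.
# An empty cluster is re-seeded at the point currently farthest from its
# assigned center.
#' @noRd
.lloyd <- function(X, centers, maxIter, tol) {
  n <- nrow(X); k <- nrow(centers)
  trace <- numeric(0)
  labels <- integer(n)
  for (it in seq_len(maxIter)) {
    d2 <- .rowDist2(X, centers)
    labels <- max.col(-d2, ties.method = "first")
    repeat {
      empty <- setdiff(seq_len(k), labels)
      if (!length(empty)) break
      assigned <- d2[cbind(seq_len(n), labels)]
      far <- which.max(assigned)
      centers[empty[1L], ] <- X[far, ]
      d2[, empty[1L]] <- .rowDist2(X, centers[empty[1L], , drop = FALSE])[, 1L]
      labels <- max.col(-d2, ties.method = "first")
    }
    trace <- c(trace, sum(d2[cbind(seq_len(n), labels)]))
    sizes <- tabulate(labels, nbins = k)
    newC <- rowsum(X, labels, reorder = TRUE) / sizes
    shift <- sum((newC - centers)^2)
    centers <- newC
    if (shift <= tol) break
  }
  d2 <- .rowDist2(X, centers)
  labels <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(n), labels)])
  list(labels = labels, centers = centers, wcss = wcss, trace = c(trace, wcss))
}

#' Fit k-means on sample profiles
#'
#' Lloyd's algorithm with k-means++ initialization, keeping the best of
#' `nInit` seeded restarts by within-cluster sum of squares (WCSS).
#' Deterministic given `seed`. If a cluster empties during iteration its
#' centroid is re-seeded at the point farthest from its current center.
#'
#' @param x `KOSet` with a `clr` assay, or a numeric samples-by-features
#'   matrix.
#' @param k number of clusters (`1 <= k <= n_samples`).
#' @param seed integer seed.
#' @param nInit number of k-means++ restarts.
#' @param maxIter maximum Lloyd iterations per restart.
#' @param tol convergence threshold on the squared centroid shift.
#' @return A [ClusterModel-class]; `diagnostics` carries the winning
#'   restart's WCSS trace and final WCSS.
#' @export
kmeansFit <- function(x, k, seed = 1, nInit = 10, maxIter = 300, tol = 1e-6) {
  X <- .sampleMatrix(x)
  k <- .assertCount(k, "k", min = 1L)
  if (k > nrow(X))
    stop(sprintf("k = %d exceeds the number of samples (%d)", k, nrow(X)),
         call. = FALSE)
  nInit <- .assertCount(nInit, "nInit", min = 1L)
  best <- NULL
  with_seed(as.integer(seed), {
    for (i in seq_len(nInit)) {
      fit <- .lloyd(X, .kmeansPP(X, k), maxIter, tol)
      if (is.null(best) || fit$wcss < best$wcss) best <- fit
    }
  })
  new("ClusterModel", method = "kmeans", k = k,
      labels = setNames(best$labels, rownames(X)),
      centers = best$centers, trainingSamples = rownames(X),
      seed = as.integer(seed),
      diagnostics = list(wcss = best$wcss, wcss_trace = best$trace))
}

# Lance-Williams Ward agglomeration on a squared Euclidean distance matrix.
# Returns the merge table in hclust coding plus merge heights (equal to twice
# the within-cluster sum-of-squares increase of each merge).
#' @noRd
.wardLinkage <- function(d2) {
  n <- nrow(d2)
  D <- d2
  diag(D) <- Inf
  size <- rep(1, n)
  clusterId <- -seq_len(n)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (s in seq_len(n - 1L)) {
    flat <- which.min(D)
    ij <- arrayInd(flat, dim(D))
    i <- min(ij); j <- max(ij)
    height[s] <- D[i, j]
    pair <- c(clusterId[i], clusterId[j])
    merge[s, ] <- if (all(pair < 0)) sort(pair, decreasing = TRUE) else sort(pair)
    others <- setdiff(which(size > 0), c(i, j))
    ni <- size[i]; nj <- size[j]; nm <- size[others]
    if (length(others)) {
      upd <- ((ni + nm) * D[i, others] + (nj + nm) * D[j, others] -
                nm * D[i, j]) / (ni + nj + nm)
      D[i, others] <- upd
      D[others, i] <- upd
    }
    size[i] <- ni + nj
    size[j] <- 0
    clusterId[i] <- s
    D[j, ] <- Inf
    D[, j] <- Inf
    D[i, i] <- Inf
  }
  list(merge = merge, height = height)
}

#' @noRd
.linkageToHclust <- function(linkage, labels) {
  mergeOrder <- function(i) {
    if (i < 0) return(-i)
    c(mergeOrder(linkage$merge[i, 1L]), mergeOrder(linkage$merge[i, 2L]))
  }
  structure(list(merge = linkage$merge, height = linkage$height,
                 order = mergeOrder(nrow(linkage$merge)),
                 labels = labels, method = "ward",
                 call = match.call(), dist.method = "euclidean"),
            class = "hclust")
}

#' Fit Ward hierarchical clustering
#'
#' Agglomerates samples by the Lance-Williams Ward minimum-variance update on
#' squared Euclidean distances and cuts the dendrogram at `k` clusters.
#' Deterministic (no seed). Merge heights are non-decreasing (Ward is
#' monotone) and equal twice the increase in total within-cluster sum of
#' squares of each merge.
#'
#' @inheritParams kmeansFit
#' @return A [ClusterModel-class]; `diagnostics` carries the merge table and
#'   merge heights.
#' @export
wardFit <- function(x, k) {
  X <- .sampleMatrix(x)
  k <- .assertCount(k, "k", min = 1L)
  if (k > nrow(X))
    stop(sprintf("k = %d exceeds the number of samples (%d)", k, nrow(X)),
         call. = FALSE)
  linkage <- .wardLinkage(.pairwiseDist(X)^2)
  hc <- .linkageToHclust(linkage, rownames(X))
  labels <- stats::cutree(hc, k = k)
  centers <- rowsum(X, labels, reorder = TRUE) /
    tabulate(labels, nbins = k)
  new("ClusterModel", method = "ward", k = k,
      labels = setNames(as.integer(labels), rownames(X)),
      centers = centers, trainingSamples = rownames(X), seed = NA_integer_,
      diagnostics = list(merge = linkage$merge, height = linkage$height))
}
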