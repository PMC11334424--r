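# Bootstrap model selection, final half-sample fit, sub-clustering, PCA.

#' Bootstrap selection of the cluster number and method
#'
#' For every method and candidate `k`, draws `B` without-replacement
#' subsamples of `subsampleFraction * n` samples, clusters each subsample,
#' and records (i) the mean silhouette of the replicate partition on its
#' subsample and (ii) the adjusted Rand index between the replicate's labels
#' and a reference model fitted once on the full data, restricted to the
#' subsample (a stability-against-consensus score). The chosen `(method, k)`
#' maximizes mean silhouette, with ties broken by higher mean ARI and then
#' smaller `k`. The same `B` subsamples are reused across methods and `k`
#' (a paired design). Deterministic given `seed`.
#'
#' @param x `KOSet` with a `clr` assay or a samples-by-features matrix.
#' @param kRange candidate cluster numbers (all >= 2 and <= subsample size).
#' @param methods subset of `c("kmeans", "ward")`.
#' @param B number of bootstrap replicates (>= 2), default 100.
#' @param subsampleFraction fraction of samples per replicate, default 0.8.
#' @param seed master seed of the scan.
#' @param nInit k-means++ restarts per k-means fit.
#' @return A [BootstrapReport-class].
#' @export
bootstrapSelect <- function(x, kRange = 2:10, methods = c("kmeans", "ward"),
                            B = 100, subsampleFraction = 0.8, seed = 1,
                            nInit = 10) {
  X <- .sampleMatrix(x)
  n <- nrow(X)
  kRange <- sort(unique(vapply(kRange, .assertCount, 0L, name = "kRange", min = 2L)))
  methods <- match.arg(methods, c("kmeans", "ward"), several.ok = TRUE)
  B <- .assertCount(B, "B", min = 2L)
  .assertScalarNumber(subsampleFraction, "subsampleFraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  m <- floor(subsampleFraction * n)
  if (max(kRange) > m)
    stop(sprintf("k = %d exceeds the subsample size (%d)", max(kRange), m),
         call. = FALSE)
  D <- .pairwiseDist(X)
  nK <- length(kRange)
  sil <- ari <- setNames(vector("list", length(methods)), methods)
  with_seed(as.integer(seed), {
    subIdx <- replicate(B, sort(sample.int(n, m)), simplify = FALSE)
    refSeeds <- matrix(sample.int(.Machine$integer.max, length(methods) * nK),
                       length(methods), nK)
    repSeeds <- array(sample.int(.Machine$integer.max, length(methods) * nK * B),
                      c(length(methods), nK, B))
  })
  for (mi in seq_along(methods)) {
    method <- methods[mi]
    refLabels <- lapply(seq_len(nK), function(ki) {
      if (method == "kmeans")
        clusterLabels(kmeansFit(X, kRange[ki], seed = refSeeds[mi, ki],
                                nInit = nInit))
      else clusterLabels(wardFit(X, kRange[ki]))
    })
    silM <- ariM <- matrix(NA_real_, nK, B,
                           dimnames = list(paste0("k", kRange), NULL))
    for (b in seq_len(B)) {
      idx <- subIdx[[b]]
      Db <- D[idx, idx]
      if (method == "ward") {
        hc <- .linkageToHclust(.wardLinkage(Db^2), rownames(X)[idx])
        cuts <- matrix(stats::cutree(hc, k = kRange), ncol = nK)
      }
      for (ki in seq_len(nK)) {
        labs <- if (method == "kmeans")
          clusterLabels(kmeansFit(X[idx, , drop = FALSE], kRange[ki],
                                  seed = repSeeds[mi, ki, b], nInit = nInit))
        else cuts[, ki]
        silM[ki, b] <- mean(.silhouetteFromDist(Db, labs))
        ariM[ki, b] <- adjustedRand(labs, refLabels[[ki]][idx])
      }
    }
    sil[[method]] <- silM
    ari[[method]] <- ariM
  }
  grid <- expand.grid(ki = seq_len(nK), mi = seq_along(methods))
  grid$meanSil <- mapply(function(ki, mi) mean(sil[[mi]][ki, ]), grid$ki, grid$mi)
  grid$meanAri <- mapply(function(ki, mi) mean(ari[[mi]][ki, ]), grid$ki, grid$mi)
  ord <- order(-grid$meanSil, -grid$meanAri, kRange[grid$ki], grid$mi)
  best <- grid[ord[1L], ]
  new("BootstrapReport", silhouettes = sil, aris = ari,
      kRange = as.integer(kRange), methods = methods, B = B,
      subsampleFraction = subsampleFraction,
      chosenK = as.integer(kRange[best$ki]),
      chosenMethod = methods[best$mi], seed = as.integer(seed))
}

#' Fit the final clustering on a random half of the samples
#'
#' To limit overfitting, the final k-means model is trained on a seeded
#' random subset containing `trainFraction` of the samples (default one
#' half); every sample, trained on or held out, is then assigned to its
#' nearest centroid. With `trainFraction = 1` this is identical to
#' [kmeansFit()] on the full data with the same seed.
#'
#' @inheritParams kmeansFit
#' @param method only `"kmeans"` supports centroid assignment of held-out
#'   samples.
#' @param trainFraction fraction of samples used for fitting, in (0, 1\].
#' @return A [ClusterModel-class] with labels for all samples and
#'   `trainingSamples` recording the training subset.
#' @export
fitFinal <- function(x, k, method = "kmeans", trainFraction = 0.5, seed = 1,
                     nInit = 10) {
  method <- match.arg(method, "kmeans")
  .assertScalarNumber(trainFraction, "trainFraction", lower = 0, upper = 1,
                      strict_lower = TRUE)
  X <- .sampleMatrix(x)
  n <- nrow(X)
  if (trainFraction == 1) return(kmeansFit(X, k, seed = seed, nInit = nInit))
  with_seed(as.integer(seed), {
    idx <- sort(sample.int(n, max(k, floor(trainFraction * n))))
    fitSeed <- sample.int(.Machine$integer.max, 1L)
  })
  core <- kmeansFit(X[idx, , drop = FALSE], k, seed = fitSeed, nInit = nInit)
  d2 <- .rowDist2(X, clusterCenters(core))
  labels <- max.col(-d2, ties.method = "first")
  new("ClusterModel", method = "kmeans", k = as.integer(k),
      labels = setNames(labels, rownames(X)),
      centers = clusterCenters(core), trainingSamples = rownames(X)[idx],
      seed = as.integer(seed),
      diagnostics = core@diagnostics)
}

#' Sub-cluster each cluster of a fitted model
#'
#' Subsets the samples of every parent cluster and fits a fresh k-means model
#' with `kSub` clusters within each.
#'
#' @inheritParams kmeansFit
#' @param model fitted [ClusterModel-class] whose labels partition the
#'   samples of `x`.
#' @param kSub sub-clusters per parent cluster (every parent needs at least
#'   `2 * kSub` samples).
#' @return named list (one [ClusterModel-class] per parent cluster).
#' @export
subcluster <- function(x, model, kSub = 2, seed = 1, nInit = 10) {
  kSub <- .assertCount(kSub, "kSub", min = 1L)
  X <- .sampleMatrix(x)
  labels <- clusterLabels(model)[rownames(X)]
  if (anyNA(labels))
    stop("model labels do not cover all samples of 'x'", call. = FALSE)
  sizes <- tabulate(labels, nbins = nClusters(model))
  small <- which(sizes < 2L * kSub)
  if (length(small))
    stop(sprintf("cluster %d has %d samples; at least %d required for kSub = %d",
                 small[1L], sizes[small[1L]], 2L * kSub, kSub), call. = FALSE)
  subSeeds <- with_seed(as.integer(seed),
                        sample.int(.Machine$integer.max, nClusters(model)))
  out <- lapply(seq_len(nClusters(model)), function(cl) {
    kmeansFit(X[labels == cl, , drop = FALSE], kSub, seed = subSeeds[cl],
              nInit = nInit)
  })
  names(out) <- as.character(seq_len(nClusters(model)))
  out
}

#' Project samples onto principal components
#'
#' Centered (unscaled) PCA of the sample profiles, returning the scores of
#' the leading components ordered by explained variance.
#'
#' @inheritParams kmeansFit
#' @param nComponents number of components (<= min(n_samples, n_features)).
#' @return samples-by-components score matrix; the per-component fraction of
#'   explained variance is attached as attribute `explained`.
#' @export
pcaProject <- function(x, nComponents = 5) {
  X <- .sampleMatrix(x)
  nComponents <- .assertCount(nComponents, "nComponents", min = 1L)
  if (nComponents > min(dim(X)))
    stop(sprintf("nComponents = %d exceeds min(n_samples, n_features) = %d",
                 nComponents, min(dim(X))), call. = FALSE)
  p <- prcomp(X, center = TRUE, scale. = FALSE, rank. = nComponents)
  scores <- p$x
  attr(scores, "explained") <- (p$sdev^2 / sum(p$sdev^2))[seq_len(nComponents)]
  scores
}
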