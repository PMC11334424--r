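# k-means, Ward, silhouette, ARI, bootstrap selection, final fit,
# sub-clustering, PCA.

test_that("k-means recovers planted blobs and is deterministic", {
  blobs <- makeBlobs(20, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 0.1, seed = 2)
  m1 <- kmeansFit(blobs$X, 3, seed = 7)
  expect_equal(adjustedRand(clusterLabels(m1), blobs$labels), 1)
  m2 <- kmeansFit(blobs$X, 3, seed = 7)
  expect_identical(clusterLabels(m1), clusterLabels(m2))
  expect_identical(clusterCenters(m1), clusterCenters(m2))

  # k = n: every point its own cluster, WCSS = 0
  Xs <- blobs$X[1:6, ]
  ms <- kmeansFit(Xs, 6, seed = 1)
  expect_equal(sort(unique(clusterLabels(ms))), 1:6)
  expect_equal(ms@diagnostics$wcss, 0)
  expect_error(kmeansFit(Xs, 7, seed = 1), "exceeds")
})

test_that("Lloyd's WCSS trace never increases", {
  withr::with_seed(11, X <- matrix(rnorm(200 * 5), 200))
  rownames(X) <- paste0("S", 1:200)
  for (seed in 1:5) {
    tr <- kmeansFit(X, 4, seed = seed, nInit = 1)@diagnostics$wcss_trace
    expect_true(all(diff(tr) <= 1e-8))
  }
})

test_that("Ward separates {0,1} from {10} and has monotone merge heights", {
  X <- matrix(c(0, 1, 10), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  w <- wardFit(X, 2)
  labs <- clusterLabels(w)
  expect_equal(labs[["a"]], labs[["b"]])
  expect_false(labs[["a"]] == labs[["c"]])
  expect_equal(nClusters(wardFit(X, 1)), 1L)
  expect_equal(unname(clusterLabels(wardFit(X, 1))), rep(1L, 3))

  withr::with_seed(3, Y <- matrix(rnorm(40 * 3), 40))
  rownames(Y) <- paste0("S", 1:40)
  h <- wardFit(Y, 2)@diagnostics$height
  expect_true(all(diff(h) >= -1e-10))
})

test_that("Ward merge sequence equals the exhaustive greedy oracle (n <= 8)", {
  for (seed in 1:6) {
    withr::with_seed(seed, X <- matrix(rnorm(8 * 2), 8))
    rownames(X) <- paste0("S", 1:8)
    got <- wardFit(X, 1)@diagnostics
    want <- oracleWardMerges(X)
    expect_identical(mergeSetsFromMatrix(got$merge), want$merges)
    expect_equal(got$height, want$heights, tolerance = 1e-10)
  }
})

test_that("Ward labels agree with hclust ward.D on squared distances", {
  withr::with_seed(8, X <- matrix(rnorm(30 * 4), 30))
  rownames(X) <- paste0("S", 1:30)
  mine <- clusterLabels(wardFit(X, 4))
  ref <- stats::cutree(stats::hclust(stats::dist(X)^2, method = "ward.D"), 4)
  expect_equal(adjustedRand(mine, ref), 1)
})

test_that("silhouette matches the anchor, the brute-force oracle, and cluster::silhouette", {
  X <- matrix(c(0, 0.1, 10, 10.1), 4, 1, dimnames = list(paste0("S", 1:4), NULL))
  expect_equal(silhouetteMean(X, c(1, 1, 2, 2)),
               (9.95 / 10.05 + 9.85 / 9.95) / 2, tolerance = 1e-12)
  expect_equal(round(silhouetteMean(X, c(1, 1, 2, 2)), 3), 0.990)

  for (seed in 1:5) {
    withr::with_seed(seed, {
      Y <- matrix(rnorm(50 * 3), 50)
      labs <- sample(1:4, 50, replace = TRUE)
    })
    rownames(Y) <- paste0("S", 1:50)
    labs <- as.integer(factor(labs))   # ensure all clusters present
    expect_equal(silhouetteMean(Y, labs), oracleSilhouette(Y, labs),
                 tolerance = 1e-10)
    sil <- cluster::silhouette(labs, stats::dist(Y))
    expect_equal(silhouetteMean(Y, labs), mean(sil[, "sil_width"]),
                 tolerance = 1e-10)
  }
  expect_error(silhouetteMean(X, rep(1, 4)), "single cluster")
})

test_that("a random split of one population scores silhouette near zero", {
  reps <- vapply(1:20, function(s) {
    withr::with_seed(s, {
      Y <- matrix(rnorm(60 * 5), 60)
      labs <- sample(rep(1:2, 30))
    })
    rownames(Y) <- paste0("S", 1:60)
    silhouetteMean(Y, labs)
  }, numeric(1))
  expect_lt(abs(mean(reps)), 0.05)
})

test_that("adjusted Rand matches the pair-counting oracle and known values", {
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjustedRand(c(1, 1, 2, 2), c(1, 2, 2, 2)),
               oracleARI(c(1, 1, 2, 2), c(1, 2, 2, 2)))
  expect_equal(adjustedRand(1:4, 1:4), 1)            # all singletons
  expect_equal(adjustedRand(rep(1, 4), rep(2, 4)), 1) # both single-cluster
  expect_error(adjustedRand(1:3, 1:4), "equal length")

  # exhaustive over all partition pairs of n = 5
  parts <- allPartitions(5)
  for (i in seq_along(parts)) for (j in seq(i, length(parts), by = 7)) {
    expect_equal(adjustedRand(parts[[i]], parts[[j]]),
                 oracleARI(parts[[i]], parts[[j]]), tolerance = 1e-12)
  }
  # random partitions of n = 7, cross-checked against mclust too
  for (seed in 1:10) {
    withr::with_seed(seed, {
      a <- sample(1:3, 7, replace = TRUE)
      b <- sample(1:4, 7, replace = TRUE)
    })
    expect_equal(adjustedRand(a, b), oracleARI(a, b), tolerance = 1e-12)
    if (length(unique(a)) > 1 || length(unique(b)) > 1)
      expect_equal(adjustedRand(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
  }
})

test_that("independent random labelings have ARI centered on zero", {
  vals <- vapply(1:100, function(s) {
    withr::with_seed(s, adjustedRand(sample(1:3, 200, replace = TRUE),
                                     sample(1:3, 200, replace = TRUE)))
  }, numeric(1))
  expect_lt(abs(mean(vals)), 0.02)
})

test_that("bootstrap selection finds the planted k and is deterministic", {
  blobs <- makeBlobs(15, rbind(c(0, 0), c(8, 0), c(0, 8)), sd = 0.3, seed = 5)
  rep1 <- bootstrapSelect(blobs$X, kRange = 2:5, B = 10, seed = 42, nInit = 3)
  expect_equal(chosenK(rep1), 3L)
  rep2 <- bootstrapSelect(blobs$X, kRange = 2:5, B = 10, seed = 42, nInit = 3)
  expect_identical(rep1@silhouettes, rep2@silhouettes)
  expect_identical(rep1@aris, rep2@aris)

  # near-zero noise: replicate partitions always agree with the reference
  tight <- makeBlobs(10, rbind(c(0, 0), c(50, 0), c(0, 50)), sd = 1e-4, seed = 1)
  rep3 <- bootstrapSelect(tight$X, kRange = 3, B = 5, seed = 2, nInit = 2)
  expect_true(all(rep3@aris$kmeans == 1))
  expect_true(all(rep3@aris$ward == 1))

  expect_error(bootstrapSelect(blobs$X, kRange = 2:3, B = 1, seed = 1), "B")
  expect_error(bootstrapSelect(blobs$X[1:5, ], kRange = 2:5, B = 5, seed = 1),
               "subsample")
})

test_that("cluster stability degrades with k on unstructured data", {
  # Monte-Carlo tendency, averaged over independent unstructured data sets
  m <- vapply(1:8, function(s) {
    withr::with_seed(s, X <- matrix(rnorm(150 * 2), 150))
    rownames(X) <- paste0("S", 1:150)
    rep <- bootstrapSelect(X, kRange = c(2, 8), B = 10, seed = 100 + s,
                           nInit = 5, methods = "kmeans")
    rowMeans(rep@aris$kmeans)
  }, numeric(2))
  expect_gt(mean(m["k2", ]), mean(m["k8", ]))
})

test_that("the final half-sample fit assigns held-out samples consistently", {
  blobs <- makeBlobs(20, rbind(c(0, 0), c(10, 0), c(0, 10)), sd = 0.2, seed = 9)
  model <- fitFinal(blobs$X, 3, seed = 13)
  expect_equal(length(trainingSamples(model)), 30L)       # half of 60
  expect_equal(adjustedRand(clusterLabels(model), blobs$labels), 1)
  expect_identical(clusterLabels(fitFinal(blobs$X, 3, seed = 13)),
                   clusterLabels(model))
  # trainFraction = 1 is exactly kmeansFit on all data
  expect_identical(clusterLabels(fitFinal(blobs$X, 3, trainFraction = 1, seed = 4)),
                   clusterLabels(kmeansFit(blobs$X, 3, seed = 4)))
  expect_error(fitFinal(blobs$X, 3, trainFraction = 0, seed = 1), "trainFraction")
  expect_error(fitFinal(blobs$X, 3, method = "ward", seed = 1), "kmeans")
})

test_that("sub-clustering recovers planted sub-blobs within each parent", {
  # two parents, each a mixture of two tight sub-blobs
  blobs <- makeBlobs(12, rbind(c(0, 0), c(3, 0), c(40, 0), c(43, 0)),
                     sd = 0.15, seed = 21)
  parent <- rep(1:2, each = 24)
  model <- kmeansFit(blobs$X, 2, seed = 5)
  expect_equal(adjustedRand(clusterLabels(model), parent), 1)
  subs <- subcluster(blobs$X, model, kSub = 2, seed = 6)
  expect_named(subs, c("1", "2"))
  for (p in names(subs)) {
    members <- names(clusterLabels(subs[[p]]))
    expect_setequal(members,
                    names(clusterLabels(model))[clusterLabels(model) ==
                                                  as.integer(p)])
    truthSub <- blobs$labels[match(members, rownames(blobs$X))]
    expect_equal(adjustedRand(clusterLabels(subs[[p]]), truthSub), 1)
  }
  triv <- subcluster(blobs$X, model, kSub = 1, seed = 1)
  expect_true(all(vapply(triv, nClusters, integer(1)) == 1L))
  expect_error(subcluster(blobs$X, model, kSub = 13, seed = 1), "at least")
})

test_that("PCA projection keeps rank structure, orthogonality and separability", {
  withr::with_seed(6, {
    u <- rnorm(40); v <- rnorm(8)
  })
  X1 <- outer(u, v)
  rownames(X1) <- paste0("S", 1:40)
  sc <- pcaProject(X1, 2)
  expect_gt(attr(sc, "explained")[1], 0.999)

  blobs <- makeBlobs(15, rbind(c(0, 0, 0), c(9, 0, 0), c(0, 9, 0)),
                     sd = 0.2, seed = 30)
  sc3 <- pcaProject(blobs$X, 3)
  expect_lt(max(abs(crossprod(sc3) - diag(diag(crossprod(sc3))))), 1e-8)
  km <- kmeansFit(sc3, 3, seed = 2)
  expect_equal(adjustedRand(clusterLabels(km), blobs$labels), 1)
  expect_error(pcaProject(blobs$X, 50), "exceeds")
})
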