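# Rank tests, fold-changes, the marker criterion, permutation FDR,
# pathway roll-ups.

test_that("Kruskal-Wallis matches the anchor, the oracle and stats::kruskal.test", {
  expect_equal(unname(kruskalWallis(list(1:3, 4:6, 7:9))["H"]), 7.2,
               tolerance = 1e-12)
  expect_equal(unname(kruskalWallis(list(1:3, 1:3, 1:3))["H"]), 0)

  for (seed in 1:8) {
    withr::with_seed(seed, {
      groups <- lapply(1:3, function(i) round(rnorm(sample(4:10, 1)), 1)) # ties
    })
    got <- kruskalWallis(groups)
    want <- oracleKW(groups)
    expect_equal(got, want, tolerance = 1e-10)
    ref <- stats::kruskal.test(unlist(groups),
                               rep(seq_along(groups), lengths(groups)))
    expect_equal(unname(got["H"]), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(got["p"]), ref$p.value, tolerance = 1e-10)
  }

  # identical values everywhere: H = 0, p = 1, not an error
  expect_equal(unname(kruskalWallis(list(c(2, 2), c(2, 2, 2)))), c(0, 1))
  # large planted shift is overwhelmingly significant
  withr::with_seed(1, g <- list(rnorm(30), rnorm(30) + 10))
  expect_lt(kruskalWallis(g)["p"], 1e-6)
  expect_error(kruskalWallis(list(1:3)), "two groups")
})

test_that("Dunn z statistics match the brute-force oracle and are antisymmetric", {
  withr::with_seed(5, groups <- lapply(1:4, function(i) round(rnorm(7), 1)))
  got <- dunnPosthoc(groups)
  want <- oracleDunn(groups)
  expect_equal(got$z, want$z, tolerance = 1e-10)
  expect_equal(got$p_bonferroni, want$p_bonferroni, tolerance = 1e-10)
  expect_equal(nrow(got), 6L)
  expect_true(all(got$p_bonferroni <= 1))

  swapped <- dunnPosthoc(groups[c(2, 1, 3, 4)])
  expect_equal(swapped$z[1], -got$z[1], tolerance = 1e-12)
  expect_equal(swapped$p_bonferroni[1], got$p_bonferroni[1], tolerance = 1e-12)

  tied <- dunnPosthoc(list(c(1, 1), c(1, 1), c(1, 1)))
  expect_true(all(tied$p_bonferroni == 1))
  expect_true(all(tied$z == 0))
})

test_that("median log2 fold-change behaves on degenerate and planted inputs", {
  X <- cbind(ko1 = c(5, 5, 5, 1, 1, 1))
  rownames(X) <- paste0("S", 1:6)
  labs <- rep(c("a", "b"), each = 3)
  expect_equal(medianLFC(X, labs, "ko1", "a", "b"), 4)
  expect_equal(medianLFC(X, labs, "ko1", "b", "a"), -4)
  expect_equal(medianLFC(X, rep("a", 6), "ko1", "a", "a"), 0)
  expect_error(medianLFC(X, labs, "ko1", "a", "zzz"), "unknown cluster")
  expect_error(medianLFC(X, labs, "nope", "a", "b"), "unknown KO")

  # median-of-differences flavour equals the direct definition
  withr::with_seed(2, Y <- cbind(k = rnorm(12)))
  rownames(Y) <- paste0("S", 1:12)
  l2 <- rep(c("a", "b"), each = 6)
  direct <- median(outer(Y[1:6, 1], Y[7:12, 1], "-"))
  expect_equal(medianLFC(Y, l2, "k", "a", "b", method = "median_of_differences"),
               direct)
})

test_that("the marker criterion recovers planted markers exactly", {
  sim <- simNormalized(smallScenario(seed = 31))
  truth <- sort(unlist(sim$truth$markers))
  mk <- callMarkers(sim$kset, sim$truth$clusters)
  called <- mk$ko[!is.na(mk$marker_of)]
  expect_setequal(called, truth)
  # marker_of points at the planting cluster
  for (cl in seq_along(sim$truth$markers)) {
    expect_setequal(mk$ko[!is.na(mk$marker_of) & mk$marker_of == cl],
                    sim$truth$markers[[cl]])
  }
  # an infinite fold-change threshold calls nothing
  expect_equal(sum(!is.na(callMarkers(sim$kset, sim$truth$clusters,
                                      minLfc = Inf)$marker_of)), 0L)
  # shuffled labels call nothing at default thresholds
  shuffled <- withr::with_seed(1, sample(sim$truth$clusters))
  expect_equal(sum(!is.na(callMarkers(sim$kset, shuffled)$marker_of)), 0L)
})

test_that("marker calls are invariant to sample order and label renaming", {
  sim <- simNormalized(smallScenario(seed = 8, samplesPerCluster = 15,
                                     nKOs = 150, markersPerCluster = 4))
  X <- t(clrValues(sim$kset))
  labs <- sim$truth$clusters
  base <- callMarkers(X, labs)
  perm <- withr::with_seed(3, sample(nrow(X)))
  reordered <- callMarkers(X[perm, ], labs[perm])
  expect_identical(base$marker_of, reordered$marker_of)

  renamed <- callMarkers(X, c("gamma", "alpha", "beta")[labs])
  map <- c("1" = "gamma", "2" = "alpha", "3" = "beta")
  expect_identical(unname(map[as.character(base$marker_of)]),
                   as.character(renamed$marker_of))
})

test_that("cluster sizes below two are rejected", {
  X <- matrix(rnorm(10), 5, 2, dimnames = list(paste0("S", 1:5), c("a", "b")))
  expect_error(callMarkers(X, c(1, 1, 2, 2, 3)), "fewer than 2")
  expect_error(callMarkers(X, rep(1, 5)), "two clusters")
})

test_that("permutation FDR is zero on planted data and deterministic", {
  sim <- simNormalized(smallScenario(seed = 14))
  pf <- permutationFDR(sim$kset, sim$truth$clusters, nPerm = 25, seed = 5)
  expect_equal(pf@observedMarkers, length(unlist(sim$truth$markers)))
  expect_equal(fdrEstimate(pf), 0)
  expect_false(pf@noObservedMarkers)
  pf2 <- permutationFDR(sim$kset, sim$truth$clusters, nPerm = 25, seed = 5)
  expect_identical(pf@permCounts, pf2@permCounts)
})

test_that("permutation FDR flags the no-observed-markers case", {
  nul <- simulateNull(36, 120, seed = 7)
  kn <- clrNormalize(filterRareKOs(nul$profiles))
  labs <- rep(1:3, each = 12)
  pf <- permutationFDR(kn, labs, nPerm = 10, seed = 2)
  expect_equal(pf@observedMarkers, 0L)
  expect_true(pf@noObservedMarkers)
  expect_equal(fdrEstimate(pf), 0)
})

test_that("pathway roll-ups count marker KOs per pathway and category", {
  mk <- S4Vectors::DataFrame(
    ko = sprintf("K%05d", 1:100),
    marker_of = c(rep("1", 80), rep("2", 10), rep(NA, 10)))
  pm <- data.frame(
    ko_id = c(sprintf("K%05d", 1:76), sprintf("K%05d", 81:85),
              sprintf("K%05d", 1:3)),
    pathway_id = c(rep("map01052", 76), rep("map00195", 5), rep("map99999", 3)),
    pathway_name = c(rep("Polyketide biosynthesis", 76),
                     rep("Photosynthesis", 5), rep("Extra", 3)),
    category = c(rep("Biosynthesis of polyketides", 76),
                 rep("Energy metabolism", 5), rep("Other", 3)),
    stringsAsFactors = FALSE)
  ru <- mapMarkersToPathways(mk, pm)
  cat1 <- ru$categories[ru$categories$cluster == "1", ]
  expect_equal(cat1$n_markers[cat1$category == "Biosynthesis of polyketides"], 76L)
  expect_equal(ru$pathways$n_markers[ru$pathways$pathway_id == "map00195"], 5L)
  # KOs 1:3 map to two pathways: once per pathway, once per category
  expect_equal(ru$pathways$n_markers[ru$pathways$pathway_id == "map99999"], 3L)
  # markers 77:80 of cluster 1 are unmapped
  expect_equal(ru$unmapped$n_unmapped[ru$unmapped$cluster == "1"], 4L)
  expect_equal(ru$unmapped$n_unmapped[ru$unmapped$cluster == "2"], 5L)
})

test_that("top markers are ranked by fold-change with deterministic ties", {
  mk <- S4Vectors::DataFrame(
    ko = c("K00003", "K00001", "K00002", "K00004"),
    H = c(5, 9, 7, 7),
    marker_of = c("1", "1", "1", NA),
    lfc_min_1 = c(4.0, 2.5, 2.5, NA_real_))
  S4Vectors::metadata(mk) <- list(clusters = "1")
  top <- topMarkers(mk, n = 15)
  expect_equal(top$ko, c("K00003", "K00001", "K00002"))  # lfc desc, then H desc
  expect_equal(top$rank, 1:3)
  top1 <- topMarkers(mk, n = 1)
  expect_equal(top1$ko, "K00003")
})

test_that("the strongest planted marker tops its cluster ranking", {
  sim <- simNormalized(smallScenario(seed = 77))
  # boost one known marker far beyond the others on the CLR scale
  X <- t(clrValues(sim$kset))
  star <- sim$truth$markers[[1]][1]
  X[sim$truth$clusters == 1, star] <- X[sim$truth$clusters == 1, star] + 6
  mk <- callMarkers(X, sim$truth$clusters)
  top <- topMarkers(mk, n = 15)
  expect_equal(top$ko[top$cluster == "1"][1], star)
})
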