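# Shared synthetic inputs built in code at test time.

# Well-separated Gaussian blobs: one cluster per row of `centers`.
makeBlobs <- function(nPer, centers, sd = 0.1, seed = 1) {
  centers <- as.matrix(centers)
  withr::with_seed(seed, {
    X <- do.call(rbind, lapply(seq_len(nrow(centers)), function(c) {
      matrix(rnorm(nPer * ncol(centers), 0, sd), nPer) +
        matrix(centers[c, ], nPer, ncol(centers), byrow = TRUE)
    }))
  })
  rownames(X) <- sprintf("S%03d", seq_len(nrow(X)))
  list(X = X, labels = rep(seq_len(nrow(centers)), each = nPer))
}

# Scaled-down planted scenario for unit tests (smaller than the reference
# validation scenario, same structure).
smallScenario <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nClusters = 3, samplesPerCluster = 30, nKOs = 400,
         markersPerCluster = 8, markerDelta = 4, depthLogMean = 18,
         nGCLinkedKOs = 6, gcBeta = 8, contigsPerSample = 2000, seed = seed),
    list(...))
  do.call(koScenario, args)
}

# Generate, prevalence-filter and CLR-normalize in one go.
simNormalized <- function(scenario) {
  sim <- simulateKOProfiles(scenario)
  sim$kset <- clrNormalize(filterRareKOs(sim$profiles))
  sim
}

fixtureDir <- function() system.file("extdata", "synthetic_small",
                                     package = "koclust")

# Basic metadata table that passes QC for hand-built count matrices.
passingMeta <- function(ids, ...) {
  base <- data.frame(sample_id = ids, gene_count = 200000,
                     pct_ko_annotated = 40, has_copy_data = TRUE,
                     is_combined_assembly = FALSE, use_restricted = FALSE,
                     stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) base[[nm]] <- extra[[nm]]
  base
}

randomKOSet <- function(nKO = 20, nSamp = 8, seed = 1, lambda = 50) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nKO * nSamp, lambda), nKO, nSamp,
                dimnames = list(sprintf("K%05d", seq_len(nKO)),
                                sprintf("S%03d", seq_len(nSamp))))
  })
  KOSet(m)
}
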