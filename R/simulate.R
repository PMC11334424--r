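# Seeded synthetic-data generator with planted structure. The scenario
# emulates a compendium of assembled-metagenome KO profiles: per-KO baseline
# abundances are log-normal on the log2 scale, k latent ecosystem clusters
# carry cluster-specific enriched marker KOs with a controlled log2 effect,
# a per-sample GC covariate has cluster-dependent means and drives a
# designated set of GC-linked KOs, per-sample sequencing depth varies
# log-normally, and counts are Poisson draws around the depth-closed
# expected composition. Because marker effects are planted on the log2 scale
# before closure and markers are a small fraction of total abundance, the
# realized CLR-scale shift approximately equals `markerDelta`.

#' Define a synthetic-profile scenario
#'
#' Defaults describe the reference validation scenario: 3 clusters of 60
#' samples, 2000 KOs, 10 planted markers per cluster with a log2 effect of 4,
#' 10 GC-linked KOs with slope 8 CLR units per unit GC fraction, cluster GC
#' means 0.62/0.45/0.45 (sd 0.03), and an archaea-enriched first cluster.
#'
#' @param nClusters number of planted clusters.
#' @param samplesPerCluster samples per cluster (scalar or vector).
#' @param nKOs total number of KOs.
#' @param markersPerCluster planted marker KOs per cluster.
#' @param markerDelta planted log2 abundance shift of a marker in its cluster.
#' @param baselineLogMean,baselineLogSD log2-scale normal parameters of the
#'   per-KO baseline abundance.
#' @param depthLogMean,depthLogSD log2-scale normal parameters of per-sample
#'   sequencing depth (total expected counts).
#' @param gcMeans per-cluster mean GC fraction (recycled to `nClusters`).
#' @param gcSD within-cluster GC standard deviation.
#' @param nGCLinkedKOs number of GC-linked KOs.
#' @param gcBeta planted GC slope (log2 abundance per unit GC fraction).
#' @param archaeaRichCluster cluster index with boosted archaeal contigs
#'   (`NA` to disable).
#' @param contigsPerSample contigs drawn per sample for the taxonomy table.
#' @param seed scenario seed; all outputs are reproducible from it.
#' @return a validated scenario (list, class `koScenario`).
#' @export
koScenario <- function(nClusters = 3, samplesPerCluster = 60, nKOs = 2000,
                       markersPerCluster = 10, markerDelta = 4,
                       baselineLogMean = 6, baselineLogSD = 2,
                       depthLogMean = 21, depthLogSD = 0.5,
                       gcMeans = c(0.62, 0.45, 0.45), gcSD = 0.03,
                       nGCLinkedKOs = 10, gcBeta = 8,
                       archaeaRichCluster = 1, contigsPerSample = 5000,
                       seed = 1) {
  spec <- list(nClusters = .assertCount(nClusters, "nClusters", min = 1L),
               samplesPerCluster = rep_len(as.integer(samplesPerCluster), nClusters),
               nKOs = .assertCount(nKOs, "nKOs", min = 2L),
               markersPerCluster = .assertCount(markersPerCluster,
                                                "markersPerCluster", min = 0L),
               markerDelta = markerDelta,
               baselineLogMean = baselineLogMean,
               baselineLogSD = .assertScalarNumber(baselineLogSD, "baselineLogSD",
                                                   lower = 0, strict_lower = TRUE),
               depthLogMean = depthLogMean,
               depthLogSD = .assertScalarNumber(depthLogSD, "depthLogSD", lower = 0),
               gcMeans = rep_len(as.numeric(gcMeans), nClusters),
               gcSD = .assertScalarNumber(gcSD, "gcSD", lower = 0),
               nGCLinkedKOs = .assertCount(nGCLinkedKOs, "nGCLinkedKOs", min = 0L),
               gcBeta = gcBeta,
               archaeaRichCluster = archaeaRichCluster,
               contigsPerSample = .assertCount(contigsPerSample,
                                               "contigsPerSample", min = 1L),
               seed = as.integer(seed))
  if (any(spec$samplesPerCluster < 1L))
    stop("every cluster needs at least one sample", call. = FALSE)
  if (any(spec$gcMeans <= 0 | spec$gcMeans >= 1))
    stop("gcMeans must lie strictly inside (0, 1)", call. = FALSE)
  if (spec$markersPerCluster * spec$nClusters + spec$nGCLinkedKOs > spec$nKOs)
    stop("markersPerCluster * nClusters + nGCLinkedKOs exceeds nKOs",
         call. = FALSE)
  if (!is.na(spec$archaeaRichCluster) &&
      (spec$archaeaRichCluster < 1 || spec$archaeaRichCluster > spec$nClusters))
    stop("archaeaRichCluster out of range", call. = FALSE)
  structure(spec, class = "koScenario")
}

.ECOSYSTEM_TYPES <- c("Soil-like", "Aquatic-like", "Anaerobic-like")

#' Generate a synthetic profile compendium with planted structure
#'
#' @param scenario a [koScenario()]; its `seed` makes the output fully
#'   reproducible (identical scenario, identical bytes).
#' @return list of class `koSimulation`: `profiles` (a [KOSet-class] with
#'   counts and sample metadata, including `true_cluster`), `pathwayMap`
#'   (markers of each cluster share a planted pathway/category; every KO also
#'   carries a background pathway), `taxonomy` (per-sample contig counts per
#'   domain) and `truth` (planted cluster labels, marker sets, GC-linked KO
#'   set, archaea-rich cluster, the scenario).
#' @export
simulateKOProfiles <- function(scenario) {
  stopifnot(inherits(scenario, "koScenario"))
  s <- scenario
  n <- sum(s$samplesPerCluster)
  cluster <- rep(seq_len(s$nClusters), s$samplesPerCluster)
  sampleIds <- sprintf("S%04d", seq_len(n))
  koIds <- sprintf("K%05d", seq_len(s$nKOs))
  with_seed(s$seed, {
    special <- sample.int(s$nKOs, s$nClusters * s$markersPerCluster + s$nGCLinkedKOs)
    markers <- if (s$markersPerCluster > 0)
      split(koIds[special[seq_len(s$nClusters * s$markersPerCluster)]],
            rep(seq_len(s$nClusters), each = s$markersPerCluster))
    else setNames(rep(list(character(0)), s$nClusters),
                  seq_len(s$nClusters))
    gcKOs <- if (s$nGCLinkedKOs > 0)
      koIds[special[s$nClusters * s$markersPerCluster + seq_len(s$nGCLinkedKOs)]]
    else character(0)
    mu <- rnorm(s$nKOs, s$baselineLogMean, s$baselineLogSD)
    names(mu) <- koIds
    gc <- pmin(pmax(rnorm(n, s$gcMeans[cluster], s$gcSD), 0.01), 0.99)
    depth <- 2^rnorm(n, s$depthLogMean, s$depthLogSD)
    logA <- matrix(mu, s$nKOs, n, dimnames = list(koIds, sampleIds))
    for (c in seq_len(s$nClusters))
      logA[markers[[c]], cluster == c] <-
        logA[markers[[c]], cluster == c] + s$markerDelta
    if (length(gcKOs))
      logA[gcKOs, ] <- logA[gcKOs, ] +
        matrix(s$gcBeta * (gc - mean(gc)), length(gcKOs), n, byrow = TRUE)
    expected <- 2^logA
    expected <- sweep(expected, 2L, colSums(expected), "/")   # close composition
    expected <- sweep(expected, 2L, depth, "*")
    counts <- matrix(rpois(length(expected), expected), s$nKOs, n,
                     dimnames = dimnames(expected))
    sampleTab <- data.frame(
      sample_id = sampleIds,
      ecosystem_type = rep_len(.ECOSYSTEM_TYPES, s$nClusters)[cluster],
      ecosystem = "Environmental",
      gc_content = gc,
      gene_count = round(runif(n, 150000, 500000)),
      pct_ko_annotated = round(runif(n, 35, 45), 1),
      has_copy_data = TRUE,
      is_combined_assembly = FALSE,
      use_restricted = FALSE,
      true_cluster = cluster,
      stringsAsFactors = FALSE)
    taxProbs <- matrix(rep(c(0.966, 0.010, 0.012, 0.006, 0.006), each = n),
                       n, 5, dimnames = list(sampleIds, .TAX_DOMAINS))
    if (!is.na(s$archaeaRichCluster)) {
      rich <- cluster == s$archaeaRichCluster
      taxProbs[rich, "archaea"] <- 0.150
      taxProbs[rich, "bacteria"] <- 0.826
    }
    taxCounts <- t(vapply(seq_len(n), function(i)
      rmultinom(1L, s$contigsPerSample, taxProbs[i, ])[, 1L],
      numeric(5)))
    taxonomy <- data.frame(sample_id = sampleIds, taxCounts,
                           stringsAsFactors = FALSE)
    names(taxonomy)[-1L] <- .TAX_DOMAINS
  })
  pmBg <- data.frame(ko_id = koIds,
                     pathway_id = sprintf("map%05d", (seq_len(s$nKOs) - 1L) %% 20L + 1L),
                     pathway_name = sprintf("Background pathway %d",
                                            (seq_len(s$nKOs) - 1L) %% 20L + 1L),
                     category = "Background", stringsAsFactors = FALSE)
  pmMk <- do.call(rbind, lapply(seq_len(s$nClusters), function(c) {
    if (!length(markers[[c]])) return(NULL)
    data.frame(ko_id = markers[[c]],
               pathway_id = sprintf("map9%04d", c),
               pathway_name = sprintf("Planted marker pathway %d", c),
               category = sprintf("Planted markers %d", c),
               stringsAsFactors = FALSE)
  }))
  pmGc <- if (length(gcKOs))
    data.frame(ko_id = gcKOs, pathway_id = "map80000",
               pathway_name = "Planted GC-linked pathway",
               category = "Planted GC-linked", stringsAsFactors = FALSE)
  else NULL
  pathwayMap <- rbind(pmBg, pmMk, pmGc)
  rownames(pathwayMap) <- NULL
  profiles <- KOSet(counts, sampleData = sampleTab)
  truth <- list(clusters = setNames(cluster, sampleIds), markers = markers,
                gcKOs = gcKOs, archaeaRichCluster = s$archaeaRichCluster,
                scenario = unclass(s))
  structure(list(profiles = profiles, pathwayMap = pathwayMap,
                 taxonomy = taxonomy, truth = truth),
            class = "koSimulation")
}

#' Generate a structureless null compendium
#'
#' Single-population version of [simulateKOProfiles()]: no clusters, no
#' planted markers, no GC-linked KOs (GC is drawn around a common mean).
#' Intended for type-I-error and permutation checks.
#'
#' @param nSamples,nKOs dimensions.
#' @param seed generator seed.
#' @return list with `profiles` (a [KOSet-class] with metadata passing QC).
#' @export
simulateNull <- function(nSamples, nKOs, seed = 1) {
  sc <- koScenario(nClusters = 1, samplesPerCluster = nSamples, nKOs = nKOs,
                   markersPerCluster = 0, markerDelta = 0,
                   gcMeans = 0.5, nGCLinkedKOs = 0, gcBeta = 0,
                   archaeaRichCluster = NA, seed = seed)
  sim <- simulateKOProfiles(sc)
  list(profiles = sim$profiles, taxonomy = sim$taxonomy, truth = sim$truth)
}

#' Write a simulation to disk in the canonical file formats
#'
#' Writes `counts.tsv` (samples as rows), `samples.tsv`, `pathways.tsv`,
#' `taxonomy.tsv`, `truth.json` and `scenario.json` into `dir`, all
#' re-readable with the package's readers and regenerable byte-identically
#' from the recorded scenario seed.
#'
#' @param sim a `koSimulation` from [simulateKOProfiles()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeFixture <- function(sim, dir) {
  stopifnot(inherits(sim, "koSimulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeCountMatrix(sim$profiles, file.path(dir, "counts.tsv"))
  writeSampleTable(colData(sim$profiles), file.path(dir, "samples.tsv"))
  writePathwayMap(sim$pathwayMap, file.path(dir, "pathways.tsv"))
  writeTaxonomyTable(sim$taxonomy, file.path(dir, "taxonomy.tsv"))
  truthOut <- sim$truth
  truthOut$clusters <- as.list(truthOut$clusters)   # keep sample names in JSON
  jsonlite::write_json(truthOut, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(sim$truth$scenario, file.path(dir, "scenario.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Rebuild a scenario from its serialized form
#'
#' @param path `scenario.json` written by [writeFixture()].
#' @return a [koScenario()].
#' @export
readScenario <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  koScenario(nClusters = s$nClusters, samplesPerCluster = s$samplesPerCluster,
             nKOs = s$nKOs, markersPerCluster = s$markersPerCluster,
             markerDelta = s$markerDelta, baselineLogMean = s$baselineLogMean,
             baselineLogSD = s$baselineLogSD, depthLogMean = s$depthLogMean,
             depthLogSD = s$depthLogSD, gcMeans = s$gcMeans, gcSD = s$gcSD,
             nGCLinkedKOs = s$nGCLinkedKOs, gcBeta = s$gcBeta,
             archaeaRichCluster = if (is.null(s$archaeaRichCluster)) NA
                                  else s$archaeaRichCluster,
             contigsPerSample = s$contigsPerSample, seed = s$seed)
}
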