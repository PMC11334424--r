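#' KOSet: a sample-by-KO profile container
#'
#' `KOSet` extends [SummarizedExperiment::SummarizedExperiment] with KEGG
#' orthologs (KOs) as rows and metagenome samples as columns. The `counts`
#' assay holds estimated gene copies (non-negative, read-coverage weighted
#' sums over all genes carrying each KO); [clrNormalize()] adds a `clr` assay
#' of per-sample centered log2-ratio values. Sample metadata (ecosystem
#' fields, GC content, gene counts, QC flags) lives in `colData`.
#'
#' @slot .. inherited from `SummarizedExperiment`.
#' @aliases KOSet-class
#' @exportClass KOSet
setClass("KOSet", contains = "SummarizedExperiment")

setValidity("KOSet", function(object) {
  msgs <- character()
  if (!"counts" %in% assayNames(object))
    msgs <- c(msgs, "a 'counts' assay is required")
  if (nrow(object) < 1L || ncol(object) < 1L)
    msgs <- c(msgs, "at least one KO (row) and one sample (column) required")
  rn <- rownames(object); cn <- colnames(object)
  if (is.null(rn) || is.null(cn))
    msgs <- c(msgs, "KO (row) and sample (column) identifiers are required")
  else {
    if (anyDuplicated(rn))
      msgs <- c(msgs, sprintf("duplicate KO identifier: '%s'", rn[duplicated(rn)][1L]))
    if (anyDuplicated(cn))
      msgs <- c(msgs, sprintf("duplicate sample identifier: '%s'", cn[duplicated(cn)][1L]))
  }
  if ("counts" %in% assayNames(object)) {
    cts <- assay(object, "counts")
    if (!is.numeric(cts) || anyNA(cts) || any(!is.finite(cts)))
      msgs <- c(msgs, "counts must be finite and non-missing")
    else if (any(cts < 0))
      msgs <- c(msgs, "counts must be non-negative")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a KOSet
#'
#' @param counts numeric matrix of estimated gene copies with KOs as rows and
#'   samples as columns (dimnames required; use [readCountMatrix()] for files).
#' @param sampleData optional `DataFrame`/`data.frame` of per-sample metadata,
#'   matched to samples by a `sample_id` column or by row names.
#' @return A [KOSet-class] object.
#' @examples
#' m <- matrix(rpois(12, 50), 4, 3,
#'             dimnames = list(paste0("K0000", 1:4), paste0("S", 1:3)))
#' KOSet(m)
#' @export
KOSet <- function(counts, sampleData = NULL) {
  if (!is.matrix(counts)) counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  se <- SummarizedExperiment(assays = list(counts = counts))
  obj <- new("KOSet", se)
  if (!is.null(sampleData)) obj <- addSampleData(obj, sampleData)
  obj
}

#' Fitted partition of samples
#'
#' Holds the result of [kmeansFit()], [wardFit()] or [fitFinal()]: integer
#' cluster labels in `1..k` for every sample, the fitting method, the subset
#' of samples the model was trained on, and (for k-means) the centroids used
#' to assign held-out samples.
#'
#' @slot method "kmeans" or "ward".
#' @slot k number of clusters.
#' @slot labels named integer vector, one label in `1..k` per sample.
#' @slot centers k-by-features centroid matrix (k-means; cluster means for Ward).
#' @slot trainingSamples sample identifiers used for fitting.
#' @slot seed integer seed used (NA for the deterministic Ward fit).
#' @slot diagnostics list of fit diagnostics (WCSS trace, merge heights, ...).
#' @aliases ClusterModel-class
#' @exportClass ClusterModel
setClass("ClusterModel",
         representation(method = "character", k = "integer",
                        labels = "integer", centers = "matrix",
                        trainingSamples = "character", seed = "integer",
                        diagnostics = "list"))

setValidity("ClusterModel", function(object) {
  msgs <- character()
  if (!object@method %in% c("kmeans", "ward"))
    msgs <- c(msgs, "method must be 'kmeans' or 'ward'")
  if (object@k < 1L) msgs <- c(msgs, "k must be >= 1")
  if (is.null(names(object@labels)))
    msgs <- c(msgs, "labels must be named by sample")
  if (any(object@labels < 1L | object@labels > object@k))
    msgs <- c(msgs, "labels must lie in 1..k")
  train <- intersect(object@trainingSamples, names(object@labels))
  if (length(train) && !all(seq_len(object@k) %in% object@labels[train]))
    msgs <- c(msgs, "every cluster must be non-empty on the training set")
  if (length(msgs)) msgs else TRUE
})

#' Bootstrap model-selection report
#'
#' Per method and candidate k, the silhouette and adjusted-Rand-index scores
#' of `B` subsample replicates, plus the jointly chosen method and k
#' (highest mean silhouette; ties broken by higher mean ARI, then smaller k).
#'
#' @slot silhouettes,aris named list (per method) of k-by-B score matrices.
#' @slot kRange candidate cluster numbers scanned.
#' @slot methods clustering methods scanned.
#' @slot B number of bootstrap replicates.
#' @slot subsampleFraction fraction of samples drawn (without replacement).
#' @slot chosenK,chosenMethod the selected model.
#' @slot seed master seed of the scan.
#' @aliases BootstrapReport-class
#' @exportClass BootstrapReport
setClass("BootstrapReport",
         representation(silhouettes = "list", aris = "list",
                        kRange = "integer", methods = "character",
                        B = "integer", subsampleFraction = "numeric",
                        chosenK = "integer", chosenMethod = "character",
                        seed = "integer"))

setValidity("BootstrapReport", function(object) {
  msgs <- character()
  sil <- unlist(object@silhouettes, use.names = FALSE)
  if (length(sil) && (any(sil < -1 - 1e-12) || any(sil > 1 + 1e-12)))
    msgs <- c(msgs, "silhouette scores must lie in [-1, 1]")
  ari <- unlist(object@aris, use.names = FALSE)
  if (length(ari) && any(ari > 1 + 1e-12))
    msgs <- c(msgs, "adjusted Rand indices cannot exceed 1")
  if (length(object@chosenK) && !object@chosenK %in% object@kRange)
    msgs <- c(msgs, "chosenK must lie in the scanned range")
  if (length(msgs)) msgs else TRUE
})

#' Permutation false-discovery estimate for the marker criterion
#'
#' @slot observedMarkers number of marker KOs called on the real labels.
#' @slot permCounts false-positive marker counts under each label permutation.
#' @slot fdrEstimate mean permutation count divided by
#'   `max(observedMarkers, 1)`.
#' @slot noObservedMarkers flag set when no markers were observed (the
#'   estimate is then reported as 0 by convention).
#' @slot seed permutation seed.
#' @aliases PermutationFDR-class
#' @exportClass PermutationFDR
setClass("PermutationFDR",
         representation(observedMarkers = "integer", permCounts = "integer",
                        fdrEstimate = "numeric", noObservedMarkers = "logical",
                        seed = "integer"))

setValidity("PermutationFDR", function(object) {
  msgs <- character()
  if (any(object@permCounts < 0L))
    msgs <- c(msgs, "permutation counts must be non-negative")
  expected <- mean(object@permCounts) / max(object@observedMarkers, 1L)
  if (abs(object@fdrEstimate - expected) > 1e-12)
    msgs <- c(msgs, "fdrEstimate must equal mean(permCounts)/max(observed, 1)")
  if (length(msgs)) msgs else TRUE
})

#' Cross-cluster comparison of a per-sample variable
#'
#' Kruskal-Wallis test plus Dunn post-hoc pairwise comparisons of one
#' per-sample quantity (GC content, a taxonomy fraction, ...) across clusters.
#'
#' @slot variable name of the compared quantity.
#' @slot groups named list of per-cluster value vectors (missing values dropped).
#' @slot H,p Kruskal-Wallis statistic and chi-square p-value.
#' @slot dunn data.frame of pairwise z and Bonferroni-corrected p-values.
#' @slot nDropped per-cluster count of dropped missing values.
#' @aliases GroupComparison-class
#' @exportClass GroupComparison
setClass("GroupComparison",
         representation(variable = "character", groups = "list",
                        H = "numeric", p = "numeric", dunn = "data.frame",
                        nDropped = "integer"))
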