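# Accessors and show methods.

#' @rdname KOSet
#' @param x a `KOSet`.
#' @export
koCounts <- function(x) assay(x, "counts")

#' @rdname KOSet
#' @export
clrValues <- function(x) {
  if (!"clr" %in% assayNames(x))
    stop("no 'clr' assay; run clrNormalize() first", call. = FALSE)
  assay(x, "clr")
}

#' @rdname KOSet
#' @export
koIds <- function(x) rownames(x)

#' @rdname KOSet
#' @export
sampleIds <- function(x) colnames(x)

#' @rdname KOSet
#' @export
sampleData <- function(x) colData(x)

#' Attach per-sample metadata to a KOSet
#'
#' Rows are matched to samples by the `sample_id` column (or row names).
#' Every sample in the KOSet must be present in the table; extra table rows
#' are dropped.
#'
#' @param x a `KOSet`.
#' @param table `DataFrame`/`data.frame` of sample metadata.
#' @return `x` with updated `colData`.
#' @export
addSampleData <- function(x, table) {
  tab <- as.data.frame(table, stringsAsFactors = FALSE)
  ids <- if ("sample_id" %in% names(tab)) as.character(tab$sample_id) else rownames(tab)
  if (is.null(ids)) stop("sample metadata needs a 'sample_id' column", call. = FALSE)
  missing <- setdiff(sampleIds(x), ids)
  if (length(missing))
    stop(sprintf("sample '%s' has no metadata row", missing[1L]), call. = FALSE)
  tab <- tab[match(sampleIds(x), ids), , drop = FALSE]
  rownames(tab) <- sampleIds(x)
  colData(x) <- DataFrame(tab)
  x
}

setMethod("show", "KOSet", function(object) {
  cat(sprintf("KOSet: %d KOs x %d samples\n", nrow(object), ncol(object)))
  cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
  if (ncol(colData(object)))
    cat("sampleData:", paste(colnames(colData(object)), collapse = ", "), "\n")
})

#' @rdname ClusterModel-class
#' @param x a `ClusterModel`.
#' @export
clusterLabels <- function(x) x@labels

#' @rdname ClusterModel-class
#' @export
clusterMethod <- function(x) x@method

#' @rdname ClusterModel-class
#' @export
nClusters <- function(x) x@k

#' @rdname ClusterModel-class
#' @export
clusterCenters <- function(x) x@centers

#' @rdname ClusterModel-class
#' @export
trainingSamples <- function(x) x@trainingSamples

setMethod("show", "ClusterModel", function(object) {
  cat(sprintf("ClusterModel: %s, k = %d, %d samples (%d used for training)\n",
              object@method, object@k, length(object@labels),
              length(object@trainingSamples)))
  print(table(cluster = object@labels))
})

#' @rdname BootstrapReport-class
#' @param x a `BootstrapReport`.
#' @export
chosenK <- function(x) x@chosenK

#' @rdname BootstrapReport-class
#' @export
chosenMethod <- function(x) x@chosenMethod

#' Summarise a bootstrap model-selection scan
#'
#' @param object a `BootstrapReport`.
#' @param ... ignored.
#' @return data.frame with one row per (method, k): mean/sd silhouette and ARI.
#' @export
setMethod("summary", "BootstrapReport", function(object, ...) {
  rows <- lapply(object@methods, function(m) {
    sil <- object@silhouettes[[m]]; ari <- object@aris[[m]]
    data.frame(method = m, k = object@kRange,
               mean_silhouette = rowMeans(sil), sd_silhouette = apply(sil, 1, sd),
               mean_ari = rowMeans(ari), sd_ari = apply(ari, 1, sd),
               row.names = NULL)
  })
  do.call(rbind, rows)
})

setMethod("show", "BootstrapReport", function(object) {
  cat(sprintf("BootstrapReport: B = %d, subsample = %.2f, methods = %s\n",
              object@B, object@subsampleFraction,
              paste(object@methods, collapse = "/")))
  cat(sprintf("chosen: %s with k = %d\n", object@chosenMethod, object@chosenK))
  print(summary(object), digits = 3)
})

#' @rdname PermutationFDR-class
#' @param x a `PermutationFDR`.
#' @export
fdrEstimate <- function(x) x@fdrEstimate

setMethod("show", "PermutationFDR", function(object) {
  cat(sprintf("PermutationFDR: %d observed markers, %d permutations\n",
              object@observedMarkers, length(object@permCounts)))
  cat(sprintf("mean false positives = %.3f, FDR estimate = %.4f%s\n",
              mean(object@permCounts), object@fdrEstimate,
              if (object@noObservedMarkers) " (no observed markers)" else ""))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison of '%s' across %d clusters\n",
              object@variable, length(object@groups)))
  cat(sprintf("Kruskal-Wallis H = %.4g, p = %.3g\n", object@H, object@p))
  print(object@dunn, digits = 3)
})
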