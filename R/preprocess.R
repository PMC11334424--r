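# Sample QC, ecosystem labelling, rare-KO filtering and CLR normalization.
# Boundary semantics follow the selection rules literally: QC thresholds are
# strict (a sample needs *more than* 100,000 genes and *more than* 30%
# KO-annotated), while the prevalence filter removes KOs present in *less
# than* 10% of samples (exactly 10% is kept).

#' Apply sample-selection quality control
#'
#' Retains exactly the samples that satisfy all five selection criteria:
#' no use restriction, `gene_count > minGenes`,
#' `pct_ko_annotated > minPctAnnotated`, estimated gene-copy data available,
#' and not a combined assembly of multiple read libraries. Samples with a
#' missing value for a criterion fail that criterion.
#'
#' @param x `KOSet` with counts; sample metadata either already attached or
#'   supplied via `samples`.
#' @param samples optional sample table (`DataFrame`/`data.frame`); every
#'   sample in `x` must be present.
#' @param minGenes minimum assembled gene count (strict, default 100000).
#' @param minPctAnnotated minimum percent of genes with a KO annotation
#'   (strict, default 30).
#' @return list with `kset` (the filtered `KOSet`) and `report`, a data.frame
#'   of per-sample pass/fail booleans for each criterion plus `pass`.
#' @export
applySampleQC <- function(x, samples = NULL, minGenes = 100000,
                          minPctAnnotated = 30) {
  .assertScalarNumber(minGenes, "minGenes", lower = 0)
  .assertScalarNumber(minPctAnnotated, "minPctAnnotated", lower = 0, upper = 100)
  if (!is.null(samples)) x <- addSampleData(x, samples)
  cd <- as.data.frame(colData(x), stringsAsFactors = FALSE)
  needed <- c("use_restricted", "gene_count", "pct_ko_annotated",
              "has_copy_data", "is_combined_assembly")
  absent <- setdiff(needed, names(cd))
  if (length(absent))
    stop(sprintf("sample metadata lacks QC field(s): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  passOf <- function(v) !is.na(v) & v
  report <- data.frame(
    sample_id = sampleIds(x),
    unrestricted = passOf(!cd$use_restricted),
    min_genes = !is.na(cd$gene_count) & cd$gene_count > minGenes,
    min_pct_annotated = !is.na(cd$pct_ko_annotated) &
      cd$pct_ko_annotated > minPctAnnotated,
    has_copy_data = passOf(cd$has_copy_data),
    single_assembly = passOf(!cd$is_combined_assembly),
    stringsAsFactors = FALSE)
  report$pass <- report$unrestricted & report$min_genes &
    report$min_pct_annotated & report$has_copy_data & report$single_assembly
  attr(report, "n_input") <- nrow(report)
  attr(report, "n_passed") <- sum(report$pass)
  if (!any(report$pass))
    stop("no sample passes QC", call. = FALSE)
  list(kset = x[, report$pass], report = report)
}

#' Derive ecosystem labels
#'
#' A sample is labelled by its `ecosystem_type` when more than `minCount`
#' samples in the table share that type; otherwise the broader `ecosystem`
#' field is used, and `"Unclassified"` when both are missing. The count is
#' global over the supplied table (exactly `minCount` sharers falls back to
#' the broader field).
#'
#' @param samples sample table (`DataFrame`/`data.frame`) or a `KOSet` with
#'   attached metadata.
#' @param minCount sharing threshold (strict), default 100.
#' @return the input with an `ecosystem_label` column added/overwritten.
#' @export
assignEcosystemLabels <- function(samples, minCount = 100) {
  minCount <- .assertCount(minCount, "minCount")
  if (is(samples, "KOSet")) {
    cd <- assignEcosystemLabels(colData(samples), minCount)
    colData(samples) <- cd
    return(samples)
  }
  tab <- as.data.frame(samples, stringsAsFactors = FALSE)
  type <- if ("ecosystem_type" %in% names(tab)) as.character(tab$ecosystem_type)
          else rep(NA_character_, nrow(tab))
  eco <- if ("ecosystem" %in% names(tab)) as.character(tab$ecosystem)
         else rep(NA_character_, nrow(tab))
  counts <- table(type[!is.na(type)])
  keepType <- !is.na(type) & as.vector(counts[type]) > minCount
  keepType[is.na(keepType)] <- FALSE
  label <- as.character(ifelse(keepType, type, eco))
  label[is.na(label)] <- "Unclassified"
  tab$ecosystem_label <- label
  if (is(samples, "DataFrame")) {
    samples$ecosystem_label <- label
    samples
  } else tab
}

#' Remove rare KOs
#'
#' Keeps KOs whose prevalence (fraction of samples with a strictly positive
#' count) is at least `minPrevalence`; i.e. KOs present in less than
#' `minPrevalence` of samples are removed. The sample set is unchanged.
#' Idempotent.
#'
#' @param x `KOSet`.
#' @param minPrevalence fraction in \[0,1\], default 0.10.
#' @return the filtered `KOSet`.
#' @export
filterRareKOs <- function(x, minPrevalence = 0.10) {
  .assertScalarNumber(minPrevalence, "minPrevalence", lower = 0, upper = 1)
  prev <- rowMeans(koCounts(x) > 0)
  keep <- prev >= minPrevalence
  if (!any(keep))
    stop("prevalence filter removed every KO; downstream analysis undefined",
         call. = FALSE)
  x[keep, ]
}

#' Centered log2-ratio (CLR) normalization
#'
#' Per sample i and KO j computes
#' `clr[j,i] = log2(x[j,i] + prior) - mean_k log2(x[k,i] + prior)`,
#' the log2 abundance centered on the sample's mean log2 abundance over the
#' retained KOs, so zero marks a KO whose abundance equals the geometric mean
#' of its sample. The deterministic point-estimate CLR with a pseudocount
#' prior (default 0.5, the uniform prior of the ALDEx2 family) is used;
#' `prior = 0` is permitted only when no zero counts remain.
#'
#' @param x `KOSet` (normalization runs over its current, i.e. already
#'   prevalence-filtered, KO set).
#' @param prior pseudocount added to every count before taking logs.
#' @return `x` with a `clr` assay added; the prior is recorded in
#'   `metadata(x)$clr_prior`.
#' @export
clrNormalize <- function(x, prior = 0.5) {
  .assertScalarNumber(prior, "prior", lower = 0)
  cts <- koCounts(x)
  if (prior == 0 && any(cts == 0))
    stop("prior = 0 requires strictly positive counts", call. = FALSE)
  lg <- log2(cts + prior)
  clr <- sweep(lg, 2L, colMeans(lg), "-")
  assay(x, "clr") <- clr
  metadata(x)$clr_prior <- prior
  x
}
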