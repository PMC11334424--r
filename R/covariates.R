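# Linking clusters to per-sample covariates: GC content and contig-level
# taxonomy via Kruskal-Wallis/Dunn, and per-KO linear regression of CLR
# abundance on GC content with Pearson r and a Wald test.

#' Compare a per-sample variable across clusters
#'
#' Kruskal-Wallis across clusters followed by Dunn's pairwise post-hoc tests
#' on the per-cluster value vectors. Missing values are dropped per sample
#' (counts recorded); a cluster with fewer than two non-missing values is an
#' error.
#'
#' @param values numeric vector, one value per sample.
#' @param labels cluster assignment per sample.
#' @param variable name of the compared quantity (for reporting).
#' @return A [GroupComparison-class].
#' @export
compareAcrossClusters <- function(values, labels, variable = "value") {
  if (length(values) != length(labels))
    stop("'values' and 'labels' must have equal length", call. = FALSE)
  f <- droplevels(factor(labels))
  keep <- !is.na(values)
  nDropped <- vapply(levels(f), function(l) sum(f == l & !keep), integer(1))
  groups <- split(values[keep], f[keep])
  short <- names(groups)[lengths(groups) < 2L]
  missingLev <- setdiff(levels(f), names(groups))
  if (length(c(missingLev, short)))
    stop(sprintf("cluster '%s' has fewer than 2 non-missing values",
                 c(missingLev, short)[1L]), call. = FALSE)
  kw <- kruskalWallis(groups)
  new("GroupComparison", variable = variable, groups = groups,
      H = unname(kw["H"]), p = unname(kw["p"]), dunn = dunnPosthoc(groups),
      nDropped = nDropped)
}

#' Per-sample taxonomy fractions
#'
#' Converts contig counts per domain into per-sample fractions (each domain
#' divided by the sample's total contigs, so fractions sum to 1). Samples
#' with zero total contigs are dropped with a warning.
#'
#' @param tax data.frame from [readTaxonomyTable()].
#' @return data.frame `sample_id` + one fraction column per domain.
#' @export
taxonomyProportions <- function(tax) {
  m <- as.matrix(tax[.TAX_DOMAINS])
  tot <- rowSums(m)
  drop <- tot <= 0
  if (any(drop)) {
    warning(sprintf("dropped %d sample(s) with zero total contigs", sum(drop)))
    m <- m[!drop, , drop = FALSE]
    tot <- tot[!drop]
  }
  out <- data.frame(sample_id = tax$sample_id[!drop], m / tot,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Regress every KO's normalized abundance on GC content
#'
#' Per KO, ordinary least squares of CLR abundance on the per-sample GC
#' fraction, with the Pearson correlation coefficient as goodness of fit and
#' a Wald test of the slope via `t = r * sqrt((n-2)/(1-r^2))` against the t
#' distribution with `n - 2` degrees of freedom (two-sided). Samples with
#' missing GC are dropped. A KO with constant abundance gets slope 0,
#' Pearson r 0 and p-value 1; constant GC is an error. Bonferroni-adjusted p-values
#' across KOs are reported alongside the raw p-values.
#'
#' @param x `KOSet` with a `clr` assay or samples-by-KOs matrix.
#' @param gc per-sample GC fraction in \[0,1\] (taken from
#'   `sampleData(x)$gc_content` when `x` is a `KOSet` and `gc` is missing).
#' @return `S4Vectors::DataFrame` with one row per KO: `ko`, `slope`
#'   (CLR units per unit GC fraction), `intercept`, `pearson_r`, `t`,
#'   `wald_p`, `p_bonferroni`, `n`.
#' @export
gcKORegression <- function(x, gc = NULL) {
  X <- .sampleMatrix(x)
  if (is.null(gc)) {
    if (!is(x, "KOSet") || !"gc_content" %in% colnames(colData(x)))
      stop("supply 'gc' or a KOSet with a gc_content metadata column",
           call. = FALSE)
    gc <- colData(x)$gc_content
  }
  if (length(gc) != nrow(X))
    stop("'gc' must have one value per sample", call. = FALSE)
  keep <- !is.na(gc)
  X <- X[keep, , drop = FALSE]
  gc <- as.numeric(gc[keep])
  n <- length(gc)
  if (n < 3L) stop("need at least 3 samples with GC content", call. = FALSE)
  sxx <- sum((gc - mean(gc))^2)
  if (sxx <= 0) stop("GC content is constant; regression undefined",
                     call. = FALSE)
  xc <- gc - mean(gc)
  ybar <- colMeans(X)
  sxy <- as.vector(crossprod(xc, X))                # sum(xc * (y - ybar))
  syy <- colSums(X^2) - n * ybar^2
  syy <- pmax(syy, 0)
  slope <- sxy / sxx
  intercept <- ybar - slope * mean(gc)
  r <- ifelse(syy > 0, sxy / sqrt(sxx * syy), 0)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), df = n - 2)
  const <- syy <= .Machine$double.eps * n
  slope[const] <- 0; r[const] <- 0; tstat[const] <- 0; p[const] <- 1
  out <- DataFrame(ko = colnames(X), slope = unname(slope),
                   intercept = unname(intercept), pearson_r = unname(r),
                   t = unname(tstat), wald_p = unname(p),
                   p_bonferroni = unname(p.adjust(p, method = "bonferroni")),
                   n = n)
  metadata(out) <- list(n = n, gc_mean = mean(gc), gc_sd = sd(gc))
  out
}

#' Rank KOs by their correlation with GC content
#'
#' @param results regression table from [gcKORegression()].
#' @param nTop entries per list (default 20; capped at the KO count).
#' @return list with `positive` (sorted by Pearson r descending) and
#'   `negative` (ascending) data.frames; ties broken by KO identifier.
#' @export
rankGCCorrelates <- function(results, nTop = 20) {
  nTop <- min(.assertCount(nTop, "nTop", min = 1L), nrow(results))
  df <- data.frame(ko = results$ko, slope = results$slope,
                   pearson_r = results$pearson_r, wald_p = results$wald_p,
                   stringsAsFactors = FALSE)
  pos <- df[order(-df$pearson_r, df$ko), , drop = FALSE][seq_len(nTop), ]
  neg <- df[order(df$pearson_r, df$ko), , drop = FALSE][seq_len(nTop), ]
  rownames(pos) <- rownames(neg) <- NULL
  list(positive = pos, negative = neg)
}
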