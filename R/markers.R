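# Cluster-specific marker-KO discovery: Kruskal-Wallis across clusters,
# Dunn's joint-rank post-hoc z tests with Bonferroni correction over the
# g(g-1)/2 cluster pairs of each KO, a median log2 fold-change criterion on
# CLR values, and a label-permutation estimate of the false discovery rate of
# the combined criterion. Rank statistics are computed in vectorized form
# across all KOs at once; ranks and tie corrections are label-free and are
# reused across label permutations.

#' @noRd
.colRanks <- function(X) apply(X, 2L, rank)          # mid-ranks for ties

# Per-column tie term sum(t^3 - t) over tie groups.
#' @noRd
.colTieTerms <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    t <- rle(sort(X[, j]))$lengths
    sum(t^3 - t)
  }, numeric(1))
}

# Vectorized Kruskal-Wallis over columns. R: n x p mid-rank matrix, f: group
# factor, tieT: per-column tie terms. Tie-corrected H; all-tied columns give
# H = 0, p = 1.
#' @noRd
.kwFromRanks <- function(R, f, tieT) {
  N <- nrow(R)
  sizes <- as.numeric(table(f))
  g <- length(sizes)
  rankSums <- rowsum(R, f, reorder = TRUE)
  H0 <- 12 / (N * (N + 1)) * colSums(rankSums^2 / sizes) - 3 * (N + 1)
  C <- 1 - tieT / (N^3 - N)
  H <- ifelse(C > 0, H0 / C, 0)
  H <- pmax(H, 0)
  p <- ifelse(C > 0, pchisq(H, df = g - 1, lower.tail = FALSE), 1)
  list(H = H, p = p)
}

# Vectorized Dunn post-hoc z over columns for every cluster pair, on joint
# mid-ranks, with the tie-corrected variance N(N+1)/12 - sum(t^3-t)/(12(N-1)).
# Returns z (pairs x p), Bonferroni p (pairs x p, multiplier g(g-1)/2 capped
# at 1) and the pair index matrix.
#' @noRd
.dunnFromRanks <- function(R, f, tieT) {
  N <- nrow(R)
  sizes <- as.numeric(table(f))
  g <- length(sizes)
  meanRanks <- rowsum(R, f, reorder = TRUE) / sizes
  sig2 <- N * (N + 1) / 12 - tieT / (12 * (N - 1))
  pairs <- utils::combn(g, 2L)
  nPairs <- ncol(pairs)
  z <- matrix(0, nPairs, ncol(R))
  for (q in seq_len(nPairs)) {
    a <- pairs[1L, q]; b <- pairs[2L, q]
    denom <- sqrt(sig2 * (1 / sizes[a] + 1 / sizes[b]))
    zq <- (meanRanks[a, ] - meanRanks[b, ]) / denom
    zq[!is.finite(zq)] <- 0                        # all values tied
    z[q, ] <- zq
  }
  pRaw <- 2 * pnorm(-abs(z))
  pRaw[, sig2 <= 0] <- 1
  list(z = z, p = pmin(pRaw * nPairs, 1), pairs = pairs,
       levels = levels(f))
}

#' Kruskal-Wallis H test
#'
#' Rank-based k-group test of identical distributions with mid-ranks for ties
#' and the standard tie correction; p-value from the chi-square distribution
#' with `g - 1` degrees of freedom. When every value is identical across all
#' groups, `H = 0` and `p = 1`.
#'
#' @param groups list of >= 2 non-empty numeric vectors (total N >= 3).
#' @return named vector `c(H, p)`.
#' @export
kruskalWallis <- function(groups) {
  .checkGroups(groups)
  v <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  X <- matrix(v, ncol = 1L)
  res <- .kwFromRanks(.colRanks(X), f, .colTieTerms(X))
  c(H = res$H[1L], p = res$p[1L])
}

#' @noRd
.checkGroups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("need a list of at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0L))
    stop("every group must be non-empty", call. = FALSE)
  if (sum(lengths(groups)) < 3L)
    stop("need at least 3 observations in total", call. = FALSE)
  invisible(TRUE)
}

#' Dunn's post-hoc pairwise comparisons
#'
#' Joint mid-rank z statistics for every group pair following a
#' Kruskal-Wallis test, with tie-corrected variance and two-sided normal
#' p-values Bonferroni-corrected by the number of pairs `g(g-1)/2` (capped at
#' 1). When all values are tied the z statistics are 0 and p-values 1.
#'
#' @inheritParams kruskalWallis
#' @return data.frame with one row per pair: `group_a`, `group_b`, `z`, `p`
#'   (raw two-sided) and `p_bonferroni`.
#' @export
dunnPosthoc <- function(groups) {
  .checkGroups(groups)
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_along(groups))
  v <- unlist(groups, use.names = FALSE)
  f <- factor(rep(seq_along(groups), lengths(groups)))
  X <- matrix(v, ncol = 1L)
  res <- .dunnFromRanks(.colRanks(X), f, .colTieTerms(X))
  pRaw <- 2 * pnorm(-abs(res$z[, 1L]))   # z = 0 for all-tied data, so pRaw = 1 there
  data.frame(group_a = nm[res$pairs[1L, ]], group_b = nm[res$pairs[2L, ]],
             z = res$z[, 1L], p = pRaw,
             p_bonferroni = res$p[, 1L],
             stringsAsFactors = FALSE)
}

# Group medians of every column: g x p matrix in level order.
#' @noRd
.groupMedians <- function(X, f) {
  t(vapply(levels(f), function(l) {
    sub <- X[f == l, , drop = FALSE]
    apply(sub, 2L, median)
  }, numeric(ncol(X))))
}

# Median log2 fold-change matrix between two clusters for all KOs.
#' @noRd
.pairLfc <- function(X, f, a, b, method) {
  if (method == "difference_of_medians") {
    ma <- apply(X[f == a, , drop = FALSE], 2L, median)
    mb <- apply(X[f == b, , drop = FALSE], 2L, median)
    ma - mb
  } else {
    xa <- X[f == a, , drop = FALSE]
    xb <- X[f == b, , drop = FALSE]
    vapply(seq_len(ncol(X)), function(j) median(outer(xa[, j], xb[, j], "-")),
           numeric(1))
  }
}

#' Median log2 fold-change of one KO between two clusters
#'
#' On CLR-normalized values (already log2 scale) the default
#' `"difference_of_medians"` is the difference between the two cluster
#' medians; `"median_of_differences"` is the median over all cross-cluster
#' sample pairs of the per-pair difference.
#'
#' @param x `KOSet` with a `clr` assay or samples-by-KOs matrix.
#' @param labels cluster assignment per sample.
#' @param ko KO identifier (column name) or index.
#' @param clusterA,clusterB cluster labels to compare (A minus B).
#' @param method fold-change flavour, see above.
#' @return median log2 fold-change (positive when higher in `clusterA`).
#' @export
medianLFC <- function(x, labels, ko, clusterA, clusterB,
                      method = c("difference_of_medians", "median_of_differences")) {
  method <- match.arg(method)
  X <- .sampleMatrix(x)
  f <- factor(labels)
  for (cl in c(clusterA, clusterB))
    if (!as.character(cl) %in% levels(f))
      stop(sprintf("unknown cluster '%s'", cl), call. = FALSE)
  j <- if (is.character(ko)) match(ko, colnames(X)) else as.integer(ko)
  if (is.na(j) || j < 1L || j > ncol(X))
    stop(sprintf("unknown KO '%s'", ko), call. = FALSE)
  unname(.pairLfc(X[, j, drop = FALSE], f, as.character(clusterA),
                  as.character(clusterB), method)[1L])
}

# Core marker criterion: for each KO, marker_of cluster c iff every Dunn pair
# involving c has Bonferroni p < alpha AND the median log2 fold-change of c
# over every other cluster exceeds minLfc. Returns per-KO tables; ranks and
# tie terms may be supplied for reuse across permutations.
#' @noRd
.markerCore <- function(X, f, alpha, minLfc, lfcMethod, R = NULL, tieT = NULL) {
  if (is.null(R)) R <- .colRanks(X)
  if (is.null(tieT)) tieT <- .colTieTerms(X)
  kw <- .kwFromRanks(R, f, tieT)
  dn <- .dunnFromRanks(R, f, tieT)
  g <- nlevels(f)
  lev <- levels(f)
  p <- ncol(X)
  med <- .groupMedians(X, f)
  sigAll <- matrix(TRUE, g, p)        # all pairs involving c significant
  for (q in seq_len(ncol(dn$pairs))) {
    ok <- dn$p[q, ] < alpha
    sigAll[dn$pairs[1L, q], ] <- sigAll[dn$pairs[1L, q], ] & ok
    sigAll[dn$pairs[2L, q], ] <- sigAll[dn$pairs[2L, q], ] & ok
  }
  lfcMin <- matrix(Inf, g, p)
  if (lfcMethod == "difference_of_medians") {
    for (c in seq_len(g)) {
      others <- setdiff(seq_len(g), c)
      diffs <- sweep(-med[others, , drop = FALSE], 2L, med[c, ], "+")
      lfcMin[c, ] <- do.call(pmin, as.data.frame(t(diffs)))
    }
  } else {
    for (c in seq_len(g)) {
      for (o in setdiff(seq_len(g), c)) {
        lfcMin[c, ] <- pmin(lfcMin[c, ],
                            .pairLfc(X, f, lev[c], lev[o], lfcMethod))
      }
    }
  }
  isMarker <- sigAll & (lfcMin > minLfc)
  markerOf <- rep(NA_character_, p)
  hit <- which(colSums(isMarker) > 0L)
  markerOf[hit] <- lev[apply(isMarker[, hit, drop = FALSE], 2L, which.max)]
  list(H = kw$H, pKW = kw$p, dunn = dn, lfcMin = lfcMin, markerOf = markerOf,
       levels = lev)
}

#' Call cluster-specific marker KOs
#'
#' A KO is a marker of cluster `c` iff every Dunn pairwise comparison
#' involving `c` has a Bonferroni-corrected p-value below `alpha` *and* its
#' median log2 fold-change over each other cluster exceeds `minLfc`. The
#' Bonferroni correction is per KO across its `g(g-1)/2` Dunn pairs; KO-level
#' multiplicity is guarded by [permutationFDR()]. Kruskal-Wallis H and p are
#' reported per KO but do not enter the marker rule. A KO can be a marker of
#' at most one cluster (the fold-change requirement is mutually exclusive).
#'
#' @param x `KOSet` with a `clr` assay or samples-by-KOs matrix.
#' @param labels cluster assignment per sample (at least 2 clusters, each
#'   with at least 2 samples).
#' @param alpha Bonferroni-corrected p threshold (default 0.001).
#' @param minLfc median log2 fold-change threshold (default 2).
#' @param lfcMethod fold-change flavour, see [medianLFC()].
#' @return An `S4Vectors::DataFrame` with one row per KO: `ko`, `H`, `p_kw`,
#'   per-pair `z_a_b` and Bonferroni `p_a_b`, per-cluster `lfc_min_c` (the
#'   minimum median log2 fold-change of cluster c over the others) and
#'   `marker_of` (cluster label or `NA`). The criterion is stored in
#'   `metadata()`.
#' @export
callMarkers <- function(x, labels, alpha = 0.001, minLfc = 2,
                        lfcMethod = c("difference_of_medians",
                                      "median_of_differences")) {
  lfcMethod <- match.arg(lfcMethod)
  .assertScalarNumber(alpha, "alpha", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  if (!is.numeric(minLfc) || length(minLfc) != 1L || is.na(minLfc) || minLfc < 0)
    stop("'minLfc' must be a single number >= 0 (Inf allowed)", call. = FALSE)
  X <- .sampleMatrix(x)
  f <- .checkClusterLabels(X, labels)
  core <- .markerCore(X, f, alpha, minLfc, lfcMethod)
  out <- DataFrame(ko = colnames(X), H = core$H, p_kw = core$pKW)
  lev <- core$levels
  for (q in seq_len(ncol(core$dunn$pairs))) {
    a <- lev[core$dunn$pairs[1L, q]]; b <- lev[core$dunn$pairs[2L, q]]
    out[[paste0("z_", a, "_", b)]] <- core$dunn$z[q, ]
    out[[paste0("p_", a, "_", b)]] <- core$dunn$p[q, ]
  }
  for (c in seq_along(lev))
    out[[paste0("lfc_min_", lev[c])]] <- core$lfcMin[c, ]
  out$marker_of <- core$markerOf
  metadata(out) <- list(alpha = alpha, min_lfc = minLfc,
                        lfc_method = lfcMethod, clusters = lev)
  out
}

#' @noRd
.checkClusterLabels <- function(X, labels) {
  if (length(labels) != nrow(X))
    stop("'labels' must have one entry per sample", call. = FALSE)
  f <- droplevels(factor(labels))
  if (nlevels(f) < 2L)
    stop("need at least two clusters", call. = FALSE)
  sizes <- table(f)
  if (any(sizes < 2L))
    stop(sprintf("cluster '%s' has fewer than 2 samples",
                 names(sizes)[which(sizes < 2L)[1L]]), call. = FALSE)
  f
}

#' Permutation estimate of the marker false discovery rate
#'
#' Shuffles the cluster labels `nPerm` times (preserving cluster sizes),
#' re-runs the full marker criterion on each shuffle, and estimates
#' `FDR = mean(false positives) / max(observed markers, 1)`. Ranks and tie
#' corrections are label-free and computed once.
#'
#' @inheritParams callMarkers
#' @param nPerm number of label permutations (default 100).
#' @param seed permutation seed.
#' @return A [PermutationFDR-class].
#' @export
permutationFDR <- function(x, labels, alpha = 0.001, minLfc = 2, nPerm = 100,
                           seed = 1,
                           lfcMethod = c("difference_of_medians",
                                         "median_of_differences")) {
  lfcMethod <- match.arg(lfcMethod)
  nPerm <- .assertCount(nPerm, "nPerm", min = 1L)
  X <- .sampleMatrix(x)
  f <- .checkClusterLabels(X, labels)
  R <- .colRanks(X)
  tieT <- .colTieTerms(X)
  observed <- sum(!is.na(.markerCore(X, f, alpha, minLfc, lfcMethod,
                                     R = R, tieT = tieT)$markerOf))
  counts <- integer(nPerm)
  with_seed(as.integer(seed), {
    for (i in seq_len(nPerm)) {
      fp <- f[sample.int(length(f))]
      counts[i] <- sum(!is.na(.markerCore(X, fp, alpha, minLfc, lfcMethod,
                                          R = R, tieT = tieT)$markerOf))
    }
  })
  new("PermutationFDR", observedMarkers = as.integer(observed),
      permCounts = counts,
      fdrEstimate = mean(counts) / max(observed, 1L),
      noObservedMarkers = observed == 0L, seed = as.integer(seed))
}

#' Roll marker KOs up to KEGG pathways and categories
#'
#' Counts each cluster's marker KOs per pathway and per category. A KO
#' mapping to several pathways counts once per pathway (and once per distinct
#' category); markers absent from the map are tallied as unmapped.
#'
#' @param markers marker table from [callMarkers()].
#' @param pathwayMap data.frame from [readPathwayMap()].
#' @return list with `pathways` (cluster, pathway_id, pathway_name, n_markers),
#'   `categories` (cluster, category, n_markers) and `unmapped`
#'   (cluster, n_unmapped).
#' @export
mapMarkersToPathways <- function(markers, pathwayMap) {
  mk <- data.frame(ko = markers$ko, cluster = markers$marker_of,
                   stringsAsFactors = FALSE)
  mk <- mk[!is.na(mk$cluster), , drop = FALSE]
  hits <- merge(mk, pathwayMap, by.x = "ko", by.y = "ko_id")
  pw <- unique(hits[c("cluster", "pathway_id", "pathway_name", "ko")])
  pw$pathway_name[is.na(pw$pathway_name)] <- ""   # link-dialect maps carry no names
  pathways <- stats::aggregate(ko ~ cluster + pathway_id + pathway_name,
                               data = pw, FUN = length)
  names(pathways)[names(pathways) == "ko"] <- "n_markers"
  ct <- unique(hits[!is.na(hits$category), c("cluster", "category", "ko")])
  categories <- if (nrow(ct))
    stats::aggregate(ko ~ cluster + category, data = ct, FUN = length)
  else data.frame(cluster = character(), category = character(),
                  ko = integer())
  names(categories)[names(categories) == "ko"] <- "n_markers"
  unm <- vapply(unique(mk$cluster), function(cl) {
    sum(!mk$ko[mk$cluster == cl] %in% pathwayMap$ko_id)
  }, integer(1))
  unmapped <- data.frame(cluster = unique(mk$cluster), n_unmapped = unm,
                         stringsAsFactors = FALSE)
  ord <- function(d) d[order(d$cluster, -d$n_markers), , drop = FALSE]
  list(pathways = ord(pathways), categories = ord(categories),
       unmapped = unmapped[order(unmapped$cluster), , drop = FALSE])
}

#' Top marker KOs per cluster
#'
#' Ranks each cluster's markers by their minimum median log2 fold-change over
#' the other clusters (descending), with ties broken by Kruskal-Wallis H and
#' then KO identifier, and returns the top `n`.
#'
#' @param markers marker table from [callMarkers()].
#' @param n markers to keep per cluster (default 15).
#' @return data.frame `cluster, rank, ko, lfc_min, H`.
#' @export
topMarkers <- function(markers, n = 15) {
  n <- .assertCount(n, "n", min = 1L)
  clusters <- metadata(markers)$clusters
  out <- lapply(clusters, function(cl) {
    sel <- which(!is.na(markers$marker_of) & markers$marker_of == cl)
    if (!length(sel)) return(NULL)
    lfc <- markers[[paste0("lfc_min_", cl)]][sel]
    ord <- order(-lfc, -markers$H[sel], markers$ko[sel])
    keep <- sel[ord][seq_len(min(n, length(sel)))]
    data.frame(cluster = cl, rank = seq_along(keep), ko = markers$ko[keep],
               lfc_min = markers[[paste0("lfc_min_", cl)]][keep],
               H = markers$H[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
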