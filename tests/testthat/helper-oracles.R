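# Brute-force reference implementations, written naively and independently of
# the package's vectorized code paths.

# Mid-ranks by direct counting.
oracleRank <- function(v) {
  vapply(seq_along(v), function(i) sum(v < v[i]) + (sum(v == v[i]) + 1) / 2,
         numeric(1))
}

oracleKW <- function(groups) {
  v <- unlist(groups)
  f <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- oracleRank(v)
  H0 <- 12 / (N * (N + 1)) *
    sum(vapply(seq_along(groups), function(g) sum(r[f == g])^2 / sum(f == g),
               numeric(1))) - 3 * (N + 1)
  tieSizes <- as.numeric(table(v))
  C <- 1 - sum(tieSizes^3 - tieSizes) / (N^3 - N)
  if (C <= 0) return(c(H = 0, p = 1))
  H <- H0 / C
  c(H = H, p = pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

oracleDunn <- function(groups) {
  v <- unlist(groups)
  f <- rep(seq_along(groups), lengths(groups))
  N <- length(v)
  r <- oracleRank(v)
  tieSizes <- as.numeric(table(v))
  sig2 <- N * (N + 1) / 12 - sum(tieSizes^3 - tieSizes) / (12 * (N - 1))
  g <- length(groups)
  nPairs <- g * (g - 1) / 2
  out <- NULL
  for (a in 1:(g - 1)) for (b in (a + 1):g) {
    za <- (mean(r[f == a]) - mean(r[f == b])) /
      sqrt(sig2 * (1 / sum(f == a) + 1 / sum(f == b)))
    if (!is.finite(za)) za <- 0
    p <- if (sig2 <= 0) 1 else min(2 * pnorm(-abs(za)) * nPairs, 1)
    out <- rbind(out, data.frame(a = a, b = b, z = za, p_bonferroni = p))
  }
  out
}

oracleSilhouette <- function(X, labels) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(vapply(setdiff(own, i), d, numeric(1), i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      others <- which(labels == cl)
      b <- min(b, mean(vapply(others, d, numeric(1), i = i)))
    }
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Pair-counting ARI.
oracleARI <- function(a, b) {
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) n11 <- n11 + 1
    else if (sa && !sb) n10 <- n10 + 1
    else if (!sa && sb) n01 <- n01 + 1
    else n00 <- n00 + 1
  }
  num <- 2 * (n11 * n00 - n10 * n01)
  den <- (n11 + n10) * (n10 + n00) + (n11 + n01) * (n01 + n00)
  if (den == 0) return(1)
  num / den
}

# Greedy Ward agglomeration tracked as member sets; merge cost is the
# increase in total within-cluster sum of squares.
oracleWardMerges <- function(X) {
  clusters <- lapply(seq_len(nrow(X)), identity)
  merges <- list(); heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- NULL; bestCost <- Inf
    for (i in 1:(length(clusters) - 1)) for (j in (i + 1):length(clusters)) {
      ci <- clusters[[i]]; cj <- clusters[[j]]
      mi <- colMeans(X[ci, , drop = FALSE]); mj <- colMeans(X[cj, , drop = FALSE])
      cost <- length(ci) * length(cj) / (length(ci) + length(cj)) *
        sum((mi - mj)^2)
      if (cost < bestCost) { bestCost <- cost; best <- c(i, j) }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    heights <- c(heights, 2 * bestCost)
    clusters <- c(clusters[-best], list(merged))
  }
  list(merges = merges, heights = heights)
}

# Member sets per merge step from an hclust-style merge matrix.
mergeSetsFromMatrix <- function(merge) {
  sets <- list()
  for (s in seq_len(nrow(merge))) {
    members <- function(id) if (id < 0) -id else sets[[id]]
    sets[[s]] <- sort(c(members(merge[s, 1]), members(merge[s, 2])))
  }
  sets
}

# All set partitions of 1..n (restricted growth strings).
allPartitions <- function(n) {
  out <- list()
  rec <- function(prefix, maxUsed) {
    if (length(prefix) == n) { out[[length(out) + 1L]] <<- prefix; return() }
    for (v in 1:(maxUsed + 1)) rec(c(prefix, v), max(maxUsed, v))
  }
  rec(integer(0), 0L)
  out
}
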