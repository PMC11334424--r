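# Internal helpers shared across modules.

#' @noRd
.assertScalarNumber <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  ok_lo <- if (strict_lower) x > lower else x >= lower
  ok_hi <- if (strict_upper) x < upper else x <= upper
  if (!ok_lo || !ok_hi)
    stop(sprintf("'%s' = %s is outside its allowed range %s%s, %s%s",
                 name, format(x),
                 if (strict_lower) "(" else "[", format(lower),
                 format(upper), if (strict_upper) ")" else "]"),
         call. = FALSE)
  invisible(x)
}

#' @noRd
.assertCount <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x) || x < min)
    stop(sprintf("'%s' must be a single integer >= %d", name, min), call. = FALSE)
  as.integer(x)
}

# Derive a stage seed from a master seed and a stage name. Stable across
# platforms, stays below 2^31 so it is a legal R seed.
#' @noRd
.deriveSeed <- function(master, stage) {
  h <- as.double(master %% 2147483647L)
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 2147483647
  as.integer(h)
}

# Squared Euclidean distances between rows of X and rows of C.
#' @noRd
.rowDist2 <- function(X, C) {
  d2 <- matrix(rowSums(X^2), nrow(X), nrow(C)) +
    matrix(rowSums(C^2), nrow(X), nrow(C), byrow = TRUE) -
    2 * tcrossprod(X, C)
  d2[d2 < 0] <- 0
  d2
}

# Full pairwise Euclidean distance matrix for rows of X.
#' @noRd
.pairwiseDist <- function(X) {
  g <- tcrossprod(X)
  sq <- diag(g)
  d2 <- outer(sq, sq, "+") - 2 * g
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Extract the samples-by-features matrix cluster/statistics functions work on:
# a plain matrix is taken as samples-in-rows; a KOSet contributes its clr
# assay transposed (samples in rows).
#' @noRd
.sampleMatrix <- function(x, assayName = "clr") {
  if (is(x, "KOSet")) {
    if (!assayName %in% assayNames(x))
      stop(sprintf("KOSet has no '%s' assay; run clrNormalize() first", assayName),
           call. = FALSE)
    t(assay(x, assayName))
  } else if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("S", seq_len(nrow(x)))
    x
  } else {
    stop("'x' must be a KOSet or a numeric samples-by-features matrix",
         call. = FALSE)
  }
}

# md5 of an in-memory character scalar (via a temp file; tools::md5sum is
# file-based).
#' @noRd
.md5String <- function(s) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(s, f)
  unname(md5sum(f))
}

#' @noRd
.delimFor <- function(path) if (tolower(file_ext(path)) == "csv") "," else "\t"
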