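# Readers and writers for every table the pipeline touches. All files are
# UTF-8 delimited text (TSV canonical, CSV by ".csv" extension), "." decimal,
# missing = empty cell or NA. The canonical on-disk count layout is
# samples-as-rows; `orientation` accommodates feature-major exports such as
# the JGI functional-profile convention (KOs as rows).

#' Read a sample-by-KO count matrix
#'
#' @param path TSV/CSV file with one header row of identifiers and one id
#'   column (first column).
#' @param orientation `"samples_as_rows"` (canonical) if file rows are
#'   samples, `"samples_as_cols"` if file rows are KOs.
#' @return A [KOSet-class] with a `counts` assay (no sample metadata).
#' @details Duplicate identifiers raise a schema error naming the duplicate;
#'   negative or non-numeric cells raise a parse error with their row and
#'   column identifiers.
#' @export
readCountMatrix <- function(path, orientation = c("samples_as_rows", "samples_as_cols")) {
  orientation <- match.arg(orientation)
  raw <- read.delim(path, sep = .delimFor(path), header = TRUE,
                    row.names = NULL, check.names = FALSE,
                    colClasses = "character", na.strings = c("NA", ""))
  if (ncol(raw) < 2L) stop("count matrix needs an id column plus >= 1 value column",
                           call. = FALSE)
  rowIds <- as.character(raw[[1L]])
  colIds <- colnames(raw)[-1L]
  if (anyDuplicated(rowIds))
    stop(sprintf("duplicate row identifier: '%s'", rowIds[duplicated(rowIds)][1L]),
         call. = FALSE)
  if (anyDuplicated(colIds))
    stop(sprintf("duplicate column identifier: '%s'", colIds[duplicated(colIds)][1L]),
         call. = FALSE)
  vals <- suppressWarnings(
    vapply(raw[-1L], function(col) as.numeric(col), numeric(nrow(raw))))
  vals <- matrix(vals, nrow = length(rowIds),
                 dimnames = list(rowIds, colIds))
  bad <- which(is.na(vals) | !is.finite(vals) | vals < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("invalid count at row '%s', column '%s' (negative, missing or non-numeric)",
                 rowIds[bad[1L, 1L]], colIds[bad[1L, 2L]]), call. = FALSE)
  }
  counts <- if (orientation == "samples_as_rows") t(vals) else vals
  KOSet(counts)
}

#' Write a count matrix
#'
#' @param x `KOSet` or KO-by-sample numeric matrix.
#' @param path output file (TSV unless the extension is `.csv`).
#' @param orientation layout to write; samples-as-rows is canonical.
#' @param idColumn header of the identifier column.
#' @return `path`, invisibly.
#' @export
writeCountMatrix <- function(x, path,
                             orientation = c("samples_as_rows", "samples_as_cols"),
                             idColumn = "sample_id") {
  orientation <- match.arg(orientation)
  m <- if (is(x, "KOSet")) koCounts(x) else x
  out <- if (orientation == "samples_as_rows") t(m) else m
  df <- data.frame(id = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1L] <- if (orientation == "samples_as_rows") idColumn else "ko_id"
  write.table(df, path, sep = .delimFor(path), quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Typed sample-metadata columns: name -> list(coerce, check).
.SAMPLE_FIELDS <- list(
  ecosystem_type      = list(as.character, NULL),
  ecosystem           = list(as.character, NULL),
  ecosystem_label     = list(as.character, NULL),
  gc_content          = list(as.numeric, function(v) v >= 0 & v <= 1),
  gene_count          = list(as.numeric, function(v) v >= 0 & v == round(v)),
  pct_ko_annotated    = list(as.numeric, function(v) v >= 0 & v <= 100),
  has_copy_data       = list(NULL, NULL),
  is_combined_assembly = list(NULL, NULL),
  use_restricted      = list(NULL, NULL)
)

#' @noRd
.asLogicalField <- function(v) {
  if (is.logical(v)) return(v)
  s <- toupper(trimws(as.character(v)))
  out <- rep(NA, length(s))
  out[s %in% c("TRUE", "T", "YES", "1")] <- TRUE
  out[s %in% c("FALSE", "F", "NO", "0")] <- FALSE
  out
}

#' Read a per-sample metadata table
#'
#' Requires a `sample_id` column; recognised columns (`ecosystem_type`,
#' `ecosystem`, `gc_content`, `gene_count`, `pct_ko_annotated`,
#' `has_copy_data`, `is_combined_assembly`, `use_restricted`) are typed and
#' range-checked (`gc_content` in \[0,1\], `pct_ko_annotated` in \[0,100\]);
#' unknown columns are preserved untouched. Missing optional values stay
#' missing (`NA`), never defaulted.
#'
#' @param path TSV/CSV file.
#' @return An `S4Vectors::DataFrame` keyed by `sample_id` (also row names).
#' @export
readSampleTable <- function(path) {
  tab <- read.delim(path, sep = .delimFor(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE,
                    na.strings = c("NA", ""))
  if (!"sample_id" %in% names(tab))
    stop("sample table must have a 'sample_id' column", call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop(sprintf("duplicate sample_id: '%s'",
                 tab$sample_id[duplicated(tab$sample_id)][1L]), call. = FALSE)
  for (fld in names(.SAMPLE_FIELDS)) {
    if (!fld %in% names(tab)) next
    spec <- .SAMPLE_FIELDS[[fld]]
    v <- tab[[fld]]
    v <- if (is.null(spec[[1L]])) .asLogicalField(v) else spec[[1L]](v)
    chk <- spec[[2L]]
    if (!is.null(chk)) {
      bad <- which(!is.na(v) & !chk(v))
      if (length(bad))
        stop(sprintf("'%s' value %s for sample '%s' is out of range",
                     fld, format(v[bad[1L]]), tab$sample_id[bad[1L]]),
             call. = FALSE)
    }
    tab[[fld]] <- v
  }
  out <- DataFrame(tab)
  rownames(out) <- tab$sample_id
  out
}

#' Write a sample metadata table
#' @param table `DataFrame`/`data.frame` with a `sample_id` column.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeSampleTable <- function(table, path) {
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  write.table(df, path, sep = .delimFor(path), quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a KO-to-pathway map
#'
#' Two dialects are accepted: the canonical four-column layout
#' `ko_id, pathway_id, pathway_name, category` (with header), and KEGG's
#' two-column link file (`ko:K00001<TAB>path:ko00010`, no header), for which
#' name and category are recorded as missing. Duplicate
#' `(ko_id, pathway_id)` pairs are dropped; malformed rows are skipped with a
#' warning and counted in the `n_skipped` attribute.
#'
#' @param path TSV/CSV file.
#' @return data.frame `ko_id, pathway_id, pathway_name, category`.
#' @export
readPathwayMap <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(ko_id = character(), pathway_id = character(),
                      pathway_name = character(), category = character(),
                      stringsAsFactors = FALSE)
  if (!length(lines)) {
    warning("pathway map file is empty")
    attr(empty, "n_skipped") <- 0L
    return(empty)
  }
  sep <- .delimFor(path)
  cells <- strsplit(lines, sep, fixed = TRUE)
  isLink <- grepl("^ko:", vapply(cells, `[`, "", 1L))
  nSkipped <- 0L
  if (any(isLink)) {
    keep <- lengths(cells) >= 2L & isLink &
      grepl("^path:", vapply(cells, function(x) if (length(x) >= 2L) x[2L] else "", ""))
    nSkipped <- sum(!keep)
    cells <- cells[keep]
    map <- data.frame(
      ko_id = sub("^ko:", "", vapply(cells, `[`, "", 1L)),
      pathway_id = sub("^path:", "", vapply(cells, `[`, "", 2L)),
      pathway_name = NA_character_, category = NA_character_,
      stringsAsFactors = FALSE)
  } else {
    if (grepl("^ko_id", lines[1L])) { cells <- cells[-1L] }
    ok <- lengths(cells) >= 2L &
      nzchar(vapply(cells, `[`, "", 1L)) &
      nzchar(vapply(cells, function(x) if (length(x) >= 2L) x[2L] else "", ""))
    nSkipped <- sum(!ok)
    cells <- cells[ok]
    pick <- function(i) vapply(cells, function(x) {
      v <- if (length(x) >= i) x[i] else ""
      if (nzchar(v)) v else NA_character_
    }, "")
    map <- data.frame(ko_id = pick(1L), pathway_id = pick(2L),
                      pathway_name = pick(3L), category = pick(4L),
                      stringsAsFactors = FALSE)
  }
  if (nSkipped > 0L)
    warning(sprintf("skipped %d malformed pathway-map row(s)", nSkipped))
  map <- map[!duplicated(map[c("ko_id", "pathway_id")]), , drop = FALSE]
  rownames(map) <- NULL
  attr(map, "n_skipped") <- nSkipped
  map
}

#' Write a KO-to-pathway map in the canonical four-column layout
#' @param map data.frame as returned by [readPathwayMap()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePathwayMap <- function(map, path) {
  write.table(map[c("ko_id", "pathway_id", "pathway_name", "category")],
              path, sep = .delimFor(path), quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}

.TAX_DOMAINS <- c("bacteria", "archaea", "eukaryota", "viruses", "unassigned")

#' Read a contig-taxonomy count table
#'
#' Expects a `sample_id` column plus per-domain contig counts for the five
#' fixed domains `bacteria, archaea, eukaryota, viruses, unassigned`. Missing
#' domain columns are zero-filled with a warning (taxonomy exports often cover
#' only part of a compendium); negative counts or duplicated samples raise a
#' schema error.
#'
#' @param path TSV/CSV file.
#' @return data.frame `sample_id` + five domain count columns.
#' @export
readTaxonomyTable <- function(path) {
  tab <- read.delim(path, sep = .delimFor(path), header = TRUE,
                    check.names = FALSE, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(tab))
    stop("taxonomy table must have a 'sample_id' column", call. = FALSE)
  tab$sample_id <- as.character(tab$sample_id)
  if (anyDuplicated(tab$sample_id))
    stop(sprintf("duplicate sample_id: '%s'",
                 tab$sample_id[duplicated(tab$sample_id)][1L]), call. = FALSE)
  out <- data.frame(sample_id = tab$sample_id, stringsAsFactors = FALSE)
  for (d in .TAX_DOMAINS) {
    if (d %in% names(tab)) {
      v <- as.numeric(tab[[d]])
      if (anyNA(v) || any(v < 0))
        stop(sprintf("negative or non-numeric '%s' count (sample '%s')",
                     d, tab$sample_id[which(is.na(v) | v < 0)[1L]]),
             call. = FALSE)
      out[[d]] <- v
    } else {
      warning(sprintf("taxonomy table lacks a '%s' column; filled with 0", d))
      out[[d]] <- 0
    }
  }
  out
}

#' Write a contig-taxonomy count table
#' @param tax data.frame as returned by [readTaxonomyTable()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTaxonomyTable <- function(tax, path) {
  write.table(tax[c("sample_id", .TAX_DOMAINS)], path, sep = .delimFor(path),
              quote = FALSE, row.names = FALSE)
  invisible(path)
}
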