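#' OTU count table
#'
#' Lightweight container for a samples x OTUs table of non-negative integer
#' read counts, the universal currency of the pipeline.  Rows are samples,
#' columns are OTUs; both must carry unique identifiers.  An optional
#' taxonomy vector (OTU id -> lineage string) tags along.
#'
#' @param counts integer matrix, samples in rows, OTUs in columns, with
#'   unique row and column names.
#' @param taxonomy optional named character vector of lineage strings; names
#'   must be a superset of the OTU ids.
#' @return An object of class `otu_table`.
#' @examples
#' m <- matrix(c(5L, 3L, 0L, 2L), 2, 2,
#'             dimnames = list(c("S1", "S2"), c("OTU1", "OTU2")))
#' otu_table(m)
#' @export
otu_table <- function(counts, taxonomy = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("'counts' must have sample (row) and OTU (column) names")
  if (anyDuplicated(rownames(counts)))
    stop("duplicate sample ids: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]),
               collapse = ", "))
  if (anyDuplicated(colnames(counts)))
    stop("duplicate OTU ids: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  if (!is.numeric(counts))
    stop("'counts' must be numeric")
  bad <- which(!is.finite(counts) | counts < 0 |
                 abs(counts - round(counts)) > 1e-8)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(counts))
    stop(sprintf(
      "counts must be non-negative integers; offending cell sample '%s', OTU '%s' (value %s)",
      rownames(counts)[i[1L]], colnames(counts)[i[2L]], counts[bad[1L]]))
  }
  storage.mode(counts) <- "integer"
  if (!is.null(taxonomy)) {
    if (is.null(names(taxonomy)))
      stop("'taxonomy' must be a named character vector")
    missing_tax <- setdiff(colnames(counts), names(taxonomy))
    if (length(missing_tax))
      stop("taxonomy missing for OTUs: ",
           paste(utils::head(missing_tax, 5L), collapse = ", "))
    taxonomy <- as.character(taxonomy[colnames(counts)])
    names(taxonomy) <- colnames(counts)
  }
  structure(list(counts = counts, taxonomy = taxonomy), class = "otu_table")
}

#' @export
print.otu_table <- function(x, ...) {
  cat(sprintf("otu_table: %d samples x %d OTUs\n",
              nrow(x$counts), ncol(x$counts)))
  depth <- rowSums(x$counts)
  cat(sprintf("  reads/sample: min %d, median %s, max %d\n",
              min(depth), format(stats::median(depth)), max(depth)))
  if (!is.null(x$taxonomy)) cat("  taxonomy: present\n")
  invisible(x)
}

#' @export
dim.otu_table <- function(x) dim(x$counts)

#' Accessors for `otu_table` objects
#'
#' @param x an [otu_table()].
#' @return `otu_counts()` the integer count matrix; `sample_ids()` and
#'   `otu_ids()` character vectors of identifiers.
#' @export
otu_counts <- function(x) {
  stopifnot(inherits(x, "otu_table"))
  x$counts
}

#' @rdname otu_counts
#' @export
sample_ids <- function(x) rownames(otu_counts(x))

#' @rdname otu_counts
#' @export
otu_ids <- function(x) colnames(otu_counts(x))

# Internal: subset an otu_table, keeping taxonomy in sync.
subset_otu_table <- function(x, samples = NULL, otus = NULL) {
  cnt <- x$counts
  if (!is.null(samples)) cnt <- cnt[samples, , drop = FALSE]
  if (!is.null(otus)) cnt <- cnt[, otus, drop = FALSE]
  tax <- if (is.null(x$taxonomy)) NULL else x$taxonomy[colnames(cnt)]
  otu_table(cnt, taxonomy = tax)
}

env_variables <- c("moisture", "pH", "TP", "TC", "TN", "CN")
metadata_columns <- c("sample_id", "land_use", "lon", "lat", env_variables)

#' Read an OTU table from a tab-delimited file
#'
#' The canonical layout is samples as rows with a leading id column.  The
#' common amplicon-pipeline export (OTUs as rows, optionally with a trailing
#' `taxonomy` column) is accepted via `orientation = "otus_as_rows"`; the
#' returned table is always samples x OTUs.
#'
#' @param path path to a TSV file with a header row and an id column first.
#' @param orientation `"samples_as_rows"` (default) or `"otus_as_rows"`.
#' @return An [otu_table()].
#' @seealso [write_otu_table()]
#' @export
read_otu_table <- function(path,
                           orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expected an id column plus at least one data column")
  ids <- as.character(df[[1L]])
  df <- df[, -1L, drop = FALSE]
  taxonomy <- NULL
  if (orientation == "otus_as_rows" &&
      tolower(names(df)[ncol(df)]) == "taxonomy") {
    taxonomy <- as.character(df[[ncol(df)]])
    names(taxonomy) <- ids
    df <- df[, -ncol(df), drop = FALSE]
  }
  for (j in seq_along(df)) {
    v <- df[[j]]
    if (!is.numeric(v))
      stop(sprintf("non-numeric value in column '%s' (e.g. '%s')",
                   names(df)[j], as.character(v[!grepl("^\\s*-?[0-9.]+\\s*$",
                                                       as.character(v))][1L])))
    bad <- which(!is.finite(v) | v < 0 | abs(v - round(v)) > 1e-8)
    if (length(bad))
      stop(sprintf("non-integer or negative count at row '%s', column '%s': %s",
                   ids[bad[1L]], names(df)[j], v[bad[1L]]))
  }
  m <- as.matrix(df)
  rownames(m) <- ids
  if (orientation == "otus_as_rows") m <- t(m)
  otu_table(m, taxonomy = taxonomy)
}

#' Write an OTU table to a tab-delimited file
#'
#' @param x an [otu_table()].
#' @param path output path.
#' @param orientation row layout to write; `"otus_as_rows"` appends the
#'   taxonomy column when present.
#' @return `path`, invisibly.
#' @export
write_otu_table <- function(x, path,
                            orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "otu_table"))
  if (orientation == "samples_as_rows") {
    df <- data.frame(sample_id = sample_ids(x), x$counts,
                     check.names = FALSE, row.names = NULL)
  } else {
    df <- data.frame(otu_id = otu_ids(x), t(x$counts),
                     check.names = FALSE, row.names = NULL)
    if (!is.null(x$taxonomy)) df$taxonomy <- unname(x$taxonomy)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' Expects a TSV with one row per sample and the mandatory columns
#' `sample_id`, `land_use`, `lon`, `lat` plus the six soil variables
#' `moisture`, `pH`, `TP`, `TC`, `TN`, `CN`.  Extra columns are preserved
#' (with a message).
#'
#' @param path path to a TSV file.
#' @return A validated `data.frame` of sample metadata.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  validate_metadata(df)
}

#' Validate a metadata data frame
#'
#' @param df a data.frame candidate.
#' @return The validated data frame (invisibly the same object).
#' @export
validate_metadata <- function(df) {
  missing_cols <- setdiff(metadata_columns, names(df))
  if (length(missing_cols))
    stop("metadata is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample ids in metadata: ",
         paste(unique(df$sample_id[duplicated(df$sample_id)]), collapse = ", "))
  for (v in c("lon", "lat", env_variables)) {
    if (!is.numeric(df[[v]]))
      stop(sprintf("metadata column '%s' must be numeric", v))
    if (any(!is.finite(df[[v]])))
      stop(sprintf("metadata column '%s' contains non-finite values", v))
  }
  if (any(df$lat < -90 | df$lat > 90))
    stop("latitude out of range [-90, 90]")
  if (any(df$lon < -180 | df$lon > 180))
    stop("longitude out of range [-180, 180]")
  extra <- setdiff(names(df), metadata_columns)
  if (length(extra))
    message("metadata has extra column(s), preserved: ",
            paste(extra, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  df$land_use <- as.character(df$land_use)
  df
}

#' Write sample metadata to a tab-delimited file
#'
#' @param meta metadata data frame (see [read_metadata()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(meta, path) {
  utils::write.table(meta, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align an OTU table and metadata on their shared samples
#'
#' Both objects are restricted to the intersection of their sample ids, in
#' the OTU table's order (the count table anchors the analysis).  Dropped ids
#' are reported in a warning.  Applying the function twice changes nothing.
#'
#' @param table an [otu_table()].
#' @param meta a metadata data frame.
#' @return `list(table =, meta =)` with matching sample order.
#' @export
align_samples <- function(table, meta) {
  stopifnot(inherits(table, "otu_table"))
  meta <- validate_metadata(meta)
  shared <- intersect(sample_ids(table), meta$sample_id)
  if (!length(shared))
    stop("no shared sample ids between OTU table and metadata")
  dropped <- c(setdiff(sample_ids(table), shared),
               setdiff(meta$sample_id, shared))
  if (length(dropped))
    warning("dropping unmatched sample(s): ", paste(dropped, collapse = ", "))
  table <- subset_otu_table(table, samples = shared)
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  rownames(meta) <- NULL
  list(table = table, meta = meta)
}
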