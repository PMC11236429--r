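subcomm_levels <- c("AAT", "CAT", "MT", "CRT", "CRAT", "RT")

#' Per-sample relative abundances
#'
#' @param table an [otu_table()] or a counts matrix (samples x OTUs).
#' @return A matrix of proportions; every row sums to 1.
#' @export
relative_abundance <- function(table) {
  cnt <- if (inherits(table, "otu_table")) otu_counts(table) else as.matrix(table)
  totals <- rowSums(cnt)
  if (any(totals <= 0))
    stop("zero-total sample(s): ",
         paste(rownames(cnt)[totals <= 0], collapse = ", "))
  sweep(cnt, 1L, totals, "/")
}

#' Classify OTUs into six abundance-based subcommunities
#'
#' Every OTU is assigned exactly one category from the min/max of its
#' relative abundance across samples, with "rare" meaning at or below the
#' rare cutoff \eqn{t_r} (zeros are rare) and "abundant" meaning at or
#' above the abundant cutoff \eqn{t_a}:
#'
#' * `RT`  (always rare): max \eqn{\le t_r}
#' * `AAT` (always abundant): min \eqn{\ge t_a}
#' * `MT`  (moderate): strictly between the cutoffs in every sample
#' * `CRT` (conditionally rare): rare somewhere, never abundant
#' * `CAT` (conditionally abundant): abundant somewhere, never rare
#' * `CRAT` (conditionally rare and abundant): rare in some samples and
#'   abundant in others
#'
#' The six rules are mutually exclusive and exhaustive over (min, max).
#'
#' @param table an [otu_table()], counts matrix, or relative-abundance
#'   matrix (rows summing to 1).
#' @param rare_cutoff rare threshold \eqn{t_r} as a relative abundance
#'   (default `1e-4`, i.e. 0.01\%).
#' @param abundant_cutoff abundant threshold \eqn{t_a} (default `0.01`,
#'   i.e. 1\%).
#' @return An object of class `subcomm_partition`: a list with `category`
#'   (named factor over the six levels), and the two cutoffs.
#' @examples
#' tab <- simulate_neutral(n_samples = 8, n_otus = 300, depth = 2000,
#'                         m = 0.3, seed = 1)
#' part <- classify_taxa(tab)
#' table(part$category)
#' @export
classify_taxa <- function(table, rare_cutoff = 1e-4, abundant_cutoff = 0.01) {
  if (!(rare_cutoff > 0 && rare_cutoff < abundant_cutoff && abundant_cutoff < 1))
    stop("cutoffs must satisfy 0 < rare_cutoff < abundant_cutoff < 1")
  ra <- if (inherits(table, "otu_table") ||
            any(rowSums(as.matrix(table)) > 1 + 1e-6))
    relative_abundance(table) else as.matrix(table)
  mn <- apply(ra, 2L, min)
  mx <- apply(ra, 2L, max)
  category <- ifelse(mx <= rare_cutoff, "RT",
              ifelse(mn >= abundant_cutoff, "AAT",
              ifelse(mn <= rare_cutoff,
                     ifelse(mx >= abundant_cutoff, "CRAT", "CRT"),
                     ifelse(mx >= abundant_cutoff, "CAT", "MT"))))
  category <- factor(category, levels = subcomm_levels)
  names(category) <- colnames(ra)
  structure(list(category = category,
                 rare_cutoff = rare_cutoff,
                 abundant_cutoff = abundant_cutoff),
            class = "subcomm_partition")
}

#' @export
print.subcomm_partition <- function(x, ...) {
  cat(sprintf("subcomm_partition: %d OTUs (rare cutoff %g, abundant cutoff %g)\n",
              length(x$category), x$rare_cutoff, x$abundant_cutoff))
  print(table(x$category))
  invisible(x)
}

#' Summarize a subcommunity partition
#'
#' OTU and read shares per category, the numbers behind the classic
#' bar/pie summary of a subcommunity classification.  All six categories
#' are always reported, including empty ones.
#'
#' @param partition a [classify_taxa()] result covering the table's OTUs.
#' @param table the [otu_table()] that was classified.
#' @return A data frame with columns `category`, `n_otus`, `pct_otus`,
#'   `n_reads`, `pct_reads`; the percentage columns each sum to 100.
#' @export
partition_summary <- function(partition, table) {
  stopifnot(inherits(partition, "subcomm_partition"),
            inherits(table, "otu_table"))
  cnt <- otu_counts(table)
  if (!all(colnames(cnt) %in% names(partition$category)))
    stop("partition does not cover all OTUs of the table")
  cat_tab <- partition$category[colnames(cnt)]
  reads_per_otu <- colSums(cnt)
  n_otus <- as.integer(table(cat_tab))
  n_reads <- as.numeric(tapply(reads_per_otu, cat_tab, sum, default = 0))
  data.frame(category = subcomm_levels,
             n_otus = n_otus,
             pct_otus = 100 * n_otus / sum(n_otus),
             n_reads = n_reads,
             pct_reads = 100 * n_reads / sum(n_reads),
             stringsAsFactors = FALSE)
}

#' Restrict an OTU table to selected subcommunity categories
#'
#' @param table an [otu_table()].
#' @param partition a [classify_taxa()] result covering the table's OTUs.
#' @param categories character vector of category labels to keep.
#' @return An [otu_table()] with samples unchanged.
#' @export
subset_by_category <- function(table, partition, categories) {
  stopifnot(inherits(partition, "subcomm_partition"),
            inherits(table, "otu_table"))
  if (!length(categories)) stop("'categories' must be non-empty")
  bad <- setdiff(categories, subcomm_levels)
  if (length(bad)) stop("unknown categor(ies): ", paste(bad, collapse = ", "))
  keep <- names(partition$category)[partition$category %in% categories]
  keep <- intersect(otu_ids(table), keep)
  if (!length(keep))
    stop("no OTU falls in categor(ies) ", paste(categories, collapse = ", "))
  out <- subset_otu_table(table, otus = keep)
  empty <- rowSums(otu_counts(out)) == 0
  if (any(empty))
    message("sample(s) with zero reads in this subcommunity: ",
            paste(sample_ids(out)[empty], collapse = ", "))
  out
}

#' Subcommunity grouping presets
#'
#' How categories are pooled for the downstream analyses.  The `"paper"`
#' preset merges the two abundant-touching transient classes (CRAT with
#' CAT) and analyzes CRT and RT separately, mirroring the common practice
#' for urban-soil subcommunity studies; moderate taxa are reported in the
#' partition summary but not analyzed.  `"six"` analyzes each category on
#' its own.
#'
#' @param preset `"paper"` or `"six"`.
#' @return Named list of category sets.
#' @export
grouping_sets <- function(preset = c("paper", "six")) {
  preset <- match.arg(preset)
  if (preset == "paper")
    list(CRAT_CAT = c("CRAT", "CAT"), CRT = "CRT", RT = "RT")
  else
    as.list(stats::setNames(subcomm_levels, subcomm_levels))
}
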