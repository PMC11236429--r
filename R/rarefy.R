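#' Rarefy an OTU table to even depth
#'
#' Uniform subsampling of reads without replacement (multivariate
#' hypergeometric), so every retained sample sums exactly to `depth`.
#' Samples whose total is below the target depth are dropped with a
#' warning rather than padded: an even depth is a hard requirement
#' downstream (the neutral-model detection limit is one read in `depth`).
#' OTUs left with zero reads everywhere are removed.
#'
#' @param table an [otu_table()].
#' @param depth target reads per sample; default the minimum sample total.
#' @param seed optional integer seed (subsampling is random).
#' @return A rarefied [otu_table()].
#' @export
rarefy_table <- function(table, depth = NULL, seed = NULL) {
  stopifnot(inherits(table, "otu_table"))
  cnt <- otu_counts(table)
  totals <- rowSums(cnt)
  if (is.null(depth)) depth <- min(totals)
  if (depth <= 0) stop("'depth' must be a positive integer")
  keep <- totals >= depth
  if (!any(keep)) stop("no sample reaches the target depth ", depth)
  if (any(!keep))
    warning("dropping sample(s) below depth ", depth, ": ",
            paste(rownames(cnt)[!keep], collapse = ", "))
  cnt <- cnt[keep, , drop = FALSE]
  if (!is.null(seed)) set.seed(seed)
  rar <- withCallingHandlers(
    vegan::rrarefy(cnt, depth),
    # advisory emitted for tables that look sparse; counts are validated here
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  storage.mode(rar) <- "integer"
  nonzero <- colSums(rar) > 0
  tax <- if (is.null(table$taxonomy)) NULL else
    table$taxonomy[colnames(rar)[nonzero]]
  otu_table(rar[, nonzero, drop = FALSE], taxonomy = tax)
}

#' Expected richness under rarefaction
#'
#' Analytic (hypergeometric) expectation of the number of OTUs observed in
#' a uniform subsample of `n` reads without replacement from a single
#' sample's counts: `sum_i 1 - C(N - c_i, n) / C(N, n)`, evaluated in
#' log-space for numerical stability.
#'
#' @param counts integer vector of one sample's OTU counts.
#' @param n subsample size, `0 <= n <= sum(counts)`.
#' @return Expected richness (a real number).
#' @examples
#' expected_richness(c(5, 5), 1)   # 2 * (1 - 5/10) = 1
#' expected_richness(c(5, 5), 10)  # full depth: observed richness 2
#' @export
expected_richness <- function(counts, n) {
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("'counts' must be non-negative integers")
  N <- sum(counts)
  if (n < 0 || n > N) stop("'n' must be in [0, sum(counts)]")
  counts <- counts[counts > 0]
  sum(1 - exp(lchoose(N - counts, n) - lchoose(N, n)))
}

#' Analytic rarefaction curves
#'
#' Expected richness at a grid of depths for every sample, the sufficiency
#' check run before classifying taxa: curves that plateau indicate the
#' sequencing effort captured most of the diversity.
#'
#' @param table an [otu_table()].
#' @param n_points number of evenly spaced depths per sample (always
#'   includes the sample total).
#' @return A long data frame `sample_id`, `depth`, `expected_richness`.
#' @export
rarefaction_curve <- function(table, n_points = 20) {
  stopifnot(inherits(table, "otu_table"))
  cnt <- otu_counts(table)
  out <- lapply(rownames(cnt), function(s) {
    tot <- sum(cnt[s, ])
    depths <- unique(round(seq(0, tot, length.out = n_points + 1L)))
    data.frame(sample_id = s, depth = depths,
               expected_richness = vapply(depths, function(n)
                 expected_richness(cnt[s, ], n), numeric(1L)))
  })
  do.call(rbind, out)
}
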