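#' Bray-Curtis dissimilarity between samples
#'
#' \eqn{d_{jk} = \sum_i |x_{ij} - x_{ik}| / \sum_i (x_{ij} + x_{ik})}.
#' Computed by default on per-sample proportions, which makes the matrix
#' invariant to sequencing depth; on an evenly rarefied table counts and
#' proportions give identical results.
#'
#' @param table an [otu_table()].
#' @param on `"proportions"` (default) or `"counts"`.
#' @return A `dist` object (dissimilarity; similarity is `1 - d`).
#' @export
bray_curtis <- function(table, on = c("proportions", "counts")) {
  on <- match.arg(on)
  cnt <- otu_counts(table)
  if (any(rowSums(cnt) <= 0))
    stop("zero-total sample(s): ",
         paste(sample_ids(table)[rowSums(cnt) <= 0], collapse = ", "))
  x <- if (on == "proportions") relative_abundance(table) else cnt
  vegan::vegdist(x, method = "bray")
}

#' Standardized Euclidean environmental distance
#'
#' Each variable is z-scored across samples (mean 0, sd 1, sample sd with
#' n-1), so all variables weigh equally regardless of units, then the
#' Euclidean distance between sample vectors is taken.
#'
#' @param meta metadata data frame (see [read_metadata()]).
#' @param variables which numeric columns to use; default the six soil
#'   variables.
#' @return A `dist` object labelled by sample id.
#' @export
environmental_distance <- function(meta, variables = env_variables) {
  missing_cols <- setdiff(variables, names(meta))
  if (length(missing_cols))
    stop("metadata lacks variable(s): ", paste(missing_cols, collapse = ", "))
  X <- as.matrix(meta[, variables, drop = FALSE])
  if (!is.numeric(X)) stop("selected variables must be numeric")
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant variable(s): ",
         paste(variables[sds == 0], collapse = ", "))
  Z <- scale(X)
  rownames(Z) <- meta$sample_id
  stats::dist(Z)
}

#' Mantel test between two distance matrices
#'
#' Correlation (Spearman by default) of the lower triangles, with
#' significance from joint row/column permutations of the second matrix;
#' the p-value is one-sided (permuted r at least as large as observed)
#' with the +1 exact-test correction, so it can never be 0.
#'
#' @param d1,d2 `dist` objects over the same samples, in the same order;
#'   both are interpreted as dissimilarities.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_permutations number of permutations (default 999).
#' @param seed optional integer seed.
#' @return A list of class `mantel_result`: `r`, `p_value`,
#'   `n_permutations`, `method`, `seed`.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  d1 <- stats::as.dist(d1); d2 <- stats::as.dist(d2)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices have different sizes")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices are labelled differently; align samples first")
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::mantel(d1, d2, method = method,
                       permutations = n_permutations)
  structure(list(r = unname(fit$statistic),
                 p_value = unname(fit$signif),
                 n_permutations = n_permutations,
                 method = method, seed = seed),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (%s): r = %.4f, p = %.4g (%d permutations)\n",
              x$method, x$r, x$p_value, x$n_permutations))
  invisible(x)
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of whether between-group dissimilarities
#' exceed within-group ones; `R = (mean between-rank - mean within-rank) /
#' (M/2)` with `M = n(n-1)/2`.
#'
#' @param d a `dist` of community dissimilarities.
#' @param grouping factor or character of group labels, one per sample;
#'   at least 2 groups with at least 2 samples each.
#' @param n_permutations permutations for the p-value.
#' @param seed optional integer seed.
#' @return A list of class `anosim_result`: `R`, `p_value`,
#'   `n_permutations`, `grouping`.
#' @export
anosim_test <- function(d, grouping, n_permutations = 999, seed = NULL) {
  d <- stats::as.dist(d)
  grouping <- as.factor(grouping)
  if (length(grouping) != attr(d, "Size"))
    stop("'grouping' must have one label per sample")
  sizes <- table(grouping)
  if (length(sizes) < 2L) stop("need at least 2 groups")
  if (any(sizes < 2L))
    stop("group(s) of size 1: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::anosim(d, grouping, permutations = n_permutations)
  structure(list(R = unname(fit$statistic),
                 p_value = unname(fit$signif),
                 n_permutations = n_permutations,
                 grouping = deparse(substitute(grouping))),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations)\n",
              x$R, x$p_value, x$n_permutations))
  invisible(x)
}

#' Distance-decay regression of community similarity on distance
#'
#' Ordinary least squares of lower-triangle community similarity
#' (`1 - dissimilarity`) on lower-triangle distance, plus the
#' accompanying Mantel test.  The Mantel statistic is computed on
#' dissimilarities (sign convention documented in the vignette); the
#' regression slope is reported as-is, so a decay of similarity with
#' distance shows up as a negative slope.
#'
#' @param community `dist` of community dissimilarities (e.g.
#'   [bray_curtis()]).
#' @param distance `dist` of environmental (or geographic) distances.
#' @param method,n_permutations,seed passed to [mantel_test()].
#' @return A list of class `distance_decay`: `slope`, `intercept`,
#'   `r_squared`, and `mantel` (a `mantel_result`).
#' @export
distance_decay_fit <- function(community, distance,
                               method = "spearman",
                               n_permutations = 999, seed = NULL) {
  community <- stats::as.dist(community)
  distance <- stats::as.dist(distance)
  if (attr(community, "Size") < 3L) stop("need at least 3 sites")
  if (attr(community, "Size") != attr(distance, "Size"))
    stop("distance matrices have different sizes")
  sim <- 1 - as.vector(community)
  dst <- as.vector(distance)
  fit <- stats::lm(sim ~ dst)
  mt <- mantel_test(community, distance, method = method,
                    n_permutations = n_permutations, seed = seed)
  structure(list(slope = unname(stats::coef(fit)[2L]),
                 intercept = unname(stats::coef(fit)[1L]),
                 r_squared = summary(fit)$r.squared,
                 mantel = mt),
            class = "distance_decay")
}

#' @export
print.distance_decay <- function(x, ...) {
  cat(sprintf("distance-decay: slope = %.4g, intercept = %.4g, R2 = %.3f\n",
              x$slope, x$intercept, x$r_squared))
  print(x$mantel)
  invisible(x)
}
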