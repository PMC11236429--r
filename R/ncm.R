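#' Per-OTU occurrence statistics
#'
#' Inputs of the neutral community model: for each OTU, the mean relative
#' abundance across samples (`p`, zeros included in the mean) and the
#' occurrence frequency (`f_obs`, fraction of samples with at least one
#' read).  Requires an evenly rarefied table, because the model's
#' detection limit is one read out of the common depth.  OTUs absent from
#' every sample are dropped.
#'
#' Subsetting a rarefied table to one subcommunity necessarily unevens
#' the per-sample totals; for that case `require_even_depth = FALSE`
#' follows the usual neutral-model convention of taking `N` as the mean
#' reads per sample (rounded).
#'
#' @param table an [otu_table()] with identical sample totals.
#' @param require_even_depth error on uneven depths (default) instead of
#'   falling back to the mean depth.
#' @return Data frame `otu_id`, `p`, `f_obs`, with attribute `"N"` (the
#'   common, or mean, depth).
#' @export
occurrence_stats <- function(table, require_even_depth = TRUE) {
  cnt <- otu_counts(table)
  totals <- rowSums(cnt)
  if (any(totals == 0))
    stop("zero-total sample(s): ",
         paste(rownames(cnt)[totals == 0], collapse = ", "),
         "; drop them before fitting")
  if (length(unique(totals)) != 1L && require_even_depth)
    stop("sample depths are uneven; rarefy the table first (rarefy_table)")
  ra <- sweep(cnt, 1L, totals, "/")
  p <- colMeans(ra)
  f_obs <- colMeans(cnt > 0)
  keep <- p > 0
  out <- data.frame(otu_id = colnames(cnt)[keep], p = unname(p[keep]),
                    f_obs = unname(f_obs[keep]), stringsAsFactors = FALSE)
  attr(out, "N") <- as.integer(round(mean(totals)))
  out
}

#' Sloan's expected occurrence frequency
#'
#' Under the neutral community model an OTU with metacommunity relative
#' abundance `p` has local relative abundance distributed
#' `Beta(Nm p, Nm (1 - p))`; its expected occurrence frequency across
#' samples is the probability of exceeding the detection limit `d`:
#' `1 - I_d(Nm p, Nm (1 - p))`, with `I` the regularized incomplete beta
#' function (Beta CDF).  Monotone non-decreasing in `p`.
#'
#' @param p relative abundance(s), each in (0, 1).
#' @param Nm metacommunity size times immigration rate, > 0.
#' @param d detection limit in (0, 1), typically one read out of the
#'   sample depth.
#' @return Expected frequency in `[0, 1]`, vectorized over `p`.
#' @export
sloan_expected_frequency <- function(p, Nm, d) {
  if (any(p <= 0 | p >= 1)) stop("'p' must be in (0, 1)")
  if (Nm <= 0) stop("'Nm' must be > 0")
  if (d <= 0 || d >= 1) stop("'d' must be in (0, 1)")
  1 - stats::pbeta(d, Nm * p, Nm * (1 - p))
}

#' Least-squares fit of the Sloan occurrence curve
#'
#' Core of [fit_ncm()]: bounded nonlinear least squares of observed
#' occurrence frequencies on [sloan_expected_frequency()] over the
#' immigration rate `m` in (1e-6, 1], multi-started from
#' m = 1e-4, 1e-3, 1e-2, 1e-1, 0.5 (the 1-D objective can be multi-modal
#' at small sizes); convergence tolerance 1e-10 on `m`.
#'
#' @param p mean relative abundances in (0, 1).
#' @param f_obs observed occurrence frequencies in `[0, 1]`.
#' @param N reads per sample; the detection limit is `1/N`.
#' @return List `m`, `Nm`, `r_squared` (`1 - SSE/SST`, negative when the
#'   curve predicts worse than the mean), `sse`, `detection_limit`.
#' @export
fit_sloan_curve <- function(p, f_obs, N) {
  stopifnot(length(p) == length(f_obs), N >= 1)
  d <- 1 / N
  objective <- function(m) {
    f_hat <- 1 - stats::pbeta(d, N * m * p, N * m * (1 - p))
    sum((f_obs - f_hat)^2)
  }
  starts <- c(1e-4, 1e-3, 1e-2, 1e-1, 0.5)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      stats::nlminb(s, objective, lower = 1e-6, upper = 1,
                    control = list(x.tol = 1e-10)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best))
    stop("neutral-model fit failed to converge from starts m = ",
         paste(starts, collapse = ", "))
  sst <- sum((f_obs - mean(f_obs))^2)
  list(m = best$par, Nm = N * best$par,
       r_squared = 1 - best$objective / sst,
       sse = best$objective, detection_limit = d)
}

# Wilson score interval for a proportion (n trials), the binomial
# confidence convention used for the occurrence envelope.
wilson_interval <- function(phat, n, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  center <- (phat + z^2 / (2 * n)) / denom
  half <- z / denom * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2))
  cbind(lower = pmax(center - half, 0), upper = pmin(center + half, 1))
}

#' Fit Sloan's neutral community model
#'
#' Estimates the immigration rate `m` by bounded nonlinear least squares
#' of observed occurrence frequencies on [sloan_expected_frequency()]
#' with `Nm = N * m` and detection limit `d = 1/N` (one read), using
#' multi-start optimization over `m` in (1e-6, 1].  The goodness of fit
#' is the generalized `R2 = 1 - SSE/SST`, which is negative when the
#' model predicts worse than the mean occurrence frequency.  A 95% Wilson
#' score envelope (n = number of samples) around the predicted
#' frequencies classifies every OTU as above, within, or below the
#' neutral expectation.
#'
#' @param table an evenly rarefied [otu_table()] (or a subcommunity
#'   subset of one, with `require_even_depth = FALSE`).
#' @param min_otus minimum number of usable OTUs (default 50).
#' @param level envelope confidence level (default 0.95).
#' @param require_even_depth see [occurrence_stats()].
#' @return A list of class `ncm_fit`: `m`, `Nm`, `N`, `r_squared`,
#'   `detection_limit`, `n_otus_used`, `n_samples`, and `otu` (data
#'   frame: otu_id, p, f_obs, f_pred, lower, upper, status).
#' @examples
#' tab <- simulate_neutral(n_samples = 20, n_otus = 500, depth = 2000,
#'                         m = 0.2, seed = 1)
#' fit <- fit_ncm(tab)
#' fit$Nm
#' @export
fit_ncm <- function(table, min_otus = 50, level = 0.95,
                    require_even_depth = TRUE) {
  stats_df <- occurrence_stats(table, require_even_depth)
  N <- attr(stats_df, "N")
  if (nrow(stats_df) < min_otus)
    stop("only ", nrow(stats_df), " usable OTUs (need >= ", min_otus, ")")
  curve <- fit_sloan_curve(stats_df$p, stats_df$f_obs, N)
  p <- stats_df$p
  f_obs <- stats_df$f_obs
  m <- curve$m
  d <- curve$detection_limit
  f_pred <- sloan_expected_frequency(p, N * m, d)
  wb <- wilson_interval(f_pred, nrow(otu_counts(table)), level)
  status <- ifelse(f_obs > wb[, "upper"], "above",
                   ifelse(f_obs < wb[, "lower"], "below", "within"))
  structure(list(m = m, Nm = curve$Nm, N = N,
                 r_squared = curve$r_squared,
                 detection_limit = d,
                 n_otus_used = nrow(stats_df),
                 n_samples = nrow(otu_counts(table)),
                 otu = data.frame(stats_df, f_pred = f_pred,
                                  lower = wb[, "lower"],
                                  upper = wb[, "upper"],
                                  status = status,
                                  stringsAsFactors = FALSE)),
            class = "ncm_fit")
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf(
    "Sloan NCM fit: m = %.4g, Nm = %.1f, R2 = %.3f (N = %d, %d OTUs, %d samples)\n",
    x$m, x$Nm, x$r_squared, x$N, x$n_otus_used, x$n_samples))
  print(envelope_partition(x))
  invisible(x)
}

#' Partition OTUs by their position relative to the neutral envelope
#'
#' @param fit an [fit_ncm()] result.
#' @return Named integer vector `above`, `within`, `below`; sums to the
#'   number of OTUs used in the fit.
#' @export
envelope_partition <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  status <- factor(fit$otu$status, levels = c("above", "within", "below"))
  out <- table(status)
  stats::setNames(as.integer(out), names(out))
}

#' Plot a neutral community model fit
#'
#' Occurrence frequency against log10 mean relative abundance with the
#' fitted Sloan curve and its 95% Wilson envelope.
#'
#' @param x an [fit_ncm()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.ncm_fit <- function(x, ...) {
  ot <- x$otu
  cols <- c(above = "#1b9e77", within = "grey40", below = "#d95f02")
  graphics::plot(log10(ot$p), ot$f_obs, pch = 16, cex = 0.5,
                 col = cols[ot$status],
                 xlab = "log10 mean relative abundance",
                 ylab = "occurrence frequency", ...)
  o <- order(ot$p)
  graphics::lines(log10(ot$p[o]), ot$f_pred[o], lwd = 2, col = "blue")
  graphics::lines(log10(ot$p[o]), ot$lower[o], lty = 2, col = "blue")
  graphics::lines(log10(ot$p[o]), ot$upper[o], lty = 2, col = "blue")
  graphics::legend("topleft", bty = "n",
                   legend = sprintf("m = %.3g, Nm = %.0f, R2 = %.2f",
                                    x$m, x$Nm, x$r_squared))
  invisible(x)
}
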