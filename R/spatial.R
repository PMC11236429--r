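#' PCNM spatial eigenvectors from site coordinates
#'
#' Principal coordinates of neighbour matrices: (1) geographic distance
#' between sites, great-circle (haversine, km) by default since surveys
#' record lon/lat, or plain Euclidean on the coordinate values for planar
#' synthetic designs; (2) truncation at the longest edge of the minimum
#' spanning tree, with larger distances replaced by four times the
#' threshold; (3) principal-coordinates analysis of the truncated matrix;
#' (4) eigenvectors with positive eigenvalues (> 1e-10), scaled to unit
#' norm, ordered by decreasing eigenvalue and named `PCNM1`, `PCNM2`, ...
#' The columns are centered and mutually orthogonal, ready to serve as
#' spatial predictors.
#'
#' @param meta metadata data frame with `lon`, `lat`, `sample_id`; or a
#'   two-column matrix of coordinates.
#' @param distance_mode `"great_circle"` (default) or
#'   `"euclidean_on_degrees"`.
#' @return A list of class `pcnm_basis`: `vectors` (n x k matrix),
#'   `eigenvalues`, `threshold`, `distance_mode`, `ids`.
#' @export
pcnm_vectors <- function(meta,
                         distance_mode = c("great_circle",
                                           "euclidean_on_degrees")) {
  distance_mode <- match.arg(distance_mode)
  if (is.data.frame(meta)) {
    coords <- cbind(meta$lon, meta$lat)
    ids <- meta$sample_id
  } else {
    coords <- as.matrix(meta)
    ids <- rownames(coords)
  }
  if (nrow(coords) < 3L) stop("need at least 3 sites")
  if (distance_mode == "great_circle") {
    D <- stats::as.dist(geosphere::distm(coords,
                                         fun = geosphere::distHaversine) / 1000)
  } else {
    D <- stats::dist(coords)
  }
  if (max(D) == 0) stop("all sites are collocated")
  fit <- vegan::pcnm(D)
  pos <- which(fit$values > 1e-10)
  if (!length(pos)) stop("no positive PCNM eigenvalues")
  vec <- fit$vectors[, pos, drop = FALSE]
  vec <- sweep(vec, 2L, sqrt(colSums(vec^2)), "/")  # unit norm
  colnames(vec) <- paste0("PCNM", seq_along(pos))
  rownames(vec) <- ids
  structure(list(vectors = vec, eigenvalues = unname(fit$values[pos]),
                 threshold = fit$threshold, distance_mode = distance_mode,
                 ids = ids),
            class = "pcnm_basis")
}

#' @export
print.pcnm_basis <- function(x, ...) {
  cat(sprintf("pcnm_basis: %d sites, %d positive eigenvectors (%s, truncation %.4g)\n",
              nrow(x$vectors), ncol(x$vectors), x$distance_mode, x$threshold))
  invisible(x)
}

# Internal RDA engine: R^2 of (column-centered) Y on centered predictors X.
# Returns the thin-QR of centered X so callers can reuse it.
rda_r2_engine <- function(X) {
  Xc <- scale(as.matrix(X), center = TRUE, scale = FALSE)
  qr(Xc)
}

rda_r2 <- function(qrx, Yc, ss_tot = sum(Yc^2)) {
  if (is.null(qrx)) return(0)
  Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
  sum(crossprod(Q, Yc)^2) / ss_tot
}

#' Forward selection of predictors with the double stopping rule
#'
#' Greedy forward selection for redundancy analysis with Blanchet's two
#' stopping criteria.  The global model with all candidates is tested
#' first (permutation test); if it is not significant at `alpha`, nothing
#' is selected.  Otherwise candidates are added one at a time, always the
#' one maximizing the model R-squared, until the best candidate's partial
#' permutation p-value exceeds `alpha` or the cumulative adjusted
#' R-squared would exceed that of the global model.
#'
#' @param Y response matrix (samples x species), e.g. a
#'   Hellinger-transformed table.
#' @param X candidate predictors: data frame or matrix with unique column
#'   names.
#' @param alpha significance threshold for entry (default 0.05).
#' @param n_permutations permutations per test (default 999).
#' @param seed optional integer seed.
#' @param r2_scope enforce the adjusted-R-squared cap of the global model
#'   (default TRUE; disable together with `alpha = 1` to rank all
#'   candidates greedily).
#' @return A list of class `forward_selection`: `selected` (character),
#'   `steps` (data frame: variable, R2_cum, adjR2_cum, F, p),
#'   `global_r2`, `global_adj_r2`, `global_p`, `alpha`,
#'   `n_permutations`.
#' @export
forward_select <- function(Y, X, alpha = 0.05, n_permutations = 999,
                           seed = NULL, r2_scope = TRUE) {
  X <- as.data.frame(X)
  if (anyDuplicated(names(X)))
    stop("duplicate column names in 'X': ",
         paste(unique(names(X)[duplicated(names(X))]), collapse = ", "))
  Y <- as.matrix(Y)
  if (nrow(Y) != nrow(X)) stop("'Y' and 'X' must have the same rows")
  n <- nrow(Y)
  if (!is.null(seed)) set.seed(seed)

  # orthonormal reduction of Y: identical R2/F statistics, cheaper perms
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (ncol(Yc) > n) {
    sv <- svd(Yc, nv = 0)
    Yc <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  }
  ss_tot <- sum(Yc^2)
  perms <- replicate(n_permutations, sample.int(n), simplify = FALSE)

  # global test; a saturated global model (candidates >= n - 1) leaves the
  # adjusted R2 undefined, so both stopping aids fall away with a warning
  qr_all <- rda_r2_engine(X)
  p_all <- qr_all$rank
  global_r2 <- rda_r2(qr_all, Yc, ss_tot)
  if (n > p_all + 1) {
    global_adj <- adjusted_r2(global_r2, n, p_all)
    Q_all <- qr.Q(qr_all)[, seq_len(p_all), drop = FALSE]
    f_obs <- (global_r2 / p_all) / ((1 - global_r2) / (n - p_all - 1))
    f_perm <- vapply(perms, function(pp) {
      Yp <- Yc[pp, , drop = FALSE]
      Yp <- scale(Yp, center = TRUE, scale = FALSE)
      r2 <- sum(crossprod(Q_all, Yp)^2) / sum(Yp^2)
      (r2 / p_all) / ((1 - r2) / (n - p_all - 1))
    }, numeric(1L))
    global_p <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
  } else {
    warning("global model is saturated (", p_all, " candidates, ", n,
            " samples); falling back to alpha-only stopping")
    global_adj <- NA_real_
    global_p <- 0
    r2_scope <- FALSE
  }

  steps <- data.frame(variable = character(), R2_cum = numeric(),
                      adjR2_cum = numeric(), F = numeric(), p = numeric(),
                      stringsAsFactors = FALSE)
  selected <- character()
  if (global_p <= alpha) {
    remaining <- names(X)
    r2_old <- 0
    while (length(remaining)) {
      r2_new <- vapply(remaining, function(v) {
        rda_r2(rda_r2_engine(X[, c(selected, v), drop = FALSE]), Yc, ss_tot)
      }, numeric(1L))
      best <- remaining[which.max(r2_new)]
      r2_best <- max(r2_new)
      k <- length(selected) + 1L
      f_obs <- ((r2_best - r2_old) / 1) / ((1 - r2_best) / (n - k - 1))
      Qb <- qr.Q(rda_r2_engine(X[, c(selected, best), drop = FALSE]))
      Qs <- if (length(selected))
        qr.Q(rda_r2_engine(X[, selected, drop = FALSE])) else NULL
      f_perm <- vapply(perms, function(pp) {
        Yp <- scale(Yc[pp, , drop = FALSE], center = TRUE, scale = FALSE)
        sst <- sum(Yp^2)
        r2n <- sum(crossprod(Qb, Yp)^2) / sst
        r2o <- if (is.null(Qs)) 0 else sum(crossprod(Qs, Yp)^2) / sst
        ((r2n - r2o) / 1) / ((1 - r2n) / (n - k - 1))
      }, numeric(1L))
      p_best <- (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
      if (p_best > alpha) break
      adj_new <- adjusted_r2(r2_best, n, k)
      if (r2_scope && adj_new > global_adj + 1e-9) break
      selected <- c(selected, best)
      steps <- rbind(steps, data.frame(variable = best, R2_cum = r2_best,
                                       adjR2_cum = adj_new, F = f_obs,
                                       p = p_best,
                                       stringsAsFactors = FALSE))
      remaining <- setdiff(remaining, best)
      r2_old <- r2_best
    }
  }
  structure(list(selected = selected, steps = steps,
                 global_r2 = global_r2, global_adj_r2 = global_adj,
                 global_p = global_p, alpha = alpha,
                 n_permutations = n_permutations),
            class = "forward_selection")
}

#' @export
print.forward_selection <- function(x, ...) {
  cat(sprintf(
    "forward selection: global adjR2 = %.3f (p = %.4g), %d variable(s) selected\n",
    x$global_adj_r2, x$global_p, length(x$selected)))
  if (nrow(x$steps)) print(x$steps, row.names = FALSE)
  invisible(x)
}
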