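#' Hellinger transformation
#'
#' Square root of per-sample relative abundances:
#' \eqn{y_{ij} = \sqrt{c_{ij} / \sum_i c_{ij}}}.  Rows have unit sum of
#' squares, which removes the double-zero problem and makes community data
#' suitable for linear ordination (RDA).
#'
#' @param table an [otu_table()] or counts matrix with positive row sums.
#' @return Numeric matrix, samples x OTUs.
#' @export
hellinger <- function(table) {
  sqrt(relative_abundance(table))
}

#' Ezekiel's adjusted R-squared
#'
#' `1 - (1 - R2) * (n - 1) / (n - p - 1)`, the correction on which
#' variation-partitioning fractions are based.
#'
#' @param r2 unadjusted R-squared.
#' @param n number of samples.
#' @param p number of predictors (0 returns `r2` unchanged).
#' @return Adjusted R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, p) {
  if (p == 0) return(r2)
  if (n <= p + 1) stop("need n > p + 1 (n = ", n, ", p = ", p, ")")
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Redundancy analysis (RDA)
#'
#' Constrained linear ordination: the response matrix is column-centered,
#' regressed on the (centered) predictors by multivariate least squares,
#' and the constrained axes are the principal components of the fitted
#' values.  `R2 = SS(fitted) / SS(Y)`; the overall permutation test
#' permutes rows of `Y`.
#'
#' @param Y response matrix (samples x species), typically
#'   [hellinger()]-transformed.
#' @param X predictors: data frame or matrix of numeric columns, full
#'   column rank.
#' @param n_permutations permutations for the overall test (0 skips it).
#' @param seed optional integer seed.
#' @return A list of class `rda_fit`: `r_squared`, `adj_r_squared`,
#'   `p_value`, `eig` (axis eigenvalues), `site_scores`,
#'   `species_scores`, `biplot_scores`, `n`, `p`.
#' @export
rda_fit <- function(Y, X, n_permutations = 999, seed = NULL) {
  Y <- as.matrix(Y)
  X <- as.data.frame(X)
  n <- nrow(Y)
  if (nrow(X) != n) stop("'Y' and 'X' must have the same rows")
  if (n <= ncol(X) + 1)
    stop("need more samples than predictors + 1")
  Xm <- as.matrix(X)
  if (!is.numeric(Xm)) stop("predictors must be numeric")
  qrx <- rda_r2_engine(Xm)
  if (qrx$rank < ncol(Xm)) {
    dropped <- colnames(Xm)[qrx$pivot[(qrx$rank + 1L):ncol(Xm)]]
    stop("rank-deficient predictors; collinear column(s): ",
         paste(dropped, collapse = ", "))
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  ss_tot <- sum(Yc^2)
  if (ss_tot == 0) stop("response matrix has no variance")
  fitted <- qr.fitted(qrx, Yc)
  r2 <- sum(fitted^2) / ss_tot
  adj <- adjusted_r2(r2, n, ncol(Xm))

  sv <- svd(fitted)
  keep <- which(sv$d^2 / max(sv$d^2, 1e-300) > 1e-12)
  eig <- (sv$d[keep]^2) / (n - 1)
  site <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], length(keep))
  species <- sv$v[, keep, drop = FALSE]
  dimnames(site) <- list(rownames(Y), paste0("RDA", seq_along(keep)))
  dimnames(species) <- list(colnames(Y), paste0("RDA", seq_along(keep)))
  biplot <- stats::cor(scale(Xm), site)

  p_value <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    # reduce Y for the permutation loop (R2 invariant to orthonormal rotation)
    Yr <- Yc
    if (ncol(Yr) > n) {
      s2 <- svd(Yr, nv = 0)
      Yr <- s2$u %*% diag(s2$d, length(s2$d))
    }
    Q <- qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
    r2p <- vapply(seq_len(n_permutations), function(i) {
      Yp <- Yr[sample.int(n), , drop = FALSE]
      Yp <- scale(Yp, center = TRUE, scale = FALSE)
      sum(crossprod(Q, Yp)^2) / sum(Yp^2)
    }, numeric(1L))
    p_value <- (sum(r2p >= r2) + 1) / (n_permutations + 1)
  }
  structure(list(r_squared = r2, adj_r_squared = adj, p_value = p_value,
                 eig = eig, site_scores = site, species_scores = species,
                 biplot_scores = biplot, n = n, p = ncol(Xm)),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  cat(sprintf("RDA: R2 = %.4f, adj R2 = %.4f (n = %d, p = %d), p = %s\n",
              x$r_squared, x$adj_r_squared, x$n, x$p,
              format(x$p_value, digits = 4)))
  invisible(x)
}

# cbind that tolerates NULL blocks (cbind.data.frame does not)
cbind_blocks <- function(...) {
  blocks <- Filter(Negate(is.null), list(...))
  if (length(blocks)) do.call(cbind, blocks) else NULL
}

#' Variation partitioning between environmental and spatial predictors
#'
#' Decomposes the adjusted R-squared of `Y` into the unique environmental
#' fraction `a`, the shared fraction `b`, the unique spatial fraction `c`
#' and the residual `d`: with `A = adjR2(Y | env)`, `B = adjR2(Y | space)`
#' and `C = adjR2(Y | both)`, `a = C - B`, `c = C - A`, `b = A + B - C`,
#' `d = 1 - C` (so the four sum to 1 exactly).  The unique fractions are
#' tested by partial permutation tests (residuals of the conditioning
#' block are permuted).  `a` and `c` may come out slightly negative --
#' an adjusted-R-squared artifact, reported as-is.
#'
#' @param Y response matrix (samples x species).
#' @param X_env,X_spat predictor blocks (data frame/matrix); either may be
#'   NULL or empty, in which case its fraction is 0.
#' @param n_permutations permutations for the fraction tests (0 skips).
#' @param seed optional integer seed.
#' @return A list of class `vpa_result`: `fractions` (a, b, c, d),
#'   `adj_r2` (env = A, spat = B, both = C), `p_env`, `p_spat`,
#'   `env_variables`, `spat_variables`, `n`.
#' @export
variation_partition <- function(Y, X_env, X_spat, n_permutations = 999,
                                seed = NULL) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  empty <- function(X) is.null(X) || NCOL(X) == 0L
  env_empty <- empty(X_env); spat_empty <- empty(X_spat)
  if (env_empty) message("empty environmental block; fraction a = 0")
  if (spat_empty) message("empty spatial block; fraction c = 0")
  X_env <- if (env_empty) NULL else as.data.frame(X_env)
  X_spat <- if (spat_empty) NULL else as.data.frame(X_spat)
  if (!env_empty && !spat_empty) {
    overlap <- intersect(names(X_env), names(X_spat))
    if (length(overlap))
      stop("predictor blocks share column name(s): ",
           paste(overlap, collapse = ", "))
  }
  Yc <- scale(Y, center = TRUE, scale = FALSE)
  if (ncol(Yc) > n) {            # orthonormal reduction, R2-preserving
    sv <- svd(Yc, nv = 0)
    Yc <- sv$u %*% diag(sv$d, length(sv$d))
  }
  ss_tot <- sum(Yc^2)
  r2_of <- function(X) if (is.null(X)) 0 else
    rda_r2(rda_r2_engine(X), Yc, ss_tot)
  adj_of <- function(X) {
    if (is.null(X)) return(0)
    qrx <- rda_r2_engine(X)
    adjusted_r2(rda_r2(qrx, Yc, ss_tot), n, qrx$rank)
  }
  both <- cbind_blocks(X_env, X_spat)
  A <- adj_of(X_env); B <- adj_of(X_spat); C <- adj_of(both)
  fractions <- c(a = C - B, b = A + B - C, c = C - A, d = 1 - C)

  if (!is.null(seed)) set.seed(seed)
  p_env <- p_spat <- NA_real_
  if (n_permutations > 0) {
    partial_test <- function(X_test, X_cond) {
      if (is.null(X_test)) return(NA_real_)
      qb <- rda_r2_engine(cbind_blocks(X_cond, X_test))
      p_b <- qb$rank
      p_c <- if (is.null(X_cond)) 0L else rda_r2_engine(X_cond)$rank
      r2b <- rda_r2(qb, Yc, ss_tot)
      if (is.null(X_cond)) {
        res <- Yc
        fit_c <- matrix(0, n, ncol(Yc))
        r2c <- 0
      } else {
        qc <- rda_r2_engine(X_cond)
        fit_c <- qr.fitted(qc, Yc)
        res <- Yc - fit_c
        r2c <- sum(fit_c^2) / ss_tot
      }
      df2 <- n - p_b - 1
      f_obs <- ((r2b - r2c) / (p_b - p_c)) / ((1 - r2b) / df2)
      Qb <- qr.Q(qb)[, seq_len(p_b), drop = FALSE]
      f_perm <- vapply(seq_len(n_permutations), function(i) {
        Ystar <- fit_c + res[sample.int(n), , drop = FALSE]
        Ystar <- scale(Ystar, center = TRUE, scale = FALSE)
        sst <- sum(Ystar^2)
        r2bp <- sum(crossprod(Qb, Ystar)^2) / sst
        r2cp <- if (is.null(X_cond)) 0 else sum(qr.fitted(qc, Ystar)^2) / sst
        ((r2bp - r2cp) / (p_b - p_c)) / ((1 - r2bp) / df2)
      }, numeric(1L))
      (sum(f_perm >= f_obs) + 1) / (n_permutations + 1)
    }
    p_env <- partial_test(X_env, X_spat)
    p_spat <- partial_test(X_spat, X_env)
  }
  structure(list(fractions = fractions,
                 adj_r2 = c(env = A, spat = B, both = C),
                 p_env = p_env, p_spat = p_spat,
                 env_variables = if (env_empty) character() else names(X_env),
                 spat_variables = if (spat_empty) character() else names(X_spat),
                 n = n),
            class = "vpa_result")
}

#' @export
print.vpa_result <- function(x, ...) {
  f <- x$fractions
  disp <- pmax(f, 0)  # display convention; JSON/report keep raw values
  cat("variation partitioning (adjusted R2 fractions):\n")
  cat(sprintf("  env only   a = %6.3f (%2.0f%%)  p = %s\n", f["a"],
              100 * disp["a"], format(x$p_env, digits = 3)))
  cat(sprintf("  shared     b = %6.3f (%2.0f%%)\n", f["b"], 100 * disp["b"]))
  cat(sprintf("  space only c = %6.3f (%2.0f%%)  p = %s\n", f["c"],
              100 * disp["c"], format(x$p_spat, digits = 3)))
  cat(sprintf("  residual   d = %6.3f (%2.0f%%)\n", f["d"], 100 * disp["d"]))
  invisible(x)
}
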