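#' Simulate a study-design metadata table
#'
#' Emulates a city-scale soil survey: sites scattered in a bounded
#' lon/lat box, assigned to land-use groups with unequal replicate counts,
#' each group with its own mean level for the six soil variables.  The
#' default design (46 sites, 7 land uses with replicates 8/8/8/8/6/4/4)
#' mirrors a typical multi-land-use urban sampling campaign.
#'
#' @param n_samples number of sites.
#' @param n_landuse number of land-use groups (must not exceed `n_samples`).
#' @param seed optional integer seed for reproducibility.
#' @param bbox numeric `c(lon_min, lon_max, lat_min, lat_max)` sampling box;
#'   the default spans roughly a 50 x 35 km urban area.
#' @return A metadata data frame (see [read_metadata()] for the columns).
#' @export
simulate_metadata <- function(n_samples = 46, n_landuse = 7, seed = NULL,
                              bbox = c(121.4, 121.9, 29.65, 29.95)) {
  if (n_landuse > n_samples)
    stop("'n_landuse' must not exceed 'n_samples'")
  if (!is.null(seed)) set.seed(seed)
  land_pool <- c("farmland", "forest", "greenbelt", "hospital", "industrial",
                 "park", "residential")
  labels <- if (n_landuse <= length(land_pool)) land_pool[seq_len(n_landuse)]
            else paste0("landuse", seq_len(n_landuse))
  if (n_samples == 46 && n_landuse == 7) {
    reps <- c(8L, 8L, 8L, 8L, 6L, 4L, 4L)   # unequal replicate design
  } else {
    reps <- rep(n_samples %/% n_landuse, n_landuse)
    extra <- n_samples - sum(reps)
    if (extra > 0) reps[seq_len(extra)] <- reps[seq_len(extra)] + 1L
  }
  land_use <- rep(labels, reps)

  lon <- stats::runif(n_samples, bbox[1L], bbox[2L])
  lat <- stats::runif(n_samples, bbox[3L], bbox[4L])

  # group means drawn once, within field-realistic ranges; per-site noise on top
  grp <- function(lo, hi, sd_frac = 0.12) {
    mu <- stats::runif(n_landuse, lo, hi)[match(land_use, labels)]
    pmax(mu + stats::rnorm(n_samples, 0, sd_frac * (hi - lo)), lo * 0.5)
  }
  moisture <- grp(10, 40)        # gravimetric %
  pH <- grp(5, 8.5, 0.08)
  TC <- grp(10, 60)              # g/kg
  TN <- grp(1, 4)                # g/kg
  TP <- grp(0.3, 1.5)            # g/kg
  CN <- TC / TN

  data.frame(sample_id = sprintf("S%02d", seq_len(n_samples)),
             land_use = land_use, lon = lon, lat = lat,
             moisture = moisture, pH = pH, TP = TP, TC = TC, TN = TN, CN = CN,
             stringsAsFactors = FALSE)
}

# Lognormal rank-abundance metacommunity normalized to the simplex.
lognormal_metacommunity <- function(n_otus, sigma = 2) {
  a <- stats::rlnorm(n_otus, meanlog = 0, sdlog = sigma)
  a / sum(a)
}

# Integerize a local composition y (summing to 1) into depth reads while
# preserving the one-individual detection limit: an OTU receives reads iff
# y >= 1/depth.  floor(depth * y) first, then the remaining reads go to
# already-detected OTUs, largest fractional parts first (cycling if the
# remainder exceeds the number of detected OTUs).
census_allocate <- function(y, depth) {
  nf <- floor(depth * y)
  det <- which(nf >= 1)
  if (!length(det)) {
    det <- which.max(y)
    nf[det] <- 1
  }
  rem <- depth - sum(nf)
  if (rem > 0) {
    frac <- (depth * y - nf)[det]
    idx <- det[order(frac, decreasing = TRUE)]
    add <- rep(rem %/% length(det), length(det))
    extra <- rem %% length(det)
    if (extra > 0) add[seq_len(extra)] <- add[seq_len(extra)] + 1
    nf[idx] <- nf[idx] + add
  }
  as.integer(nf)
}

#' Simulate a neutrally assembled OTU table
#'
#' Sampling form of Sloan's neutral community model: each sample is a local
#' community of `depth` individuals connected to a common metacommunity
#' (relative abundances `p`) by immigration rate `m`.  The stationary local
#' relative abundance of OTU i is `Beta(depth*m*p_i, depth*m*(1-p_i))`; one
#' draw per OTU per sample is normalized to a composition and integerized so
#' that an OTU is present exactly when its local relative abundance reaches
#' the one-read detection limit `1/depth`.  This keeps the generator's
#' occupancy-abundance relation on the Sloan curve for the generating
#' `Nm = depth * m`, which is what makes parameter-recovery tests of
#' [fit_ncm()] meaningful.
#'
#' @param n_samples,n_otus community dimensions.
#' @param depth reads (individuals) per sample, `N` in the model.
#' @param m immigration probability in (0, 1].
#' @param meta_abund optional metacommunity relative abundances (length
#'   `n_otus`, summing to 1); default a lognormal rank-abundance distribution.
#' @param sigma_meta lognormal sd (log scale) of the default metacommunity.
#' @param seed optional integer seed.
#' @return An [otu_table()]; every sample sums exactly to `depth`.  The
#'   generating parameters are attached as attribute `"sim"`.
#' @examples
#' tab <- simulate_neutral(n_samples = 10, n_otus = 200, depth = 1000,
#'                         m = 0.2, seed = 1)
#' rowSums(otu_counts(tab))
#' @export
simulate_neutral <- function(n_samples = 46, n_otus = 5000, depth = 10000,
                             m = 0.1, meta_abund = NULL, sigma_meta = 2,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (depth < 1) stop("'depth' must be >= 1")
  if (m <= 0 || m > 1) stop("'m' must be in (0, 1]")
  if (is.null(meta_abund)) {
    p <- lognormal_metacommunity(n_otus, sigma_meta)
  } else {
    if (length(meta_abund) != n_otus)
      stop("'meta_abund' must have length n_otus")
    if (all(meta_abund == 0)) stop("metacommunity abundances are all zero")
    if (abs(sum(meta_abund) - 1) > 1e-9)
      stop("'meta_abund' must sum to 1")
    p <- meta_abund
  }
  Nm <- depth * m
  if (!is.finite(Nm * max(p)))
    stop("beta parameters overflow; use a smaller depth * m")
  cnt <- matrix(0L, n_samples, n_otus,
                dimnames = list(sprintf("S%02d", seq_len(n_samples)),
                                sprintf("OTU%05d", seq_len(n_otus))))
  for (j in seq_len(n_samples)) {
    x <- stats::rbeta(n_otus, Nm * p, Nm * (1 - p))
    x <- pmin(pmax(x, 1e-12), 1 - 1e-12)  # numeric safety at the boundaries
    cnt[j, ] <- census_allocate(x / sum(x), depth)
  }
  out <- otu_table(cnt)
  attr(out, "sim") <- list(model = "neutral", n_samples = n_samples,
                           n_otus = n_otus, depth = depth, m = m,
                           Nm = Nm, sigma_meta = sigma_meta, seed = seed)
  out
}

# Spatially autocorrelated standard-normal field over site coordinates
# (exponential-kernel Gaussian process; range on normalized coordinates).
gp_field <- function(lon, lat, range = 0.3, nugget = 1e-6) {
  xy <- cbind((lon - min(lon)) / max(diff(range(lon)), 1e-12),
              (lat - min(lat)) / max(diff(range(lat)), 1e-12))
  K <- exp(-as.matrix(stats::dist(xy)) / range)
  diag(K) <- 1 + nugget
  L <- chol(K)
  z <- drop(crossprod(L, stats::rnorm(length(lon))))
  as.numeric(scale(z))
}

#' Simulate a niche-structured OTU table with matching metadata
#'
#' Environmental-filtering counterpart of [simulate_neutral()]: each OTU has
#' a Gaussian response along `n_gradients` environmental gradients
#' (optimum per gradient, common niche breadth).  Gradients are spatially
#' autocorrelated fields over the site coordinates (or z-scores of measured
#' soil variables when `metadata` is supplied), so that environment and
#' space are collinear in the way variation partitioning has to
#' disentangle.  Expected abundances get lognormal noise and are converted
#' to counts by multinomial draws of `depth` reads.
#'
#' @param n_samples,n_otus,depth community dimensions and reads per sample.
#' @param n_gradients number of environmental gradients (at most 6, one per
#'   soil metadata slot).
#' @param niche_breadth Gaussian niche breadth (sd on the z-scored gradient);
#'   small values mean strong filtering, large values approach neutrality of
#'   composition with respect to the environment.
#' @param noise_sd lognormal abundance noise (log scale).
#' @param sar_range spatial autocorrelation range of the gradient fields (on
#'   coordinates normalized to the unit square).
#' @param metadata optional metadata frame whose first `n_gradients` soil
#'   variables act as the gradients; by default a fresh design is simulated
#'   with [simulate_metadata()] and its gradient fields are written into the
#'   soil-variable columns.
#' @param n_landuse land-use groups for the simulated design.
#' @param seed optional integer seed.
#' @return `list(table =, meta =)`.
#' @export
simulate_niche <- function(n_samples = 46, n_otus = 2000, depth = 10000,
                           n_gradients = 2, niche_breadth = 0.5,
                           noise_sd = 0.3, sar_range = 0.3,
                           metadata = NULL, n_landuse = 7, seed = NULL) {
  if (n_gradients > length(env_variables))
    stop("'n_gradients' must be at most ", length(env_variables),
         " (one per soil metadata slot)")
  if (niche_breadth <= 0) stop("'niche_breadth' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  supplied_meta <- !is.null(metadata)
  if (!supplied_meta)
    metadata <- simulate_metadata(n_samples, n_landuse)
  else
    metadata <- validate_metadata(metadata)
  n_samples <- nrow(metadata)

  if (supplied_meta) {
    grad <- scale(as.matrix(metadata[, env_variables[seq_len(n_gradients)],
                                     drop = FALSE]))
  } else {
    grad <- sapply(seq_len(n_gradients), function(g)
      gp_field(metadata$lon, metadata$lat, range = sar_range))
    grad <- matrix(grad, nrow = n_samples)
    # write the generating gradients into the soil-variable slots so the
    # metadata used downstream carries the true drivers
    scales <- list(moisture = c(25, 8), pH = c(6.8, 1), TP = c(0.9, 0.3),
                   TC = c(35, 12), TN = c(2.5, 0.8), CN = c(14, 3))
    for (g in seq_len(n_gradients)) {
      v <- env_variables[g]
      metadata[[v]] <- scales[[v]][1L] + scales[[v]][2L] * grad[, g]
    }
  }

  optima <- matrix(stats::runif(n_otus * n_gradients, -2, 2), n_otus)
  base <- stats::rlnorm(n_otus, 0, 1)
  cnt <- matrix(0L, n_samples, n_otus,
                dimnames = list(metadata$sample_id,
                                sprintf("OTU%05d", seq_len(n_otus))))
  for (j in seq_len(n_samples)) {
    logw <- log(base) -
      colSums((t(optima) - grad[j, ])^2) / (2 * niche_breadth^2) +
      stats::rnorm(n_otus, 0, noise_sd)
    w <- exp(logw - max(logw))
    cnt[j, ] <- as.integer(stats::rmultinom(1L, depth, w))
  }
  tab <- otu_table(cnt)
  attr(tab, "sim") <- list(model = "niche", n_samples = n_samples,
                           n_otus = n_otus, depth = depth,
                           n_gradients = n_gradients,
                           niche_breadth = niche_breadth,
                           noise_sd = noise_sd, sar_range = sar_range,
                           seed = seed)
  list(table = tab, meta = metadata)
}
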