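test_that("Bray-Curtis matches hand computation and its boundary cases", {
  m <- rbind(S1 = c(1L, 1L), S2 = c(1L, 0L), S3 = c(1L, 1L),
             S4 = c(0L, 2L))
  colnames(m) <- c("A", "B")
  d <- as.matrix(bray_curtis(otu_table(m), on = "counts"))
  expect_equal(d["S1", "S2"], 1 / 3)
  expect_equal(d["S1", "S3"], 0)            # identical samples
  expect_equal(d["S2", "S4"], 1)            # disjoint OTU sets
  expect_equal(diag(d), setNames(rep(0, 4), rownames(m)))
  expect_equal(d, t(d))
})

test_that("Bray-Curtis on proportions is invariant to sequencing depth", {
  m <- make_counts(5, 30, seed = 8, lambda = 6)
  m2 <- m; m2[3L, ] <- m2[3L, ] * 5L
  expect_equal(as.vector(bray_curtis(otu_table(m))),
               as.vector(bray_curtis(otu_table(m2))), tolerance = 1e-12)
})

test_that("environmental distance z-scores variables before Euclidean distance", {
  meta <- simulate_metadata(12, 3, seed = 10)
  d <- environmental_distance(meta)
  # unit change leaves distances untouched
  meta2 <- meta; meta2$TC <- meta2$TC * 1000
  expect_equal(as.vector(environmental_distance(meta2)), as.vector(d),
               tolerance = 1e-12)
  # identical env rows at distance zero
  env_cols <- c("moisture", "pH", "TP", "TC", "TN", "CN")
  meta3 <- meta; meta3[2, env_cols] <- meta3[1, env_cols]
  expect_equal(as.matrix(environmental_distance(meta3))[1, 2], 0,
               tolerance = 1e-12)
  # hand case: one variable, two values 0 and 2; sample sd sqrt(2)
  m2s <- meta[1:2, ]; m2s$pH <- c(0, 2)
  expect_equal(as.vector(environmental_distance(m2s, "pH")), 2 / sqrt(2),
               tolerance = 1e-12)
  const <- meta; const$pH <- 7
  expect_error(environmental_distance(const), "pH")
})

test_that("Mantel identity gives r = 1 and the minimal p-value", {
  meta <- simulate_metadata(15, 3, seed = 2)
  d <- environmental_distance(meta)
  for (method in c("spearman", "pearson")) {
    res <- mantel_test(d, d, method = method, n_permutations = 99, seed = 1)
    expect_equal(res$r, 1, tolerance = 1e-12)
    expect_equal(res$p_value, 1 / 100)
  }
  # Spearman is invariant to monotone transforms
  dexp <- as.dist(exp(as.matrix(d)))
  expect_equal(mantel_test(d, dexp, method = "spearman",
                           n_permutations = 99, seed = 1)$r, 1,
               tolerance = 1e-12)
  expect_error(mantel_test(d, dist(matrix(rnorm(10), 5))), "sizes")
})

test_that("ANOSIM separates perfectly separated groups and validates input", {
  # two tight clusters far apart: all within < all between
  x <- rbind(matrix(rnorm(10, 0, 0.01), 5), matrix(rnorm(10, 10, 0.01), 5))
  d <- dist(x)
  g <- rep(c("a", "b"), each = 5)
  res <- anosim_test(d, g, n_permutations = 99, seed = 1)
  expect_equal(res$R, 1, tolerance = 1e-12)
  expect_lte(res$p_value, 0.05)
  expect_error(anosim_test(d, rep(c("a", "b", "c"), c(5, 4, 1))), "size 1")
  expect_error(anosim_test(d, rep("a", 10)), "2 groups")
})

test_that("ANOSIM R is centered at zero for structureless data", {
  set.seed(99)
  g <- rep(c("a", "b", "c", "d"), each = 5)
  rs <- replicate(100, {
    d <- dist(matrix(rnorm(20 * 4), 20))
    anosim_test(d, g, n_permutations = 19)$R
  })
  expect_lt(abs(mean(rs)), 0.05)
})

test_that("distance-decay regression recovers an exact linear relation", {
  meta <- simulate_metadata(10, 2, seed = 6)
  ed <- environmental_distance(meta)
  # community dissimilarity constructed so similarity = 1 - 0.3 * distance
  comm <- as.dist(0.3 * as.matrix(ed))
  fit <- suppressWarnings(   # lm flags the deliberately perfect fit
    distance_decay_fit(comm, ed, n_permutations = 99, seed = 1))
  expect_equal(fit$slope, -0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 1, tolerance = 1e-10)
  expect_equal(fit$mantel$r, 1, tolerance = 1e-10)
  expect_error(distance_decay_fit(dist(matrix(0, 2, 2)), dist(matrix(0, 2, 2))),
               "3 sites")
})

test_that("strong environmental filtering yields a decaying, significant relation", {
  sim <- simulate_niche(n_samples = 30, n_otus = 400, depth = 3000,
                        niche_breadth = 0.3, noise_sd = 0.1, seed = 14)
  bc <- bray_curtis(sim$table)
  ed <- environmental_distance(sim$meta)
  fit <- distance_decay_fit(bc, ed, n_permutations = 999, seed = 2)
  expect_lt(fit$slope, 0)
  expect_lte(fit$mantel$p_value, 0.001)
})
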