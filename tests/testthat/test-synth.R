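test_that("simulators are deterministic under a fixed seed", {
  a <- simulate_neutral(10, 200, 1000, 0.2, seed = 5)
  b <- simulate_neutral(10, 200, 1000, 0.2, seed = 5)
  expect_identical(otu_counts(a), otu_counts(b))
  n1 <- simulate_niche(n_samples = 12, n_otus = 100, depth = 800, seed = 9)
  n2 <- simulate_niche(n_samples = 12, n_otus = 100, depth = 800, seed = 9)
  expect_identical(otu_counts(n1$table), otu_counts(n2$table))
  expect_identical(n1$meta, n2$meta)
  m1 <- simulate_metadata(20, 4, seed = 3)
  m2 <- simulate_metadata(20, 4, seed = 3)
  expect_identical(m1, m2)
})

test_that("every simulated sample sums exactly to the requested depth", {
  tab <- simulate_neutral(15, 300, 2751, 0.05, seed = 2)
  expect_true(all(rowSums(otu_counts(tab)) == 2751))
  sim <- simulate_niche(n_samples = 10, n_otus = 150, depth = 1234, seed = 2)
  expect_true(all(rowSums(otu_counts(sim$table)) == 1234))
})

test_that("the metadata generator reproduces the survey design", {
  meta <- simulate_metadata(46, 7, seed = 8)
  expect_equal(nrow(meta), 46)
  expect_equal(sort(as.integer(table(meta$land_use))),
               sort(c(8L, 8L, 8L, 8L, 6L, 4L, 4L)))
  expect_silent(validate_metadata(meta))
  one <- simulate_metadata(10, 1, seed = 8)
  expect_equal(length(unique(one$land_use)), 1)
  expect_error(simulate_metadata(5, 7), "n_landuse")
})

test_that("with full immigration the mean relative abundance tracks the metacommunity", {
  set.seed(4)
  p <- lognormal_metacommunity <- local({
    a <- exp(rnorm(50, 0, 1)); a / sum(a)
  })
  tab <- simulate_neutral(n_samples = 400, n_otus = 50, depth = 20000,
                          m = 1, meta_abund = p, seed = 4)
  ra <- relative_abundance(tab)
  for (i in which(p > 0.01)) {
    se <- sd(ra[, i]) / sqrt(nrow(ra))
    expect_lt(abs(mean(ra[, i]) - p[i]), 3 * se + 1e-4)
  }
})

test_that("neutral occupancy falls on the Sloan curve of the generating Nm", {
  N <- 10000; m <- 0.1
  tab <- simulate_neutral(n_samples = 46, n_otus = 2000, depth = N, m = m,
                          seed = 6)
  st <- occurrence_stats(tab)
  f_hat <- sloan_expected_frequency(st$p, N * m, 1 / N)
  r2 <- 1 - sum((st$f_obs - f_hat)^2) / sum((st$f_obs - mean(st$f_obs))^2)
  expect_gte(r2, 0.9)
})

test_that("niche strength controls the community-environment association", {
  weak <- simulate_niche(n_samples = 46, n_otus = 300, depth = 3000,
                         niche_breadth = 50, noise_sd = 0.3, seed = 11)
  r_weak <- mantel_test(bray_curtis(weak$table),
                        environmental_distance(weak$meta),
                        n_permutations = 99, seed = 1)
  expect_lt(abs(r_weak$r), 0.1)

  strong <- simulate_niche(n_samples = 46, n_otus = 300, depth = 3000,
                           niche_breadth = 0.3, noise_sd = 0.3, seed = 11)
  r_strong <- mantel_test(bray_curtis(strong$table),
                          environmental_distance(strong$meta),
                          n_permutations = 999, seed = 1)
  expect_gt(r_strong$r, 0.3)
  expect_lte(r_strong$p_value, 0.001)
  expect_error(simulate_niche(n_gradients = 7), "at most 6")
})

test_that("strong filtering puts the largest explained fraction on the environment", {
  # gradients taken from measured (spatially unstructured) soil variables,
  # as in the survey design, so the PCNM basis cannot absorb them
  meta <- simulate_metadata(46, 7, seed = 21)
  sim <- simulate_niche(n_otus = 300, depth = 3000, niche_breadth = 0.3,
                        noise_sd = 0.2, metadata = meta, seed = 21)
  Y <- hellinger(sim$table)
  pb <- pcnm_vectors(sim$meta)
  vp <- variation_partition(Y, sim$meta[, c("moisture", "pH")],
                            as.data.frame(pb$vectors), n_permutations = 0)
  f <- vp$fractions
  expect_gt(f[["a"]], f[["c"]])
  expect_equal(which.max(f[c("a", "b", "c")]), c(a = 1L))
})
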