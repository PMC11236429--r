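test_that("Hellinger transform matches hand values with unit row sums of squares", {
  m <- rbind(S1 = c(4L, 0L), S2 = c(1L, 1L))
  colnames(m) <- c("A", "B")
  h <- hellinger(otu_table(m))
  expect_equal(unname(h["S1", ]), c(1, 0))
  expect_equal(unname(h["S2", ]), c(sqrt(0.5), sqrt(0.5)))
  expect_equal(unname(rowSums(h^2)), c(1, 1), tolerance = 1e-12)
  one <- matrix(c(3L, 7L), 2, 1, dimnames = list(c("S1", "S2"), "A"))
  expect_equal(unname(hellinger(otu_table(one))[, 1]), c(1, 1))
})

test_that("Ezekiel adjustment matches its formula and edge cases", {
  expect_equal(adjusted_r2(0.5, 46, 3), 1 - 0.5 * 45 / 42)  # 0.46428...
  expect_equal(adjusted_r2(0.7, 46, 0), 0.7)
  expect_equal(adjusted_r2(1, 46, 5), 1)
  expect_error(adjusted_r2(0.5, 5, 4), "n > p")
})

test_that("RDA recovers exact fits, rejects collinearity, matches brute force", {
  set.seed(21)
  n <- 25
  X <- as.data.frame(matrix(rnorm(n * 3), n, dimnames = list(NULL, c("a", "b", "c"))))
  B <- matrix(rnorm(3 * 6), 3)
  Yexact <- as.matrix(X) %*% B
  fit <- rda_fit(Yexact, X, n_permutations = 0)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  # orthogonal predictors explain nothing
  Y <- matrix(rnorm(n * 6), n)
  Yc <- scale(Y, scale = FALSE)
  Xc <- scale(as.matrix(X), scale = FALSE)
  Yorth <- Yc - Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc))
  expect_lt(rda_fit(Yorth, X, n_permutations = 0)$r_squared, 1e-9)

  # brute-force projection oracle
  r2_brute <- sum((Xc %*% solve(crossprod(Xc), crossprod(Xc, Yc)))^2) / sum(Yc^2)
  expect_equal(rda_fit(Y, X, n_permutations = 0)$r_squared, r2_brute,
               tolerance = 1e-10)

  # independent implementation: vegan's rda on the same data
  vfit <- vegan::rda(Y ~ a + b + c, data = X)
  expect_equal(rda_fit(Y, X, n_permutations = 0)$r_squared,
               unname(vegan::RsquareAdj(vfit)$r.squared), tolerance = 1e-9)
  expect_equal(rda_fit(Y, X, n_permutations = 0)$adj_r_squared,
               unname(vegan::RsquareAdj(vfit)$adj.r.squared), tolerance = 1e-9)

  Xbad <- cbind(X, d = X$a + X$b)
  expect_error(rda_fit(Y, Xbad, n_permutations = 0), "collinear")
})

test_that("RDA R2 is invariant to invertible reparameterization of X", {
  set.seed(31)
  n <- 30
  X <- matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("x", 1:4)))
  Y <- matrix(rnorm(n * 8), n)
  A <- matrix(rnorm(16), 4); while (abs(det(A)) < 0.1) A <- matrix(rnorm(16), 4)
  XA <- X %*% A; colnames(XA) <- paste0("z", 1:4)
  expect_equal(rda_fit(Y, X, n_permutations = 0)$r_squared,
               rda_fit(Y, XA, n_permutations = 0)$r_squared, tolerance = 1e-9)
})

test_that("variation partitioning fractions obey the adjusted-R2 algebra", {
  set.seed(41)
  n <- 40
  Xe <- as.data.frame(matrix(rnorm(n * 3), n, dimnames = list(NULL, paste0("e", 1:3))))
  Xs <- as.data.frame(matrix(rnorm(n * 4), n, dimnames = list(NULL, paste0("s", 1:4))))
  Y <- as.matrix(Xe) %*% matrix(rnorm(3 * 10), 3) + matrix(rnorm(n * 10), n)

  vp <- variation_partition(Y, Xe, Xs, n_permutations = 99, seed = 1)
  f <- vp$fractions
  expect_equal(sum(f), 1, tolerance = 1e-9)
  expect_equal(unname(f["a"] + f["b"]), unname(vp$adj_r2["env"]), tolerance = 1e-12)
  expect_equal(unname(f["b"] + f["c"]), unname(vp$adj_r2["spat"]), tolerance = 1e-12)

  # swapping the blocks swaps a and c exactly
  vp2 <- variation_partition(Y, Xs, Xe, n_permutations = 0)
  expect_equal(unname(vp2$fractions["a"]), unname(f["c"]), tolerance = 1e-12)
  expect_equal(unname(vp2$fractions["c"]), unname(f["a"]), tolerance = 1e-12)
  expect_equal(unname(vp2$fractions["b"]), unname(f["b"]), tolerance = 1e-12)

  # identical information in both blocks: no unique fractions
  Xdup <- setNames(Xe, paste0("d", 1:3))
  vp3 <- variation_partition(Y, Xe, Xdup, n_permutations = 0)
  expect_equal(unname(vp3$fractions["a"]), 0, tolerance = 1e-9)
  expect_equal(unname(vp3$fractions["c"]), 0, tolerance = 1e-9)
  expect_equal(unname(vp3$fractions["b"]), unname(vp$adj_r2["env"]),
               tolerance = 1e-9)

  # independent implementation: vegan::varpart adjusted fractions
  # (indfract rows are ordered unique-1, unique-2, shared, residual)
  vv <- vegan::varpart(Y, Xe, Xs)
  ind <- vv$part$indfract$Adj.R.square
  expect_equal(unname(f[c("a", "c", "b", "d")]), ind, tolerance = 1e-9)

  expect_error(variation_partition(Y, Xe, setNames(Xs, c("e1", "s2", "s3", "s4"))),
               "share column")
})

test_that("empty predictor blocks yield zero unique fractions", {
  set.seed(51)
  n <- 20
  Xe <- as.data.frame(matrix(rnorm(n * 2), n, dimnames = list(NULL, c("e1", "e2"))))
  Y <- matrix(rnorm(n * 5), n)
  expect_message(vp <- variation_partition(Y, Xe, NULL, n_permutations = 0),
                 "empty spatial")
  expect_equal(unname(vp$fractions["c"]), 0)
  expect_equal(sum(vp$fractions), 1, tolerance = 1e-9)
})

test_that("an environment-driven community leaves nothing unique to space", {
  set.seed(61)
  cs <- replicate(30, {
    n <- 46
    Xe <- as.data.frame(matrix(rnorm(n * 3), n,
                               dimnames = list(NULL, paste0("e", 1:3))))
    Xs <- as.data.frame(matrix(rnorm(n * 5), n,
                               dimnames = list(NULL, paste0("s", 1:5))))
    Y <- as.matrix(Xe) %*% matrix(rnorm(3 * 12), 3) +
      matrix(rnorm(n * 12, 0, 0.8), n)
    variation_partition(Y, Xe, Xs, n_permutations = 0)$fractions["c"]
  })
  expect_lte(median(cs), 0.02)
})
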