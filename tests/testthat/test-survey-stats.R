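test_that("incomplete columns are dropped, complete ones kept", {
  m <- cbind(a = c(1, 2, 3), b = c(1, NA, 3), c = c(4, 5, 6))
  expect_message(d <- drop_incomplete(m), "b")
  expect_equal(colnames(d), c("a", "c"))
  full <- cbind(a = 1:3, b = 4:6)
  expect_equal(drop_incomplete(full), full)
  expect_error(drop_incomplete(cbind(a = c(NA, 1))), "no complete")
})

test_that("feature scaling centres and standardizes every column", {
  set.seed(42)
  m <- matrix(rnorm(60, mean = 5, sd = 3), 12, 5,
              dimnames = list(NULL, letters[1:5]))
  s <- scale_features(m)
  expect_true(all(abs(colMeans(s)) < 1e-9))
  expect_true(all(abs(apply(s, 2, sd) - 1) < 1e-9))
  expect_warning(scale_features(cbind(a = rnorm(5), b = rep(1, 5))),
                 "zero-variance")
})

test_that("Ward clustering matches the brute-force minimum-variance oracle", {
  set.seed(7)
  for (rep in 1:5) {
    x <- matrix(rnorm(40), 8, 5)
    got <- ward_cluster(x)
    want <- ward_oracle(x)
    expect_identical(got$merge, want$merge)
    expect_equal(got$height, want$height, tolerance = 1e-9)
    # cross-check heights against the reference implementation
    hc <- stats::hclust(dist(x), method = "ward.D2")
    expect_equal(sort(got$height), sort(hc$height), tolerance = 1e-9)
  }
})

test_that("Ward dendrogram is monotone and handles degenerate geometry", {
  set.seed(11)
  x <- matrix(rnorm(60), 12, 5)
  h <- ward_cluster(x)$height
  expect_true(all(diff(h) >= -1e-12))
  # two identical rows merge first at height 0
  xx <- rbind(c(0, 0), c(0, 0), c(5, 5))
  w <- ward_cluster(xx)
  expect_equal(w$merge[1, ], c(-2L, -1L))
  expect_equal(w$height[1], 0)
  # three collinear points: the close pair merges first
  x3 <- cbind(c(0, 1, 10))
  expect_equal(ward_cluster(x3)$merge[1, ], c(-2L, -1L))
  expect_error(ward_cluster(matrix("a", 2, 2)), "numeric")
})

test_that("PCA explains (1+|r|)/2 for bivariate data and reconstructs exactly", {
  set.seed(3)
  x <- rnorm(50)
  y <- 0.6 * x + sqrt(1 - 0.36) * rnorm(50)
  m <- cbind(x = x, y = y)
  r <- cor(m[, 1], m[, 2])
  p <- pca_survey(m)
  expect_equal(p$explained[1], (1 + abs(r)) / 2, tolerance = 1e-9)
  expect_equal(sum(p$explained), 1, tolerance = 1e-9)
  # loadings orthonormal
  expect_equal(crossprod(p$loadings), diag(ncol(p$loadings)),
               tolerance = 1e-9, ignore_attr = TRUE)
  # full-rank reconstruction reproduces the scaled matrix
  m5 <- matrix(rnorm(50), 10, 5)
  p5 <- pca_survey(m5)
  expect_equal(p5$scores %*% t(p5$loadings),
               scale_features(m5), tolerance = 1e-9, ignore_attr = TRUE)
  # sign convention: the largest-magnitude loading is positive
  expect_true(all(apply(p5$loadings, 2,
                        function(v) v[which.max(abs(v))] > 0)))
  # row-duplicated data give identical loadings
  pd <- pca_survey(rbind(m5, m5))
  expect_equal(abs(pd$loadings), abs(p5$loadings), tolerance = 1e-9)
})

test_that("PCA truncates rank-deficient input with a warning", {
  m <- cbind(a = rnorm(6), b = rnorm(6))
  m <- cbind(m, c = m[, "a"] + m[, "b"])
  expect_warning(p <- pca_survey(m), "rank-deficient")
  expect_equal(ncol(p$loadings), 2)
})

test_that("Pearson scan matches definitional sums and is affine-invariant", {
  x <- c(1, 2, 4, 7, 11)
  y <- c(2, 1, 5, 8, 9)
  m <- cbind(x = x, y = y)
  res <- pearson_scan(m)
  r_def <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_def, tolerance = 1e-12)
  tt <- r_def * sqrt(3) / sqrt(1 - r_def^2)
  expect_equal(res$p, 2 * pt(-abs(tt), df = 3), tolerance = 1e-12)
  # perfect linear pairs
  expect_equal(pearson_scan(cbind(a = x, b = 2 * x + 1))$r, 1)
  expect_equal(pearson_scan(cbind(a = x, b = -x))$r, -1)
  # symmetry and affine invariance
  res_sym <- pearson_scan(cbind(y = y, x = x))
  expect_equal(res_sym$r, res$r)
  res_aff <- pearson_scan(cbind(x = 3 * x - 2, y = 0.5 * y + 7))
  expect_equal(res_aff$r, res$r, tolerance = 1e-12)
  # zero variance -> missing
  z <- pearson_scan(cbind(a = x, b = rep(1, 5)))
  expect_true(is.na(z$r))
})

test_that("enzyme activities normalize to the per-enzyme maximum", {
  expect_equal(normalize_enzyme_activity(c(2, 4, 8)), c(0.25, 0.5, 1))
  expect_equal(normalize_enzyme_activity(5), 1)
  set.seed(9)
  v <- runif(10)
  out <- normalize_enzyme_activity(v)
  expect_equal(max(out), 1)
  expect_true(all(out >= 0 & out <= 1))
  expect_error(normalize_enzyme_activity(c(0, 0)), "zero")
})
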