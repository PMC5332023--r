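test_that("correlation PCA obeys its algebraic invariants", {
  set.seed(13)
  x <- matrix(rnorm(60 * 5), 60, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  pca <- correlationPca(x)
  expect_equal(sum(pca@eigenvalues), 5, tolerance = 1e-10)
  expect_equal(sum(pca@percentVariance), 100, tolerance = 1e-8)
  # reconstruction: loadings %*% diag(ev) %*% t(loadings) == correlation
  rec <- pca@loadings %*% diag(pca@eigenvalues) %*% t(pca@loadings)
  expect_equal(rec, stats::cor(x), tolerance = 1e-8, ignore_attr = TRUE)
  # orthonormal loading columns
  expect_equal(t(pca@loadings) %*% pca@loadings, diag(5),
               tolerance = 1e-10, ignore_attr = TRUE)
  # sign convention: largest-magnitude entry of each column is positive
  for (k in 1:5) expect_gt(pca@loadings[which.max(abs(pca@loadings[, k])), k], 0)
})

test_that("collinear variables concentrate variance as predicted", {
  set.seed(14)
  base <- rnorm(500)
  x <- cbind(a = base, b = base, c = rnorm(500), d = rnorm(500), e = rnorm(500))
  pca <- correlationPca(x)
  # two perfectly collinear + three independent columns: leading eigenvalue 2
  expect_equal(pca@eigenvalues[1], 2, tolerance = 0.15)
  expect_error(correlationPca(cbind(x, f = rep(1, 500))), "f")
  expect_error(correlationPca(x[1:2, ]), "at least 3 rows")
})

test_that("eigenvalue retention matches the eigenvalue > 1 rule", {
  set.seed(15)
  x <- matrix(rnorm(40 * 5), 40, 5)
  pca <- correlationPca(x)
  expect_identical(pca@retained, sum(pca@eigenvalues > 1))
  expect_identical(ncol(pca@scores), as.integer(pca@retained))
  # the published leading eigenvalue of the 5-variable call PCA implies
  # its printed share of variance under the correlation convention
  expect_equal(percentVariance(2.59, nVariables = 5), 51.8)
})

test_that("Welch tests from summaries reproduce published and closed-form anchors", {
  # published body-size contrast: clade I males vs clade C males
  wt <- welchFromSummary(26.0, 0.9, 8, 23.8, 1.5, 185)
  expect_equal(wt$t, 6.52, tolerance = 0.05 / 6.52)
  expect_identical(wt$dfRounded, 9)
  expect_lt(wt$p, 0.001)
  same <- welchFromSummary(5, 1, 10, 5, 1, 10)
  expect_identical(same$t, 0)
  expect_identical(same$p, 1)
  hand <- welchFromSummary(1, 1, 2, 0, 1, 2)
  expect_equal(hand$t, 1)
  expect_equal(hand$df, 2)
  expect_error(welchFromSummary(1, 1, 1, 0, 1, 5), "n >= 2")
  expect_error(welchFromSummary(1, 0, 5, 0, 0, 5), "not both zero")
})

test_that("summary-based Welch equals the raw-sample t-test", {
  set.seed(16)
  for (rep in 1:20) {
    x <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    y <- rnorm(sample(5:30, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    ours <- welchFromSummary(mean(x), sd(x), length(x),
                             mean(y), sd(y), length(y))
    ref <- stats::t.test(x, y)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$df, unname(ref$parameter), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("group tests on PC scores detect large offsets and skip tiny groups", {
  set.seed(17)
  n <- 10
  x <- matrix(rnorm(2 * n * 5), 2 * n, 5)
  x[1:n, 1:3] <- x[1:n, 1:3] + 5   # shift half the rows on correlated axes
  groups <- rep(c("g1", "g2"), each = n)
  pca <- correlationPca(x)
  tab <- pcGroupTests(pca, groups)
  expect_true(any(tab$p < 0.001))
  solo <- correlationPca(matrix(rnorm(50), 10, 5))
  expect_identical(nrow(pcGroupTests(solo, rep("only", 10))), 0L)
  expect_warning(pcGroupTests(solo, c(rep("a", 9), "b")), "skipped")
})

test_that("group summaries report n, mean, sample SD and range", {
  gs <- summarizeGroups(c(1, 2, 3), rep("C", 3))
  expect_equal(gs[, c("n", "mean", "sd", "min", "max")],
               data.frame(n = 3L, mean = 2, sd = 1, min = 1, max = 3),
               ignore_attr = TRUE)
  one <- summarizeGroups(5, "X")
  expect_true(is.na(one$sd))
  svl <- sampleSvl(23.8, 1.5, 185, seed = 18)
  gs2 <- summarizeGroups(svl, rep("C", 185))
  expect_lt(abs(gs2$mean - 23.8), 3 * 1.5 / sqrt(185))
  expect_warning(summarizeGroups(c(1, NA), c("a", "b")), "omitted")
  expect_error(summarizeGroups(1:3, c("a", "b")), "labeled")
})
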