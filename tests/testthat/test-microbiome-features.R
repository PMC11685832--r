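test_that("richness and Shannon match their closed forms", {
  m <- matrix(c(3, 0, 1, 5, 5, 0), 2,
    byrow = TRUE,
    dimnames = list(c("a", "b"), c("g1", "g2", "g3"))
  )
  ad <- alphaDiversity(m)
  expect_equal(ad$richness, c(2L, 2L))
  expect_equal(ad$shannon[2], log(2))
  expect_equal(ad$shannon[1], -(0.75 * log(0.75) + 0.25 * log(0.25)))
})

test_that("Shannon matches a direct per-sample loop oracle", {
  set.seed(1)
  m <- matrix(rpois(50 * 30, 4), 50, 30,
    dimnames = list(sprintf("s%02d", 1:50), sprintf("g%02d", 1:30))
  )
  m[m < 2] <- 0
  m <- m[rowSums(m) > 0, ]
  ad <- alphaDiversity(m)
  oracle <- apply(m, 1, function(row) {
    p <- row[row > 0] / sum(row)
    -sum(p * log(p))
  })
  expect_equal(ad$shannon, unname(oracle), tolerance = 1e-12)
})

test_that("all-zero samples are excluded with a warning, not scored as zero", {
  m <- rbind(a = c(1, 2, 3), b = c(0, 0, 0))
  expect_warning(ad <- alphaDiversity(m), "all-zero")
  expect_equal(ad$sample_id, "a")
})

test_that("rclr matches its closed form and treats zeros as missing", {
  expect_equal(
    as.numeric(rclrTransform(matrix(c(1, exp(1), exp(2)), 1))),
    c(-1, 0, 1)
  )
  r <- rclrTransform(matrix(c(0, exp(1), exp(3)), 1))
  expect_true(is.na(r[1]))
  expect_equal(as.numeric(r[2:3]), c(-1, 1)) # centred over nonzero cells only
})

test_that("rclr rows are centred and scale-invariant (property)", {
  set.seed(2)
  for (rep in 1:10) {
    m <- matrix(rpois(20 * 15, 3), 20, 15)
    m[sample(length(m), 40)] <- 0
    m <- m[rowSums(m) > 0, , drop = FALSE]
    r <- rclrTransform(m)
    expect_lt(max(abs(rowMeans(r, na.rm = TRUE))), 1e-12)
    scale <- sample(1:50, nrow(m), replace = TRUE)
    expect_equal(rclrTransform(m * scale), r, tolerance = 1e-12)
  }
  # dense case: exact centring identity
  dense <- matrix(rpois(30 * 10, 20) + 1, 30, 10)
  expect_lt(max(abs(rowMeans(rclrTransform(dense)))), 1e-12)
})

test_that("on dense data the completion PCA equals classical PCA up to sign", {
  set.seed(3)
  x <- matrix(rnorm(40 * 12), 40, 12)
  fit <- robustAitchisonPCA(x, k = 3)
  expect_true(fit$converged)
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  for (j in 1:3) {
    agree <- min(
      max(abs(fit$scores[, j] - pc$x[, j])),
      max(abs(fit$scores[, j] + pc$x[, j]))
    )
    expect_lt(agree, 1e-8)
  }
})

test_that("rank-1 structure is recovered through 10% masked cells", {
  set.seed(4)
  u <- rnorm(80)
  v <- rnorm(25)
  x <- outer(u, v) + matrix(rnorm(80 * 25, sd = 0.01), 80, 25)
  x[sample(length(x), round(0.1 * length(x)))] <- NA
  fit <- robustAitchisonPCA(x, k = 1, maxIter = 1000, tol = 1e-8)
  expect_gt(abs(cor(fit$scores[, 1], u)), 0.99)
})

test_that("component sign convention puts the largest loading positive", {
  set.seed(5)
  x <- matrix(rnorm(30 * 8), 30, 8)
  fit <- robustAitchisonPCA(x, k = 2)
  for (j in 1:2) {
    expect_gt(fit$loadings[which.max(abs(fit$loadings[, j])), j], 0)
  }
})

test_that("scores are invariant (up to sign) to genus column order", {
  set.seed(6)
  co <- cachedCohort("tiny", tinyConfig())
  m <- countsMatrix(microbiome(co)[["3"]])
  perm <- sample(ncol(m))
  f1 <- robustAitchisonPCA(rclrTransform(m), k = 2, tol = 1e-8)
  f2 <- robustAitchisonPCA(rclrTransform(m[, perm]), k = 2, tol = 1e-8)
  for (j in 1:2) {
    agree <- min(
      max(abs(f1$scores[, j] - f2$scores[, j])),
      max(abs(f1$scores[, j] + f2$scores[, j]))
    )
    expect_lt(agree, 1e-6)
  }
})

test_that("an over-large component count is rejected", {
  x <- matrix(rnorm(20), 5, 4)
  expect_error(robustAitchisonPCA(x, k = 4), "rank")
  expect_error(robustAitchisonPCA(x, k = 0), ">= 1")
})

test_that("microbiomeFeatures assembles the per-age phenotype table", {
  co <- cachedCohort("tiny", tinyConfig())
  fe <- microbiomeFeatures(microbiome(co)[["3"]])
  tab <- featureTable(fe)
  expect_named(tab, c("sample_id", "richness", "shannon", "mcpc1", "mcpc2"))
  expect_equal(nrow(tab), nrow(countsMatrix(microbiome(co)[["3"]])))
  expect_equal(ageYears(fe), 3)
  # scores of the two components are orthogonal in the fitted space
  expect_lt(abs(cor(tab$mcpc1, tab$mcpc2)), 0.2)
})
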