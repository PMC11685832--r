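test_that("the 70/30 split is a deterministic disjoint partition", {
  ids <- sprintf("S%03d", 1:100)
  sp <- splitSamples(ids, 0.7, seed = 4)
  expect_length(sp$train, 70L)
  expect_length(sp$test, 30L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  expect_identical(sp, splitSamples(ids, 0.7, seed = 4))
  expect_false(identical(sp$train, splitSamples(ids, 0.7, seed = 5)$train))
  # odd sizes keep the test side at floor(0.3 n)
  sp2 <- splitSamples(sprintf("S%03d", 1:101), 0.7, seed = 1)
  expect_length(sp2$test, floor(0.3 * 101))
  expect_error(splitSamples(ids, 1.2), "trainFraction")
  expect_error(splitSamples(ids[1:10], 0.7), "20")
})

mkLoopFixture <- function(n = 300, seed = 8, noise = 0.3) {
  set.seed(seed)
  ids <- sprintf("S%04d", seq_len(n))
  snpA <- rbinom(n, 2, 0.3)
  snpB <- snpA
  snpB[sample(n, round(0.05 * n))] <- rbinom(round(0.05 * n), 2, 0.3)
  met <- 0.8 * snpA + rnorm(n, sd = noise)
  bmi <- 0.6 * met + 0.3 * snpA + rnorm(n, sd = noise)
  loopData <- data.frame(snpA = snpA, snpB = snpB, met = met, bmi = bmi)
  rownames(loopData) <- ids
  covs <- data.frame(
    race = factor(sample(c("w", "b"), n, TRUE)),
    sex = factor(sample(c("f", "m"), n, TRUE)),
    site = factor(sample(c("s1", "s2"), n, TRUE)),
    row.names = ids
  )
  types <- c(
    snpA = "genotype", snpB = "genotype",
    met = "metabolite", bmi = "bmi"
  )
  mac <- cbind(snpA = snpA, snpB = snpB)
  rownames(mac) <- ids
  gt <- new("GenotypeTable",
    mac = mac,
    snpInfo = data.frame(
      snp_id = c("snpA", "snpB"), chrom = 1, position = 1:2, gene = "G",
      stringsAsFactors = FALSE
    )
  )
  groups <- collapseCorrelatedSnps(gt, 0.9)
  list(loopData = loopData, covs = covs, types = types, groups = groups, ids = ids)
}

test_that("correlated-SNP group members never predict each other", {
  fx <- mkLoopFixture()
  sp <- splitSamples(fx$ids, 0.7, seed = 2)
  models <- fitLoopModels(fx$loopData, fx$types, fx$covs, sp$train,
    snpGroups = fx$groups
  )
  expect_length(models$models, 4L)
  expect_false("snpB" %in% models$models$snpA$predictors)
  expect_false("snpA" %in% models$models$snpB$predictors)
  expect_equal(models$models$snpA$excluded, "snpB")
  expect_true(all(c("met", "bmi") %in% models$models$snpA$predictors))
  # non-genotype responses keep every other variable
  expect_setequal(models$models$met$predictors, c("snpA", "snpB", "bmi"))
  # a response never predicts itself
  for (m in models$models) expect_false(m$response %in% m$predictors)
})

test_that("perfect predictions give exactly zero MSE", {
  fx <- mkLoopFixture(noise = 1e-9) # met and bmi are deterministic functions
  sp <- splitSamples(fx$ids, 0.7, seed = 3)
  models <- fitLoopModels(
    fx$loopData[c("snpA", "met", "bmi")],
    fx$types, fx$covs, sp$train,
    snpGroups = fx$groups
  )
  rep <- evaluateMse(models, sp$test)
  res <- cvResults(rep)
  expect_lt(res$mse_percent[res$response == "met"], 1e-10)
  expect_lt(res$mse_percent[res$response == "bmi"], 1e-10)
})

test_that("a mean predictor of a uniform variable has ~8.3 percent MSE", {
  set.seed(9)
  n <- 20000
  ids <- sprintf("S%05d", seq_len(n))
  u <- runif(n)
  noisePred <- rnorm(n) # unrelated predictor: model collapses to the mean
  loopData <- data.frame(u = u, x = noisePred)
  rownames(loopData) <- ids
  covs <- data.frame(
    race = factor(rep("w", n)), sex = factor(rep(c("f", "m"), n / 2)),
    site = factor(rep("s", n)), row.names = ids
  )
  sp <- splitSamples(ids, 0.7, seed = 5)
  models <- fitLoopModels(loopData, c(u = "bmi", x = "metabolite"), covs, sp$train)
  rep <- evaluateMse(models, sp$test)
  res <- cvResults(rep)
  expect_equal(res$baseline_mse_percent[res$response == "u"], 100 / 12,
    tolerance = 0.05
  )
  expect_equal(res$mse_percent[res$response == "u"], 100 / 12, tolerance = 0.05)
})

test_that("the fitted model beats the mean predictor on training data", {
  fx <- mkLoopFixture(seed = 10)
  models <- fitLoopModels(fx$loopData, fx$types, fx$covs, fx$ids) # train on all
  rep <- evaluateMse(models, fx$ids) # evaluate on the training samples
  res <- cvResults(rep)
  expect_true(all(res$mse_percent <= res$baseline_mse_percent + 1e-9))
})

test_that("an empty complete-case test set is flagged, not fabricated", {
  fx <- mkLoopFixture(n = 60, seed = 11)
  dat <- fx$loopData
  sp <- splitSamples(fx$ids, 0.7, seed = 6)
  dat[sp$test, "met"] <- NA # no test sample is complete
  models <- fitLoopModels(dat, fx$types, fx$covs, sp$train, snpGroups = fx$groups)
  expect_warning(rep <- evaluateMse(models, sp$test), "complete")
  expect_true(all(is.na(cvResults(rep)$mse_percent)))
  expect_equal(rep@completeFraction, 0)
})
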