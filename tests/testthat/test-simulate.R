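test_that("identical config and seed reproduce the cohort bit for bit", {
  cfg <- tinyConfig(seed = 7)
  a <- simulateCohort(cfg)
  b <- simulateCohort(cfg)
  expect_identical(macMatrix(genotype(a)), macMatrix(genotype(b)))
  expect_identical(
    lapply(microbiome(a), countsMatrix),
    lapply(microbiome(b), countsMatrix)
  )
  expect_identical(abundanceMatrix(metabolome(a)), abundanceMatrix(metabolome(b)))
  expect_identical(bmiPercentile(phenotypes(a)), bmiPercentile(phenotypes(b)))
  expect_identical(covariates(phenotypes(a)), covariates(phenotypes(b)))
})

test_that("missing samples are absent or NA, never zero-filled", {
  co <- cachedCohort("tiny", tinyConfig())
  n <- length(sampleIds(co))
  # microbiome/metabolome samples are dropped from the tables
  expect_lt(nrow(countsMatrix(microbiome(co)[["3"]])), n)
  expect_lt(nrow(abundanceMatrix(metabolome(co))), n)
  # bmi cells become NA
  expect_gt(sum(is.na(bmiPercentile(phenotypes(co)))), 0)
  # genotype missingness is whole-row NA
  expect_true(all(rowSums(is.na(macMatrix(genotype(co)))) %in%
    c(0L, ncol(macMatrix(genotype(co))))))
})

test_that("LD pairs reach their target MAC correlation", {
  co <- cachedCohort("ld", tinyConfig(nSamples = 2000, seed = 5))
  mac <- macMatrix(genotype(co))
  r <- cor(mac[, "snp001"], mac[, "snp002"], use = "complete.obs")
  expect_gt(r, 0.90)
  expect_lt(r, 0.99)
})

test_that("BMI categories follow the 5/85/95 percentile cutpoints", {
  co <- cachedCohort("tiny", tinyConfig())
  p <- bmiPercentile(phenotypes(co))
  k <- bmiCategory(phenotypes(co))
  ok <- !is.na(p)
  expect_identical(k[ok], findInterval(p[ok], c(5, 85, 95)) + 0)
  expect_identical(is.na(p), is.na(k))
})

test_that("with no planted effects, SNP-BMI tests are null-calibrated", {
  co <- cachedCohort("null500", tinyConfig(
    nSamples = 500, seed = 13,
    missingness = list(genotype = 0, microbiome = 0.25, metabolome = 0.25, bmi = 0)
  ))
  mac <- macMatrix(genotype(co))
  pct <- bmiPercentile(phenotypes(co))
  cors <- ps <- c()
  for (snp in colnames(mac)) {
    for (j in seq_len(ncol(pct))) {
      ct <- suppressWarnings(cor.test(mac[, snp], pct[, j]))
      cors <- c(cors, ct$estimate)
      ps <- c(ps, ct$p.value)
    }
  }
  expect_lt(abs(mean(cors)), 0.01)
  # fraction of p < 0.01 within the binomial 99% envelope of 0.01
  frac <- mean(ps < 0.01)
  bound <- 2.58 * sqrt(0.01 * 0.99 / length(ps))
  expect_lt(abs(frac - 0.01), bound + 1e-9)
})

test_that("a planted SNP-to-BMI effect is recovered by per-age regression", {
  cfg <- tinyConfig(
    nSamples = 500, seed = 21,
    plantedEffects = list(plantedEffect("snp", "snp005", "bmi", "bmi", 0.5, ages = 2:8)),
    missingness = list(genotype = 0, microbiome = 0.25, metabolome = 0.25, bmi = 0)
  )
  co <- simulateCohort(cfg)
  mac <- macMatrix(genotype(co))[, "snp005"]
  pct <- bmiPercentile(phenotypes(co))
  for (j in seq_len(ncol(pct))) {
    z <- qnorm(pct[, j] / 100) # the latent scale the effect acts on
    fit <- summary(lm(z ~ mac))
    est <- fit$coefficients["mac", "Estimate"]
    se <- fit$coefficients["mac", "Std. Error"]
    expect_lt(abs(est - 0.5), 3 * se)
  }
})

test_that("planted genus effects shift the genus log-abundance", {
  cfg <- tinyConfig(
    nSamples = 500, seed = 31,
    plantedEffects = list(
      plantedEffect("snp", "snp003", "genus", "genus004", 0.8)
    )
  )
  co <- simulateCohort(cfg)
  mb <- microbiome(co)[["3"]]
  la <- tssLogAbundance(mb)
  ids <- intersect(rownames(la), rownames(macMatrix(genotype(co))))
  fit <- summary(lm(la[ids, "genus004"] ~ macMatrix(genotype(co))[ids, "snp003"]))
  expect_lt(fit$coefficients[2, 4], 1e-4)
  expect_gt(fit$coefficients[2, 1], 0)
})
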