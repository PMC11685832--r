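test_that("correlated-SNP grouping follows single linkage", {
  # duplicated SNP column: r = 1, one group of two
  set.seed(21)
  mac <- cbind(a = rbinom(100, 2, 0.3), c = rbinom(100, 2, 0.4))
  mac <- cbind(mac[, "a", drop = FALSE], b = mac[, "a"], mac[, "c", drop = FALSE])
  rownames(mac) <- sprintf("s%03d", 1:100)
  gt <- new("GenotypeTable",
    mac = mac,
    snpInfo = data.frame(
      snp_id = colnames(mac), chrom = 1, position = 1:3, gene = "G",
      stringsAsFactors = FALSE
    )
  )
  grp <- collapseCorrelatedSnps(gt, 0.9)
  expect_equal(sort(lengths(grp$groups)), c(1L, 2L))
  expect_equal(grp$membership[["a"]], grp$membership[["b"]])
  expect_false(grp$membership[["a"]] == grp$membership[["c"]])
})

test_that("a correlation chain is merged transitively even when the ends decouple", {
  set.seed(22)
  a <- rbinom(400, 2, 0.3)
  flip <- function(v, k) {
    idx <- sample(length(v), k)
    v[idx] <- rbinom(k, 2, 0.3)
    v
  }
  b <- flip(a, 12)
  c3 <- flip(b, 12)
  rab <- cor(a, b)
  rbc <- cor(b, c3)
  rac <- cor(a, c3)
  thr <- min(rab, rbc) - 0.005
  expect_lt(rac, thr) # the chain ends decouple below the threshold
  mac <- cbind(A = a, B = b, C = c3)
  rownames(mac) <- sprintf("s%03d", seq_len(nrow(mac)))
  gt <- new("GenotypeTable",
    mac = mac,
    snpInfo = data.frame(
      snp_id = colnames(mac), chrom = 1, position = 1:3, gene = "G",
      stringsAsFactors = FALSE
    )
  )
  grp <- collapseCorrelatedSnps(gt, thr)
  expect_length(grp$groups, 1L)
  expect_setequal(grp$groups[[1L]], c("A", "B", "C"))
})

test_that("independent SNPs stay in singleton groups", {
  co <- cachedCohort("null500", tinyConfig(
    nSamples = 500, seed = 13,
    missingness = list(genotype = 0, microbiome = 0.25, metabolome = 0.25, bmi = 0)
  ))
  grp <- collapseCorrelatedSnps(genotype(co), 0.9)
  # everything is a singleton except the simulated LD pair
  expect_equal(sum(lengths(grp$groups) > 1L), 1L)
  multi <- grp$groups[lengths(grp$groups) > 1L][[1L]]
  expect_setequal(multi, c("snp001", "snp002"))
})

test_that("the Bonferroni family size is the number of tests performed", {
  co <- cachedCohort("tiny", tinyConfig())
  fe <- lapply(microbiome(co), microbiomeFeatures)
  mg <- targetedMgwas(genotype(co), fe, covariates(phenotypes(co)), alpha = 0.05)
  nSnps <- ncol(macMatrix(genotype(co)))
  expect_equal(mg$m, nSnps * 4 * length(fe))
  expect_equal(mg$bonferroni_threshold, 0.05 / mg$m)
  expect_true(all(c("snp", "feature", "age", "beta", "p") %in% names(mg$tests)))
})

test_that("a planted effect on the community gradient is found with its sign", {
  cfg <- tinyConfig(
    nSamples = 600, nGenera = 30, seed = 23,
    plantedEffects = list(plantedEffect("snp", "snp004", "genus", ".axis", 0.6)),
    missingness = list(genotype = 0, microbiome = 0.1, metabolome = 0.25, bmi = 0.2)
  )
  co <- simulateCohort(cfg)
  fe <- lapply(microbiome(co), microbiomeFeatures)
  mg <- targetedMgwas(genotype(co), fe, covariates(phenotypes(co)))
  hits <- mg$edges[mg$edges$node_a == "snp004" & mg$edges$tier == "significant", ]
  expect_gt(nrow(hits), 0)
  expect_true(any(grepl("^mcpc1@", hits$node_b)))
  # the community gradient is mcpc1; its planted sign must be recovered there
  expect_true(all(hits$sign[grepl("^mcpc1@", hits$node_b)] ==
    hits$sign[grepl("^mcpc1@", hits$node_b)][1L]))
})

test_that("a null cohort yields no Bonferroni-significant mGWAS hit", {
  co <- cachedCohort("null500", tinyConfig(
    nSamples = 500, seed = 13,
    missingness = list(genotype = 0, microbiome = 0.25, metabolome = 0.25, bmi = 0)
  ))
  fe <- lapply(microbiome(co), microbiomeFeatures)
  mg <- targetedMgwas(genotype(co), fe, covariates(phenotypes(co)))
  expect_equal(sum(mg$edges$tier == "significant"), 0L)
})
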