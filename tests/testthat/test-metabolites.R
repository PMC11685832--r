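test_that("a planted metabolite-BMI association enters the screen with its pathway", {
  cfg <- tinyConfig(
    nSamples = 600, seed = 26,
    plantedEffects = list(plantedEffect("metabolite", "met003", "bmi", "bmi", 0.5)),
    missingness = list(genotype = 0, microbiome = 0.25, metabolome = 0.1, bmi = 0.1)
  )
  co <- simulateCohort(cfg)
  ms <- metaboliteBmiScreen(metabolome(co), phenotypes(co), age = 3)
  expect_true("met003" %in% ms$metabolites)
  pw <- metaboliteInfo(metabolome(co))
  expect_true(pw$pathway[pw$metabolite_id == "met003"] %in% ms$pathways_of_interest)
  hit <- ms$edges[ms$edges$node_a == "met003", ][1L, ]
  expect_equal(hit$sign, 1)
})

test_that("either BMI measure suffices for inclusion", {
  # construct a metabolite associated with the category but not the percentile
  set.seed(27)
  n <- 200
  ids <- sprintf("S%04d", 1:n)
  katMeasure <- sample(0:3, n, replace = TRUE)
  ab <- matrix(exp(rnorm(n * 3)), n, 3, dimnames = list(ids, c("m1", "m2", "m3")))
  ab[, "m2"] <- exp(0.4 * katMeasure + rnorm(n, sd = 0.6))
  met <- new("MetaboliteTable",
    abundance = ab,
    metabInfo = data.frame(
      metabolite_id = c("m1", "m2", "m3"),
      pathway = c("p1", "p2", "p3"),
      super_pathway = "lipid", stringsAsFactors = FALSE
    )
  )
  perc <- matrix(runif(n, 0, 100), n, dimnames = list(ids, "3"))
  katm <- matrix(katMeasure, n, dimnames = list(ids, "3"))
  ph <- new("PhenotypeSeries",
    percentile = perc, category = katm, ages = 3,
    covariates = data.frame(
      race = factor(rep("a", n)), sex = factor(rep(c("f", "m"), n / 2)),
      site = factor(rep("s1", n)), row.names = ids
    )
  )
  ms <- metaboliteBmiScreen(met, ph, age = 3)
  expect_true("m2" %in% ms$metabolites)
  m2edges <- ms$edges[ms$edges$node_a == "m2", ]
  expect_true("bmi_category" %in% m2edges$node_b)
})

test_that("selection requires significant partners in two distinct omics", {
  co <- cachedCohort("cross", tinyConfig(
    nSamples = 600, nGenera = 20, seed = 28,
    missingness = list(genotype = 0, microbiome = 0.1, metabolome = 0.1, bmi = 0.1),
    plantedEffects = list(
      # met002: SNP partner + genus partner -> two omics, selected
      plantedEffect("snp", "snp003", "metabolite", "met002", 0.6),
      plantedEffect("genus", "genus005", "metabolite", "met002", 0.6),
      # met010: the LD pair only -> two partners of one omic type, not selected
      plantedEffect("snp", "snp001", "metabolite", "met010", 0.6)
    )
  ))
  pw <- metaboliteInfo(metabolome(co))
  pathways <- pw$pathway[pw$metabolite_id %in% c("met002", "met010")]
  res <- crossOmicMetaboliteTests(
    metabolome(co), pathways, phenotypes(co), genotype(co),
    snpIds = c("snp001", "snp002", "snp003"),
    microbiomeCounts = microbiome(co)[["3"]],
    genusIds = "genus005", age = 3
  )
  expect_true("met002" %in% res$selected)
  expect_false("met010" %in% res$selected)
  e2 <- res$edges[res$edges$node_a == "met002", ]
  expect_setequal(
    unique(e2$type_b[e2$node_b %in% c("snp003", "genus005")]),
    c("genotype", "microbiome")
  )
  expect_true(all(e2$sign[e2$node_b %in% c("snp003", "genus005")] == 1))
  # met010 is significant against both members of the LD pair, yet one omic
  t10 <- res$tests[res$tests$metabolite == "met010" & res$tests$p < 0.01, ]
  expect_true(all(t10$partner_type == "genotype"))
})

test_that("an empty pathway set warns and selects nothing", {
  co <- cachedCohort("tiny", tinyConfig())
  expect_warning(
    res <- crossOmicMetaboliteTests(
      metabolome(co), character(), phenotypes(co), genotype(co),
      snpIds = "snp001", age = 3
    ),
    "pathways"
  )
  expect_length(res$selected, 0L)
})
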