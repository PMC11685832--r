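test_that("configuration invariants are enforced", {
  expect_error(tinyConfig(nSamples = 0), "n_samples")
  expect_error(
    cohortConfig(snpPanel = defaultSnpPanel()[0, ], ldPairs = data.frame()),
    "empty"
  )
  bad <- defaultSnpPanel(3, 3)
  bad$maf[1] <- 0.6
  expect_error(cohortConfig(snpPanel = bad, ldPairs = data.frame()), "0.5")
  dup <- defaultSnpPanel(3, 3)
  dup$snp_id[2] <- dup$snp_id[1]
  expect_error(cohortConfig(snpPanel = dup, ldPairs = data.frame()), "duplicate")
  expect_error(
    tinyConfig(missingness = list(
      genotype = 0, microbiome = 1.0, metabolome = 0, bmi = 0
    )),
    "missingness"
  )
})

test_that("an unachievable LD target is rejected naming the pair", {
  panel <- defaultSnpPanel(2, 2)
  panel$maf <- c(0.1, 0.4, 0.3, 0.3)
  expect_error(
    cohortConfig(
      snpPanel = panel,
      ldPairs = data.frame(snp_a = "snp001", snp_b = "snp002", r = 0.95)
    ),
    "snp001.*snp002.*unachievable|unachievable.*snp001.*snp002"
  )
})

test_that("planted effects must reference panel identifiers and cross omics", {
  expect_error(
    tinyConfig(plantedEffects = list(
      plantedEffect("snp", "no_such_snp", "bmi", "bmi", 0.5)
    )),
    "no_such_snp"
  )
  expect_error(plantedEffect("snp", "snp001", "snp", "snp002", 0.5), "different omic")
  expect_error(plantedEffect("snp", "snp001", "bmi", "bmi", 0), "non-zero")
})

test_that("planted effects are canonicalised along the generation order", {
  pe <- plantedEffect("bmi", "bmi", "snp", "snp001", -0.4)
  expect_equal(pe$source_type, "snp")
  expect_equal(pe$target_type, "bmi")
  expect_equal(pe$effect_size, -0.4)
})

test_that("plantCoherentLoop realises coherent triangles and rejects incoherent signs", {
  cfg <- tinyConfig()
  out <- plantCoherentLoop(cfg, c("snp", "metabolite", "bmi"), c(1, 1, 1))
  expect_length(out$planted_effects, 3L)
  pairs <- vapply(
    out$planted_effects,
    function(pe) paste(pe$source_type, pe$target_type), character(1)
  )
  expect_setequal(pairs, c("snp metabolite", "metabolite bmi", "snp bmi"))

  # two negative links and one positive link: coherent
  out2 <- plantCoherentLoop(cfg, c("snp", "metabolite", "genus"), c(-1, 1, -1))
  expect_length(out2$planted_effects, 3L)
  expect_equal(
    sort(vapply(out2$planted_effects, function(pe) sign(pe$effect_size), numeric(1))),
    c(-1, -1, 1)
  )

  expect_error(
    plantCoherentLoop(cfg, c("snp", "metabolite", "bmi"), c(1, 1, -1)),
    "sign product"
  )
})

test_that("loop type-distinctness rules match the network's admissibility", {
  cfg <- tinyConfig()
  expect_error(
    plantCoherentLoop(cfg, c("snp", "snp", "bmi"), c(1, 1, 1)),
    "distinct"
  )
  # repeated type on opposite corners of a 4-cycle is allowed
  out <- plantCoherentLoop(
    cfg, c("snp", "metabolite", "genus", "metabolite"), c(1, 1, 1, 1)
  )
  expect_length(out$planted_effects, 4L)
  # adjacent repeats would need a same-omic edge: rejected
  expect_error(
    plantCoherentLoop(
      cfg, c("snp", "metabolite", "metabolite", "genus"), c(1, 1, 1, 1)
    ),
    "non-adjacent"
  )
})
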