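#' @include cohort-config.R AllClasses.R
NULL

# does a planted effect act at this age?
effectActsAt <- function(pe, age) is.null(pe$ages) || age %in% pe$ages

# ordinal BMI category from percentile, CDC-style pediatric cutpoints
bmiCategoryFromPercentile <- function(p) {
  ifelse(is.na(p), NA_real_, findInterval(p, c(5, 85, 95)))
}

# Dirichlet-multinomial draw: one count vector per row of the composition
# matrix, concentration `conc` controlling overdispersion
rDirichletMultinom <- function(depth, comp, conc) {
  n <- nrow(comp)
  out <- matrix(0L, n, ncol(comp), dimnames = dimnames(comp))
  for (s in seq_len(n)) {
    w <- stats::rgamma(ncol(comp), shape = conc * comp[s, ], rate = 1)
    if (all(w == 0)) w <- comp[s, ] # degenerate gamma draw at tiny shapes
    out[s, ] <- stats::rmultinom(1L, depth[s], w / sum(w))[, 1L]
  }
  out
}

#' Simulate a multi-omic cohort with planted ground truth
#'
#' Generates the four sample-aligned omic tables the pipeline consumes, on a
#' shared latent linear chain into which the configuration's planted effects
#' are injected (always on the pre-noise scale):
#' \itemize{
#'   \item genotypes: per-SNP binomial(2, MAF) minor allele counts; each
#'     linkage-disequilibrium pair is realised by copying the first SNP and
#'     resampling a fraction \code{1 - r} of genotypes, which targets a MAC
#'     correlation of \code{r};
#'   \item microbiome: per age, genus log-baselines (log-normal) plus a
#'     one-dimensional latent community gradient and planted shifts give a
#'     log-linear composition; counts are Dirichlet-multinomial at a
#'     Poisson-distributed sequencing depth;
#'   \item metabolome: log-normal abundances with planted shifts on the log
#'     scale, measured at a single age;
#'   \item BMI: a per-sample latent trajectory, AR(1)-autocorrelated across
#'     ages, mapped through the normal CDF to percentiles and to ordinal
#'     categories by the 5/85/95 cutpoints.
#' }
#' Missingness is applied independently per omic (and per age) completely at
#' random: microbiome and metabolome samples are dropped from their tables,
#' genotype rows and BMI cells become \code{NA}. Identical configuration and
#' seed reproduce the cohort bit for bit; every stage draws from its own
#' named substream of the global seed.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return a \code{\linkS4class{SyntheticCohort}}.
#' @export
#' @examples
#' cfg <- cohortConfig(nSamples = 60, nGenera = 15, seed = 7)
#' cohort <- simulateCohort(cfg)
#' cohort
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  validateCohortConfig(config)
  cfg <- config
  n <- cfg$n_samples
  ids <- makeSampleIds(n)
  seed <- cfg$seed

  ## covariates ---------------------------------------------------------
  covs <- withSeed(stageSeed(seed, "covariates"), {
    data.frame(
      race = factor(sample(cfg$covariate_levels$race, n, replace = TRUE),
        levels = cfg$covariate_levels$race
      ),
      sex = factor(sample(cfg$covariate_levels$sex, n, replace = TRUE),
        levels = cfg$covariate_levels$sex
      ),
      site = factor(sample(cfg$covariate_levels$site, n, replace = TRUE),
        levels = cfg$covariate_levels$site
      ),
      row.names = ids, stringsAsFactors = FALSE
    )
  })

  ## genotype -----------------------------------------------------------
  sp <- cfg$snp_panel
  mac <- withSeed(stageSeed(seed, "genotype"), {
    m <- vapply(sp$maf, function(f) stats::rbinom(n, 2L, f), numeric(n))
    dimnames(m) <- list(ids, sp$snp_id)
    lp <- cfg$ld_pairs
    for (i in seq_len(nrow(lp))) {
      a <- lp$snp_a[i]
      b <- lp$snp_b[i]
      m[, b] <- m[, a]
      nres <- round(n * (1 - lp$r[i]))
      if (nres > 0) {
        idx <- sample.int(n, nres)
        m[idx, b] <- stats::rbinom(nres, 2L, sp$maf[match(b, sp$snp_id)])
      }
    }
    m
  })

  effects <- cfg$planted_effects
  byTarget <- function(ty) Filter(function(pe) pe$target_type == ty, effects)

  ## microbiome ---------------------------------------------------------
  gids <- genusIds(cfg)
  baselines <- withSeed(
    stageSeed(seed, "microbiome_baselines"),
    stats::rnorm(cfg$n_genera, 0, 1.5)
  )
  axisLoad <- withSeed(
    stageSeed(seed, "microbiome_axis_loadings"),
    stats::rnorm(cfg$n_genera, 0, 0.6)
  )
  genusEffects <- byTarget("genus")
  latentEta <- list() # per age, full pre-missingness latent log-composition
  latentAxis <- list()
  # sources resolved lazily so genus/metabolite sources can reference the
  # latent matrices generated earlier in the chain
  sourceValue <- function(pe, defaultAge) {
    switch(pe$source_type,
      snp = mac[, pe$source_id],
      genus = {
        cand <- intersect(pe$ages %||% numeric(0), cfg$microbiome_ages)
        age <- if (length(cand)) {
          cand[1L]
        } else if (defaultAge %in% cfg$microbiome_ages) {
          defaultAge
        } else {
          cfg$microbiome_ages[1L]
        }
        v <- latentEta[[as.character(age)]][, pe$source_id]
        (v - mean(v)) / stats::sd(v)
      },
      metabolite = {
        v <- latentLogMet[, pe$source_id]
        (v - mean(v)) / stats::sd(v)
      },
      stop("unsupported planted-effect source type: ", pe$source_type)
    )
  }

  microbiome <- list()
  for (age in cfg$microbiome_ages) {
    key <- as.character(age)
    st <- stageSeed(seed, paste0("microbiome_age_", key))
    u <- withSeed(stageSeed(seed, paste0("microbiome_axis_", key)), stats::rnorm(n))
    for (pe in genusEffects) {
      if (pe$target_id == ".axis" && effectActsAt(pe, age)) {
        u <- u + pe$effect_size * sourceValue(pe, age)
      }
    }
    eta <- matrix(baselines, n, cfg$n_genera, byrow = TRUE,
      dimnames = list(ids, gids)
    )
    eta <- eta + outer(u, axisLoad)
    for (pe in genusEffects) {
      if (pe$target_id != ".axis" && effectActsAt(pe, age)) {
        eta[, pe$target_id] <- eta[, pe$target_id] + pe$effect_size * sourceValue(pe, age)
      }
    }
    counts <- withSeed(st, {
      eta_noisy <- eta + matrix(stats::rnorm(n * cfg$n_genera, 0, 0.4), n)
      comp <- exp(eta_noisy - apply(eta_noisy, 1L, max))
      comp <- comp / rowSums(comp)
      depth <- pmax(1L, stats::rpois(n, cfg$sequencing_depth))
      rDirichletMultinom(depth, comp, conc = 300)
    })
    latentEta[[key]] <- eta
    latentAxis[[key]] <- u
    microbiome[[key]] <- counts
  }

  ## metabolome ---------------------------------------------------------
  mp <- cfg$metabolite_panel
  metMu <- withSeed(
    stageSeed(seed, "metabolome_baselines"),
    stats::rnorm(nrow(mp), 0, 1)
  )
  # intrinsic biological variation (the latent the chains act through) plus
  # measurement noise added below; roughly equal shares of unit variance
  latentLogMet <- matrix(metMu, n, nrow(mp), byrow = TRUE,
    dimnames = list(ids, mp$metabolite_id)
  ) + withSeed(
    stageSeed(seed, "metabolome_latent"),
    matrix(stats::rnorm(n * nrow(mp), 0, 0.7), n)
  )
  for (pe in byTarget("metabolite")) {
    if (effectActsAt(pe, cfg$metabolome_age)) {
      latentLogMet[, pe$target_id] <- latentLogMet[, pe$target_id] +
        pe$effect_size * sourceValue(pe, cfg$metabolome_age)
    }
  }
  logMet <- latentLogMet + withSeed(
    stageSeed(seed, "metabolome_noise"),
    matrix(stats::rnorm(n * nrow(mp), 0, 0.7), n)
  )

  ## bmi ----------------------------------------------------------------
  bmiAges <- sort(cfg$bmi_ages)
  rho <- cfg$bmi_autocorrelation %||% 0.85
  z <- withSeed(stageSeed(seed, "bmi_trajectory"), {
    zz <- matrix(NA_real_, n, length(bmiAges), dimnames = list(ids, bmiAges))
    zz[, 1L] <- stats::rnorm(n)
    for (j in seq_along(bmiAges)[-1L]) {
      zz[, j] <- rho * zz[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
    }
    zz
  })
  for (pe in byTarget("bmi")) {
    sv <- sourceValue(pe, cfg$metabolome_age)
    for (j in seq_along(bmiAges)) {
      if (effectActsAt(pe, bmiAges[j])) z[, j] <- z[, j] + pe$effect_size * sv
    }
  }
  percentile <- 100 * stats::pnorm(z)
  category <- bmiCategoryFromPercentile(percentile)
  dim(category) <- dim(percentile)
  dimnames(category) <- dimnames(percentile)

  ## missingness (MCAR, independent per omic per age) -------------------
  miss <- cfg$missingness
  dropIdx <- function(stream, frac) {
    if (frac <= 0) return(integer(0))
    withSeed(stageSeed(seed, stream), sample.int(n, round(n * frac)))
  }
  gmiss <- dropIdx("missing_genotype", miss$genotype %||% 0)
  macObs <- mac
  if (length(gmiss)) macObs[gmiss, ] <- NA_real_
  for (key in names(microbiome)) {
    mmiss <- dropIdx(paste0("missing_microbiome_", key), miss$microbiome %||% 0)
    if (length(mmiss)) microbiome[[key]] <- microbiome[[key]][-mmiss, , drop = FALSE]
    keep <- rowSums(microbiome[[key]]) > 0
    microbiome[[key]] <- microbiome[[key]][keep, , drop = FALSE]
  }
  metmiss <- dropIdx("missing_metabolome", miss$metabolome %||% 0)
  metObs <- exp(logMet)
  if (length(metmiss)) metObs <- metObs[-metmiss, , drop = FALSE]
  for (j in seq_along(bmiAges)) {
    bmiss <- dropIdx(paste0("missing_bmi_", bmiAges[j]), miss$bmi %||% 0)
    if (length(bmiss)) {
      percentile[bmiss, j] <- NA_real_
      category[bmiss, j] <- NA_real_
    }
  }

  ## assemble -----------------------------------------------------------
  truth <- if (length(effects)) {
    do.call(rbind, lapply(effects, function(pe) {
      data.frame(
        source_type = pe$source_type, source_id = pe$source_id,
        target_type = pe$target_type, target_id = pe$target_id,
        effect_size = pe$effect_size,
        ages = if (is.null(pe$ages)) "" else paste(pe$ages, collapse = ","),
        stringsAsFactors = FALSE
      )
    }))
  } else {
    data.frame(
      source_type = character(), source_id = character(),
      target_type = character(), target_id = character(),
      effect_size = numeric(), ages = character(), stringsAsFactors = FALSE
    )
  }

  new("SyntheticCohort",
    genotype = new("GenotypeTable",
      mac = macObs,
      snpInfo = data.frame(
        snp_id = sp$snp_id, chrom = sp$chrom,
        position = sp$position, gene = sp$gene, stringsAsFactors = FALSE
      )
    ),
    microbiome = setNames(
      lapply(names(microbiome), function(key) {
        new("MicrobiomeCounts", counts = microbiome[[key]], age = as.numeric(key))
      }),
      names(microbiome)
    ),
    metabolome = new("MetaboliteTable", abundance = metObs, metabInfo = mp),
    phenotypes = new("PhenotypeSeries",
      percentile = percentile, category = category,
      ages = bmiAges, covariates = covs
    ),
    truth = truth,
    config = unclass(cfg)
  )
}
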