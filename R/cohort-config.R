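#' @include utils.R
NULL

PLANT_TYPES <- c("snp", "genus", "metabolite", "bmi")

#' Describe one planted cross-omic effect
#'
#' A planted effect is a directed linear influence on the latent (pre-noise)
#' scale of the generator: the target's latent value gains
#' \code{effectSize * source value} for every sample. For SNP sources the
#' source value is the raw minor allele count (so \code{effectSize} is read
#' as standard deviations per allele); for genus, metabolite and BMI sources
#' it is the standardised latent value of that variable. Effects are always
#' injected along the generation order snp < genus < metabolite < bmi; an
#' effect stated against that order is canonicalised by swapping its
#' endpoints, which leaves the induced (symmetric) association untouched.
#'
#' The reserved genus-type target id \code{".axis"} addresses the generator's
#' latent community gradient -- the dominant axis of log-composition
#' variation -- so that effects on the leading microbiome principal
#' components can be planted directly.
#'
#' @param sourceType,targetType one of \code{"snp"}, \code{"genus"},
#'   \code{"metabolite"}, \code{"bmi"}; must differ.
#' @param sourceId,targetId identifiers present in the corresponding panel
#'   (for bmi use \code{"bmi"}; for the community gradient use \code{".axis"}
#'   with type \code{"genus"}).
#' @param effectSize non-zero standardised slope (signed).
#' @param ages numeric ages (years) at which the effect acts; \code{NULL}
#'   means every applicable age of the target omic.
#' @return a \code{PlantedEffect} (a validated named list).
#' @export
#' @examples
#' plantedEffect("snp", "snp001", "bmi", "bmi", 0.5, ages = 2:8)
plantedEffect <- function(sourceType, sourceId, targetType, targetId,
                          effectSize, ages = NULL) {
  sourceType <- match.arg(sourceType, PLANT_TYPES)
  targetType <- match.arg(targetType, PLANT_TYPES)
  if (sourceType == targetType) {
    stop("planted effect must connect two different omic types, got two of '",
      sourceType, "'",
      call. = FALSE
    )
  }
  if (!is.numeric(effectSize) || length(effectSize) != 1L || effectSize == 0) {
    stop("effectSize must be a single non-zero number", call. = FALSE)
  }
  if (OMIC_ORDER[[sourceType]] > OMIC_ORDER[[targetType]]) {
    # canonicalise: only the sign of the induced association is observable
    tmp <- list(sourceType, sourceId)
    sourceType <- targetType
    sourceId <- targetId
    targetType <- tmp[[1L]]
    targetId <- tmp[[2L]]
  }
  structure(
    list(
      source_type = sourceType, source_id = as.character(sourceId),
      target_type = targetType, target_id = as.character(targetId),
      effect_size = effectSize, ages = if (is.null(ages)) NULL else as.numeric(ages)
    ),
    class = "PlantedEffect"
  )
}

# default candidate-gene SNP panel: 12 genes x 5 SNPs, deterministic MAFs
defaultSnpPanel <- function(nGenes = 12L, snpsPerGene = 5L) {
  n <- nGenes * snpsPerGene
  gene <- sprintf("GENE%02d", rep(seq_len(nGenes), each = snpsPerGene))
  data.frame(
    snp_id = sprintf("snp%03d", seq_len(n)),
    gene = gene,
    chrom = rep(seq_len(nGenes), each = snpsPerGene),
    position = 60e6 + 1e4 * (seq_len(n) - 1L),
    # the first two SNPs share a MAF so the default LD pair is achievable
    maf = rep(c(0.30, 0.30, 0.10, 0.20, 0.45), length.out = n),
    stringsAsFactors = FALSE
  )
}

# default metabolite panel: 200 metabolites in 40 pathways over the five
# canonical super-pathways
defaultMetabolitePanel <- function(nMetabolites = 200L) {
  super <- rep(
    c("amino acid", "lipid", "carbohydrate", "nucleotide", "xenobiotic"),
    times = ceiling(nMetabolites * c(0.30, 0.40, 0.10, 0.075, 0.125))
  )[seq_len(nMetabolites)]
  pathway <- paste0(
    "path_", gsub(" ", "", super), "_",
    ave(seq_along(super), super, FUN = function(i) (seq_along(i) - 1L) %/% 5L + 1L)
  )
  data.frame(
    metabolite_id = sprintf("met%03d", seq_len(nMetabolites)),
    pathway = pathway,
    super_pathway = super,
    stringsAsFactors = FALSE
  )
}

#' Build a synthetic-cohort configuration
#'
#' The defaults describe the cohort structure the pipeline is designed for: a
#' multi-site longitudinal birth cohort of 676 children with candidate-gene
#' genotypes (12 genes, one pair of SNPs in tight linkage disequilibrium),
#' genus-level 16S profiles at ages 0.5, 1, 3 and 4 years, plasma
#' metabolomics at age 3 years, BMI percentiles at ages 2 through 8 years,
#' and per-omic missingness that leaves roughly 40-50 percent of samples
#' with complete multi-omic data at age 3.
#'
#' @param nSamples number of children in the cohort.
#' @param snpPanel data.frame with columns snp_id, gene, chrom, position, maf
#'   (minor allele frequency in (0, 0.5]).
#' @param ldPairs data.frame with columns snp_a, snp_b, r (target MAC
#'   correlation in [0.9, 1]); both SNPs must share a minor allele frequency.
#' @param microbiomeAges ages (years) of stool sampling.
#' @param nGenera number of genera in the count tables.
#' @param sequencingDepth mean per-sample read depth (Poisson).
#' @param metabolitePanel data.frame with columns metabolite_id, pathway,
#'   super_pathway.
#' @param metabolomeAge age (years) at which the metabolome is measured.
#' @param bmiAges ages (years) of the BMI series.
#' @param bmiAutocorrelation AR(1) coefficient of the latent BMI trajectory
#'   across consecutive ages (default 0.85; 0 gives independent ages, the
#'   regime under which the persistent-run statistic has its nominal
#'   \eqn{\approx 3\times10^{-10}} per-SNP null rate).
#' @param covariateLevels named list of level vectors for race, sex, site.
#' @param missingness named list of per-omic missing fractions in [0, 1):
#'   genotype, microbiome, metabolome, bmi (scalars, applied per age).
#' @param plantedEffects list of \code{\link{plantedEffect}} objects.
#' @param seed integer global seed; all generator randomness is derived from
#'   it through named substreams.
#' @return a validated \code{CohortConfig} (named list).
#' @export
#' @examples
#' cfg <- cohortConfig(nSamples = 50, nGenera = 20, seed = 1)
cohortConfig <- function(nSamples = 676L,
                         snpPanel = defaultSnpPanel(),
                         ldPairs = data.frame(
                           snp_a = "snp001", snp_b = "snp002", r = 0.95,
                           stringsAsFactors = FALSE
                         ),
                         microbiomeAges = c(0.5, 1, 3, 4),
                         nGenera = 100L,
                         sequencingDepth = 10000L,
                         metabolitePanel = defaultMetabolitePanel(),
                         metabolomeAge = 3,
                         bmiAges = 2:8,
                         bmiAutocorrelation = 0.85,
                         covariateLevels = list(
                           race = c("white", "black", "hispanic", "other"),
                           sex = c("female", "male"),
                           site = c("site1", "site2", "site3")
                         ),
                         missingness = list(
                           genotype = 0.02, microbiome = 0.25,
                           metabolome = 0.25, bmi = 0.20
                         ),
                         plantedEffects = list(),
                         seed = 1L) {
  cfg <- structure(
    list(
      n_samples = as.integer(nSamples),
      snp_panel = snpPanel,
      ld_pairs = ldPairs,
      microbiome_ages = as.numeric(microbiomeAges),
      n_genera = as.integer(nGenera),
      sequencing_depth = as.integer(sequencingDepth),
      metabolite_panel = metabolitePanel,
      metabolome_age = as.numeric(metabolomeAge),
      bmi_ages = as.numeric(bmiAges),
      bmi_autocorrelation = as.numeric(bmiAutocorrelation),
      covariate_levels = covariateLevels,
      missingness = missingness,
      planted_effects = plantedEffects,
      seed = as.integer(seed)
    ),
    class = "CohortConfig"
  )
  validateCohortConfig(cfg)
  cfg
}

genusIds <- function(cfg) sprintf("genus%03d", seq_len(cfg$n_genera))

validateCohortConfig <- function(cfg) {
  fail <- function(...) stop("invalid cohort configuration: ", ..., call. = FALSE)
  if (cfg$n_samples <= 0) fail("n_samples must be positive")
  sp <- cfg$snp_panel
  if (nrow(sp) == 0) fail("snp panel is empty")
  if (nrow(cfg$metabolite_panel) == 0) fail("metabolite panel is empty")
  if (cfg$n_genera <= 0) fail("n_genera must be positive")
  if (cfg$sequencing_depth <= 0) fail("sequencing_depth must be positive")
  if (anyDuplicated(sp$snp_id) > 0) fail("duplicate snp ids in panel")
  if (anyDuplicated(cfg$metabolite_panel$metabolite_id) > 0) {
    fail("duplicate metabolite ids in panel")
  }
  if (any(sp$maf <= 0 | sp$maf > 0.5)) {
    fail("minor allele frequencies must lie in (0, 0.5]")
  }
  miss <- unlist(cfg$missingness)
  if (any(miss < 0 | miss >= 1)) fail("missingness fractions must lie in [0, 1)")
  if (length(cfg$microbiome_ages) == 0) fail("at least one microbiome age required")
  if (length(cfg$bmi_ages) == 0) fail("at least one bmi age required")
  if (cfg$bmi_autocorrelation < 0 || cfg$bmi_autocorrelation >= 1) {
    fail("bmi_autocorrelation must lie in [0, 1)")
  }
  lp <- cfg$ld_pairs
  if (nrow(lp)) {
    for (i in seq_len(nrow(lp))) {
      a <- lp$snp_a[i]
      b <- lp$snp_b[i]
      if (!all(c(a, b) %in% sp$snp_id)) {
        fail(sprintf("LD pair (%s, %s) references SNPs absent from the panel", a, b))
      }
      if (lp$r[i] < 0.9 || lp$r[i] > 1) {
        fail(sprintf("LD pair (%s, %s): target correlation must lie in [0.9, 1]", a, b))
      }
      if (sp$maf[match(a, sp$snp_id)] != sp$maf[match(b, sp$snp_id)]) {
        fail(sprintf(
          "LD pair (%s, %s): target correlation unachievable, minor allele frequencies differ",
          a, b
        ))
      }
    }
  }
  valid_ids <- list(
    snp = sp$snp_id,
    genus = c(genusIds(cfg), ".axis"),
    metabolite = cfg$metabolite_panel$metabolite_id,
    bmi = "bmi"
  )
  for (pe in cfg$planted_effects) {
    if (!inherits(pe, "PlantedEffect")) fail("planted_effects must be PlantedEffect objects")
    for (side in c("source", "target")) {
      ty <- pe[[paste0(side, "_type")]]
      id <- pe[[paste0(side, "_id")]]
      if (!id %in% valid_ids[[ty]]) {
        fail(sprintf("planted effect %s '%s' (type %s) is not in the panels", side, id, ty))
      }
    }
  }
  invisible(cfg)
}

#' @export
print.CohortConfig <- function(x, ...) {
  cat(sprintf(
    paste0(
      "CohortConfig: %d samples, %d SNPs (%d LD pairs), %d genera at ages %s,\n",
      "  %d metabolites at age %g, BMI at ages %s, %d planted effects, seed %d\n"
    ),
    x$n_samples, nrow(x$snp_panel), nrow(x$ld_pairs), x$n_genera,
    paste(x$microbiome_ages, collapse = "/"), nrow(x$metabolite_panel),
    x$metabolome_age, paste(range(x$bmi_ages), collapse = "-"),
    length(x$planted_effects), x$seed
  ))
  invisible(x)
}

#' Add the planted effects realising a sign-coherent loop
#'
#' Convenience constructor: given an ordered cycle of 3 or 4 omic types and
#' the signs of its edges, appends to a configuration the planted effects
#' whose induced associations form that cycle. A cycle is realisable by a
#' consistent latent chain exactly when the product of its edge signs is +1
#' (flipping any latent variable's orientation flips two edge signs, so the
#' product is the invariant); incoherent sign patterns are rejected.
#'
#' For 3-node loops all three types must be distinct. For 4-node loops one
#' type may appear twice, but only on non-adjacent cycle positions (every
#' edge must remain cross-omic).
#'
#' @param config a \code{CohortConfig}.
#' @param nodeTypes ordered character vector of 3 or 4 omic types
#'   (\code{"snp"}, \code{"genus"}, \code{"metabolite"}, \code{"bmi"}).
#' @param signs numeric vector of +1/-1, one per cycle edge;
#'   \code{signs[i]} is the sign of the edge between \code{nodeTypes[i]} and
#'   \code{nodeTypes[i + 1]} (wrapping).
#' @param nodeIds optional concrete variable ids, one per node; defaults pick
#'   the first unused id of each type from the panels.
#' @param effectSize absolute standardised slope used for every planted edge.
#' @param ages ages at which BMI-touching edges act (default all BMI ages).
#' @return the configuration with the loop's planted effects appended.
#' @export
#' @examples
#' cfg <- cohortConfig(nSamples = 50, nGenera = 20, seed = 1)
#' cfg <- plantCoherentLoop(cfg, c("snp", "metabolite", "bmi"), c(1, 1, 1))
plantCoherentLoop <- function(config, nodeTypes, signs,
                              nodeIds = NULL, effectSize = 0.5, ages = NULL) {
  stopifnot(inherits(config, "CohortConfig"))
  k <- length(nodeTypes)
  if (!k %in% c(3L, 4L)) stop("a loop has 3 or 4 nodes", call. = FALSE)
  nodeTypes <- vapply(nodeTypes, match.arg, "", choices = PLANT_TYPES)
  if (length(signs) != k || !all(signs %in% c(-1, 1))) {
    stop("signs must be +1/-1, one per cycle edge", call. = FALSE)
  }
  if (prod(signs) != 1) {
    stop(
      "sign product is -1: an incoherent cycle cannot be realised by a ",
      "consistent latent chain (flip one sign to make the loop meaningful)",
      call. = FALSE
    )
  }
  if (k == 3L && anyDuplicated(nodeTypes) > 0) {
    stop("3-node loops require three distinct omic types", call. = FALSE)
  }
  if (k == 4L) {
    tab <- table(nodeTypes)
    if (any(tab > 2) || sum(tab == 2) > 1) {
      stop("4-node loops allow at most one omic type to repeat", call. = FALSE)
    }
    nxt <- c(2:k, 1L)
    if (any(nodeTypes == nodeTypes[nxt])) {
      stop("repeated omic types must sit on non-adjacent cycle positions",
        call. = FALSE
      )
    }
  }
  if (is.null(nodeIds)) {
    pools <- list(
      snp = config$snp_panel$snp_id,
      genus = genusIds(config),
      metabolite = config$metabolite_panel$metabolite_id,
      bmi = "bmi"
    )
    used <- list()
    nodeIds <- character(k)
    for (i in seq_len(k)) {
      ty <- nodeTypes[i]
      avail <- setdiff(pools[[ty]], used[[ty]])
      if (length(avail) == 0) stop("no unused ", ty, " id left in the panel", call. = FALSE)
      nodeIds[i] <- avail[1L]
      used[[ty]] <- c(used[[ty]], avail[1L])
    }
  }
  if (length(nodeIds) != k) stop("need one nodeId per node", call. = FALSE)
  nxt <- c(2:k, 1L)
  effects <- lapply(seq_len(k), function(i) {
    plantedEffect(
      nodeTypes[i], nodeIds[i], nodeTypes[nxt[i]], nodeIds[nxt[i]],
      effectSize * signs[i], ages = ages
    )
  })
  config$planted_effects <- c(config$planted_effects, effects)
  validateCohortConfig(config)
  config
}
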