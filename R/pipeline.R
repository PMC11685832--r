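#' @include simulate-cohort.R microbiome-features.R mgwas.R persistence.R
#' @include diffabund.R metabolites.R network.R crossval.R io.R
NULL

#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the three-phase analysis in one declarative
#' object: the input (an existing cohort or a simulation configuration), the
#' per-stage thresholds, the cross-section age at which metabolome, genus
#' abundances and the cross-validation are matched, the loop rules and the
#' split controls.
#'
#' @param cohort a \code{\linkS4class{SyntheticCohort}} (or the list
#'   returned by \code{\link{readCohortTables}}), or \code{NULL} to simulate.
#' @param simulation a \code{\link{cohortConfig}} used when \code{cohort} is
#'   \code{NULL}.
#' @param bonferroniAlpha family-wise error target of the targeted mGWAS.
#' @param suggestiveP suggestive-tier p cutoff of the mGWAS.
#' @param persistenceAlpha per-age threshold of the persistent BMI scan.
#' @param kConsecutive minimum persistent run length (ages).
#' @param qThreshold BH q cutoff of the differential-abundance stage.
#' @param metaboliteAlpha p cutoff of both metabolite stages.
#' @param minOmics distinct-omics requirement of the cross-omic stage.
#' @param rThreshold correlated-SNP grouping threshold.
#' @param prevalenceMin genus prevalence filter.
#' @param mcpcK number of MCPCs used as mGWAS phenotypes.
#' @param crossSectionAge age (years) matching metabolome, genus partners
#'   and the cross-validation.
#' @param loopSizes cycle sizes to enumerate.
#' @param distinctTypes loop omic-type distinctness rule
#'   (see \code{\link{findLoops}}).
#' @param nullPermutations sign permutations for the loop-count null
#'   (0 = skip).
#' @param cvFraction,cvSeed train fraction and seed of the 70/30 validation.
#' @param cvBmiMeasure which BMI variable enters the loop-variable set when
#'   a bmi node is part of a meaningful loop but the node itself does not
#'   name one ("percentile" or "category").
#' @param outdir output directory for all stage artifacts, or \code{NULL}
#'   to keep everything in memory.
#' @return a \code{RunConfig} list.
#' @export
runConfig <- function(cohort = NULL, simulation = NULL,
                      bonferroniAlpha = 0.05, suggestiveP = 1e-5,
                      persistenceAlpha = 0.01, kConsecutive = 5L,
                      qThreshold = 0.05, metaboliteAlpha = 0.01,
                      minOmics = 2L, rThreshold = 0.9, prevalenceMin = 0.1,
                      mcpcK = 2L, crossSectionAge = 3,
                      loopSizes = c(3L, 4L), distinctTypes = TRUE,
                      nullPermutations = 0L,
                      cvFraction = 0.7, cvSeed = 20L,
                      cvBmiMeasure = c("percentile", "category"),
                      outdir = NULL) {
  if (is.null(cohort) && is.null(simulation)) {
    stop("provide either a cohort or a simulation configuration", call. = FALSE)
  }
  stopifnot(
    bonferroniAlpha > 0, bonferroniAlpha < 1, suggestiveP > 0,
    persistenceAlpha > 0, persistenceAlpha < 1, kConsecutive >= 1,
    qThreshold > 0, qThreshold < 1, metaboliteAlpha > 0, metaboliteAlpha < 1,
    minOmics >= 1, rThreshold > 0, rThreshold <= 1,
    prevalenceMin >= 0, prevalenceMin < 1, mcpcK >= 1,
    cvFraction > 0, cvFraction < 1
  )
  structure(
    list(
      cohort = cohort, simulation = simulation,
      bonferroni_alpha = bonferroniAlpha, suggestive_p = suggestiveP,
      persistence_alpha = persistenceAlpha, k_consecutive = as.integer(kConsecutive),
      q_threshold = qThreshold, metabolite_alpha = metaboliteAlpha,
      min_omics = as.integer(minOmics), r_threshold = rThreshold,
      prevalence_min = prevalenceMin, mcpc_k = as.integer(mcpcK),
      cross_section_age = crossSectionAge,
      loop_sizes = as.integer(loopSizes), distinct_types = distinctTypes,
      null_permutations = as.integer(nullPermutations),
      cv_fraction = cvFraction, cv_seed = as.integer(cvSeed),
      cv_bmi_measure = match.arg(cvBmiMeasure),
      outdir = outdir
    ),
    class = "RunConfig"
  )
}

# per-sample values of a network node at the cross-section age, over `ids`
materializeNode <- function(id, type, ids, cohort, featuresList, age,
                            bmiMeasure = "percentile") {
  ph <- cohort@phenotypes
  v <- rep(NA_real_, length(ids))
  names(v) <- ids
  fill <- function(vals) {
    common <- intersect(names(vals), ids)
    v[common] <- vals[common]
    v
  }
  switch(type,
    genotype = fill(cohort@genotype@mac[, id]),
    metabolite = fill(logAbundance(cohort@metabolome@abundance)[, id]),
    bmi = {
      meas <- if (grepl("category", id)) "category" else if (grepl("percentile", id)) "percentile" else bmiMeasure
      j <- match(age, ph@ages)
      if (is.na(j)) stop("no BMI at age ", age, call. = FALSE)
      m <- if (meas == "category") ph@category else ph@percentile
      fill(m[, j])
    },
    microbiome = {
      if (grepl("@", id, fixed = TRUE)) {
        feat <- sub("@.*$", "", id)
        fage <- sub("^.*@", "", id)
        fe <- featuresList[[fage]]
        if (is.null(fe)) stop("no microbiome features at age ", fage, call. = FALSE)
        fill(stats::setNames(fe@features[[feat]], fe@features$sample_id))
      } else {
        mb <- cohort@microbiome[[as.character(age)]]
        if (is.null(mb)) stop("no microbiome counts at age ", age, call. = FALSE)
        fill(tssLogAbundance(mb)[, id])
      }
    },
    stop("unknown node type: ", type)
  )
}

#' Run the full three-phase pipeline
#'
#' Executes, in order: cohort acquisition (simulation unless one is given),
#' per-age microbiome features, correlated-SNP grouping, the targeted mGWAS,
#' the persistent BMI scan, genus differential abundance against the SNPs of
#' interest, the metabolite-BMI screen, the cross-omic metabolite tests,
#' network assembly, loop detection (with an optional sign-permutation
#' null), and the 70/30 predictive validation over the meaningful-loop
#' variables. When \code{outdir} is set, every stage table, the network
#' (GraphML + edge TSV), the loops (JSON), the cross-validation report and a
#' run manifest are written there; the run is idempotent under a fixed
#' configuration and seed.
#'
#' @param config a \code{\link{runConfig}}.
#' @return an object of class \code{PipelineResult}: a list with the cohort,
#'   per-stage results, the combined edge table, the network, the loop
#'   table, the optional loop null, and the \code{\linkS4class{CvReport}}.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "RunConfig"))
  cfg <- config
  cohort <- cfg$cohort
  if (is.null(cohort)) {
    cohort <- simulateCohort(cfg$simulation)
  } else if (is.list(cohort) && !isS4(cohort)) {
    # output of readCohortTables
    cohort <- new("SyntheticCohort",
      genotype = cohort$genotype, microbiome = cohort$microbiome,
      metabolome = cohort$metabolome, phenotypes = cohort$phenotypes,
      truth = if (is.null(cohort$truth) || !nrow(cohort$truth)) {
        data.frame()
      } else {
        cohort$truth
      },
      config = list()
    )
  }
  covs <- cohort@phenotypes@covariates
  age3 <- cfg$cross_section_age

  featuresList <- lapply(cohort@microbiome, microbiomeFeatures, k = cfg$mcpc_k)
  snpGroups <- collapseCorrelatedSnps(cohort@genotype, cfg$r_threshold)
  mg <- targetedMgwas(cohort@genotype, featuresList, covs,
    alpha = cfg$bonferroni_alpha, suggestive = cfg$suggestive_p
  )
  ps <- persistentBmiScan(cohort@genotype, cohort@phenotypes,
    alpha = cfg$persistence_alpha, kConsecutive = cfg$k_consecutive
  )
  snpsOfInterest <- sort(unique(c(mg$edges$node_a, ps$edges$node_a)))

  daEdges <- emptyEdges()
  daTests <- list()
  if (length(snpsOfInterest)) {
    for (mb in cohort@microbiome) {
      da <- differentialAbundance(mb, cohort@genotype, snpsOfInterest, covs,
        qThreshold = cfg$q_threshold, prevalenceMin = cfg$prevalence_min
      )
      daEdges <- rbind(daEdges, da$edges)
      if (!is.null(da$tests)) daTests[[as.character(mb@age)]] <- da$tests
    }
  } else {
    warning("no SNP of interest from phase 1; differential abundance skipped",
      call. = FALSE
    )
  }
  generaOfInterest <- sort(unique(daEdges$node_b))

  ms <- metaboliteBmiScreen(cohort@metabolome, cohort@phenotypes,
    age = age3, alpha = cfg$metabolite_alpha
  )
  co <- crossOmicMetaboliteTests(
    cohort@metabolome, ms$pathways_of_interest, cohort@phenotypes,
    cohort@genotype,
    snpIds = snpsOfInterest,
    microbiomeCounts = cohort@microbiome[[as.character(age3)]],
    genusIds = generaOfInterest,
    age = age3, alpha = cfg$metabolite_alpha, minOmics = cfg$min_omics
  )

  allEdges <- rbind(mg$edges, ps$edges, daEdges, ms$edges, co$edges)
  network <- buildNetwork(allEdges)
  loops <- findLoops(network,
    sizes = cfg$loop_sizes,
    distinctTypes = cfg$distinct_types
  )
  loopNull <- if (cfg$null_permutations > 0 && nrow(network@edges) > 0) {
    loopNullCount(network, cfg$null_permutations,
      seed = cfg$cv_seed,
      sizes = cfg$loop_sizes, distinctTypes = cfg$distinct_types
    )
  } else {
    NULL
  }

  cv <- NULL
  meaningful <- loops[loops$meaningful, , drop = FALSE]
  if (nrow(meaningful)) {
    nodeIds <- unique(unlist(meaningful$nodes))
    nodeTypes <- stats::setNames(
      network@nodes$type[match(nodeIds, network@nodes$id)], nodeIds
    )
    ids <- sampleIds(cohort)
    loopData <- as.data.frame(lapply(nodeIds, function(id) {
      materializeNode(
        id, nodeTypes[[id]], ids, cohort, featuresList, age3,
        bmiMeasure = cfg$cv_bmi_measure
      )
    }), col.names = nodeIds, check.names = FALSE)
    rownames(loopData) <- ids
    split <- splitSamples(ids, cfg$cv_fraction, seed = cfg$cv_seed)
    models <- fitLoopModels(loopData, nodeTypes, covs, split$train,
      snpGroups = snpGroups
    )
    cv <- evaluateMse(models, split$test, seed = cfg$cv_seed)
  } else {
    warning("no meaningful loop found; cross-validation skipped", call. = FALSE)
  }

  result <- structure(
    list(
      cohort = cohort, features = featuresList, snpGroups = snpGroups,
      mgwas = mg, persistence = ps,
      diffabund = list(edges = orderEdges(daEdges), tests = daTests),
      metaboliteScreen = ms, crossOmic = co,
      snpsOfInterest = snpsOfInterest, generaOfInterest = generaOfInterest,
      edges = orderEdges(allEdges), network = network, loops = loops,
      loopNull = loopNull, cv = cv, config = cfg
    ),
    class = "PipelineResult"
  )
  if (!is.null(cfg$outdir)) writePipelineOutputs(result, cfg$outdir)
  result
}

#' @export
print.PipelineResult <- function(x, ...) {
  cat(sprintf(
    paste0(
      "PipelineResult: %d samples; %d association edges ",
      "(mgwas %d, persistence %d, diffabund %d, metabolite %d);\n",
      "  network %d nodes / %d edges; %d loops (%d meaningful); %s\n"
    ),
    nrow(x$cohort@genotype@mac), nrow(x$edges),
    nrow(x$mgwas$edges), nrow(x$persistence$edges),
    nrow(x$diffabund$edges), nrow(x$metaboliteScreen$edges) + nrow(x$crossOmic$edges),
    nrow(x$network@nodes), nrow(x$network@edges),
    nrow(x$loops), sum(x$loops$meaningful),
    if (is.null(x$cv)) "no cross-validation" else {
      sprintf("%d CV models", nrow(x$cv@results))
    }
  ))
  invisible(x)
}

# write every stage artifact plus a manifest; file set is fixed by content
writePipelineOutputs <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(name) {
    files <<- c(files, name)
    file.path(outdir, name)
  }
  writeEdges(result$edges, put("edges_all.tsv"))
  writeEdges(result$mgwas$edges, put("edges_mgwas.tsv"))
  writeEdges(result$persistence$edges, put("edges_persistence.tsv"))
  writeEdges(result$diffabund$edges, put("edges_diffabund.tsv"))
  writeEdges(rbind(result$metaboliteScreen$edges, result$crossOmic$edges),
    put("edges_metabolite.tsv"))
  writeTsv(result$mgwas$tests, put("tests_mgwas.tsv"))
  if (!is.null(result$persistence$tests)) {
    writeTsv(result$persistence$tests, put("tests_persistence.tsv"))
  }
  if (length(result$diffabund$tests)) {
    writeTsv(do.call(rbind, result$diffabund$tests), put("tests_diffabund.tsv"))
  }
  if (!is.null(result$metaboliteScreen$tests)) {
    writeTsv(result$metaboliteScreen$tests, put("tests_metabolite_screen.tsv"))
  }
  if (!is.null(result$crossOmic$tests)) {
    writeTsv(result$crossOmic$tests, put("tests_crossomic.tsv"))
  }
  for (fe in result$features) {
    writeTsv(fe@features, put(sprintf("features_age_%s.tsv", fe@age)))
    ld <- data.frame(genus = rownames(fe@loadings), fe@loadings,
      check.names = FALSE, stringsAsFactors = FALSE
    )
    writeTsv(ld, put(sprintf("loadings_age_%s.tsv", fe@age)))
  }
  if (nrow(result$network@edges)) {
    writeGraphML(result$network, put("network.graphml"))
  }
  writeLoopsJson(result$loops, put("loops.json"))
  if (!is.null(result$cv)) {
    writeTsv(result$cv@results, put("cv_report.tsv"))
    jsonlite::write_json(
      result$cv@results, put("cv_report.json"),
      dataframe = "rows", digits = NA
    )
  }
  cfg <- result$config
  hashable <- cfg[setdiff(names(cfg), c("cohort", "simulation", "outdir"))]
  manifest <- list(
    config = hashable,
    config_hash = stageSeed(
      0L,
      paste(deparse(hashable), collapse = "")
    ),
    seed = if (!is.null(cfg$simulation)) cfg$simulation$seed else NA,
    stage_rows = list(
      mgwas = nrow(result$mgwas$tests),
      persistence = if (is.null(result$persistence$tests)) 0L else nrow(result$persistence$tests),
      diffabund = sum(vapply(result$diffabund$tests, nrow, integer(1))),
      metabolite_screen = if (is.null(result$metaboliteScreen$tests)) 0L else nrow(result$metaboliteScreen$tests),
      crossomic = if (is.null(result$crossOmic$tests)) 0L else nrow(result$crossOmic$tests),
      edges = nrow(result$edges),
      loops = nrow(result$loops),
      meaningful_loops = sum(result$loops$meaningful)
    ),
    files = sort(files)
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(c(files, "manifest.json"))
}
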