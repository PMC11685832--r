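#' @include linear-model.R edges.R diffabund.R
NULL

# log metabolite abundances with a per-metabolite half-minimum pseudocount
# for exact zeros; all-zero metabolites become NA
logAbundance <- function(ab) {
  for (j in seq_len(ncol(ab))) {
    v <- ab[, j]
    nz <- !is.na(v) & v > 0
    if (any(nz)) {
      v[!is.na(v) & v == 0] <- min(v[nz]) / 2
    } else {
      v[] <- NA_real_
    }
    ab[, j] <- v
  }
  log(ab)
}

bmiMeasuresAt <- function(phenotypes, age) {
  j <- match(age, phenotypes@ages)
  if (is.na(j)) {
    stop("no BMI measurements at age ", age, call. = FALSE)
  }
  list(
    bmi_percentile = phenotypes@percentile[, j],
    bmi_category = phenotypes@category[, j]
  )
}

#' Screen metabolites against BMI and collect pathways of interest
#'
#' For every metabolite and each BMI measure (percentile and ordinal
#' category), fits a covariate-adjusted model with the log-transformed
#' metabolite abundance as response and the BMI measure as exposure.
#' Metabolites reaching \code{p < alpha} for either measure are collected,
#' and the set of their annotated pathways becomes the "pathways of
#' interest" carried into the cross-omic stage.
#'
#' @param metabolome a \code{\linkS4class{MetaboliteTable}}.
#' @param phenotypes a \code{\linkS4class{PhenotypeSeries}}.
#' @param age age (years) at which metabolome and BMI are matched (default 3).
#' @param alpha significance threshold (default 0.01).
#' @return list with \code{edges} (metabolite-bmi edges, stage
#'   \code{"metabolite"}), \code{tests}, \code{metabolites} (ids passing the
#'   screen) and \code{pathways_of_interest}.
#' @export
metaboliteBmiScreen <- function(metabolome, phenotypes, age = 3, alpha = 0.01) {
  stopifnot(is(metabolome, "MetaboliteTable"), is(phenotypes, "PhenotypeSeries"))
  measures <- bmiMeasuresAt(phenotypes, age)
  ids <- intersect(rownames(metabolome@abundance), rownames(phenotypes@percentile))
  la <- logAbundance(metabolome@abundance[ids, , drop = FALSE])
  C <- dummyEncode(phenotypes@covariates[ids, , drop = FALSE])
  tests <- list()
  for (meas in names(measures)) {
    x <- measures[[meas]][ids]
    for (met in colnames(la)) {
      y <- la[, met]
      if (stats::var(y, na.rm = TRUE) %in% c(0, NA)) next # zero-variance: skipped
      fit <- .fitLM(y, x, C, warnCollinear = FALSE)
      if (fit$degenerate) next
      tests[[length(tests) + 1L]] <- data.frame(
        metabolite = met, measure = meas, age = age,
        beta = fit$beta, se = fit$se, p = fit$p, n_used = fit$n_used,
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  hits <- if (is.null(tests)) NULL else tests[tests$p < alpha, , drop = FALSE]
  info <- metabolome@metabInfo
  mets <- unique(hits$metabolite)
  edges <- if (!is.null(hits) && nrow(hits)) {
    associationEdges(
      node_a = hits$metabolite, type_a = "metabolite",
      node_b = hits$measure, type_b = "bmi",
      age = as.character(hits$age), beta = hits$beta, se = hits$se,
      p = hits$p, q = NA_real_, stage = "metabolite",
      tier = NA_character_, n_used = hits$n_used
    )
  } else {
    emptyEdges()
  }
  list(
    edges = orderEdges(edges), tests = tests, metabolites = mets,
    pathways_of_interest = sort(unique(info$pathway[info$metabolite_id %in% mets]))
  )
}

#' Cross-omic metabolite tests with a two-omics selection rule
#'
#' Every metabolite annotated to a pathway of interest is tested, with
#' covariate adjustment and the log metabolite abundance as response,
#' against each partner variable: the BMI measures at the matching age, the
#' minor allele counts of the SNPs of interest, and the TSS-log abundances
#' of the genera of interest. A metabolite is selected when it has partners
#' at \code{p < alpha} in at least \code{minOmics} distinct omic types; all
#' significant edges of selected metabolites are emitted.
#'
#' @param metabolome a \code{\linkS4class{MetaboliteTable}}.
#' @param pathwaysOfInterest pathway names from
#'   \code{\link{metaboliteBmiScreen}}.
#' @param phenotypes a \code{\linkS4class{PhenotypeSeries}}.
#' @param genotype a \code{\linkS4class{GenotypeTable}}.
#' @param snpIds SNPs of interest.
#' @param microbiomeCounts \code{\linkS4class{MicrobiomeCounts}} at the
#'   matching age (source of the genus partners), or \code{NULL} if there
#'   are no genera of interest.
#' @param genusIds genera of interest (may be empty).
#' @param age matching age in years (default 3).
#' @param alpha per-test significance threshold (default 0.01).
#' @param minOmics minimum number of distinct partner omic types (default 2).
#' @return list with \code{edges} (all significant edges of selected
#'   metabolites), \code{tests}, and \code{selected} (metabolite ids).
#' @export
crossOmicMetaboliteTests <- function(metabolome, pathwaysOfInterest,
                                     phenotypes, genotype, snpIds,
                                     microbiomeCounts = NULL, genusIds = character(),
                                     age = 3, alpha = 0.01, minOmics = 2L) {
  stopifnot(is(metabolome, "MetaboliteTable"))
  if (length(pathwaysOfInterest) == 0L) {
    warning("no pathways of interest; nothing to test", call. = FALSE)
    return(list(edges = emptyEdges(), tests = NULL, selected = character()))
  }
  info <- metabolome@metabInfo
  cand <- info$metabolite_id[info$pathway %in% pathwaysOfInterest]
  if (length(cand) == 0L) {
    warning("no metabolite annotated to the pathways of interest", call. = FALSE)
    return(list(edges = emptyEdges(), tests = NULL, selected = character()))
  }
  ids <- rownames(metabolome@abundance)
  la <- logAbundance(metabolome@abundance[, cand, drop = FALSE])

  # partner variables: named list of (values over `ids`, omic type, node id)
  partners <- list()
  measures <- bmiMeasuresAt(phenotypes, age)
  pid <- intersect(ids, rownames(phenotypes@percentile))
  for (meas in names(measures)) {
    v <- rep(NA_real_, length(ids))
    v[match(pid, ids)] <- measures[[meas]][pid]
    partners[[meas]] <- list(values = v, type = "bmi", node = meas)
  }
  gid <- intersect(ids, rownames(genotype@mac))
  for (snp in snpIds) {
    v <- rep(NA_real_, length(ids))
    v[match(gid, ids)] <- genotype@mac[gid, snp]
    partners[[snp]] <- list(values = v, type = "genotype", node = snp)
  }
  if (length(genusIds) && !is.null(microbiomeCounts)) {
    glog <- tssLogAbundance(microbiomeCounts)
    mid <- intersect(ids, rownames(glog))
    for (g in intersect(genusIds, colnames(glog))) {
      v <- rep(NA_real_, length(ids))
      v[match(mid, ids)] <- glog[mid, g]
      partners[[g]] <- list(values = v, type = "microbiome", node = g)
    }
  }
  C <- dummyEncode(phenotypes@covariates[ids, , drop = FALSE])

  tests <- list()
  for (met in cand) {
    y <- la[, met]
    if (stats::var(y, na.rm = TRUE) %in% c(0, NA)) next
    for (pn in names(partners)) {
      pt <- partners[[pn]]
      fit <- .fitLM(y, pt$values, C, warnCollinear = FALSE)
      if (fit$degenerate) next
      tests[[length(tests) + 1L]] <- data.frame(
        metabolite = met, partner = pt$node, partner_type = pt$type, age = age,
        beta = fit$beta, se = fit$se, p = fit$p, n_used = fit$n_used,
        stringsAsFactors = FALSE
      )
    }
  }
  tests <- if (length(tests)) do.call(rbind, tests) else NULL
  if (is.null(tests)) {
    return(list(edges = emptyEdges(), tests = NULL, selected = character()))
  }
  sig <- tests[tests$p < alpha, , drop = FALSE]
  nOmics <- tapply(sig$partner_type, sig$metabolite, function(x) length(unique(x)))
  selected <- names(nOmics)[nOmics >= minOmics]
  keep <- sig[sig$metabolite %in% selected, , drop = FALSE]
  edges <- if (nrow(keep)) {
    associationEdges(
      node_a = keep$metabolite, type_a = "metabolite",
      node_b = keep$partner, type_b = keep$partner_type,
      age = as.character(keep$age), beta = keep$beta, se = keep$se,
      p = keep$p, q = NA_real_, stage = "metabolite",
      tier = NA_character_, n_used = keep$n_used
    )
  } else {
    emptyEdges()
  }
  list(edges = orderEdges(edges), tests = tests, selected = sort(selected))
}
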