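#' @include AllGenerics.R
NULL

#' @describeIn sampleIds samples genotyped.
#' @export
setMethod("sampleIds", "GenotypeTable", function(x) rownames(x@mac))

#' @describeIn sampleIds samples profiled at this age.
#' @export
setMethod("sampleIds", "MicrobiomeCounts", function(x) rownames(x@counts))

#' @describeIn sampleIds samples with metabolomics.
#' @export
setMethod("sampleIds", "MetaboliteTable", function(x) rownames(x@abundance))

#' @describeIn sampleIds samples in the phenotype series.
#' @export
setMethod("sampleIds", "PhenotypeSeries", function(x) rownames(x@percentile))

#' @describeIn sampleIds the cohort's full sample namespace.
#' @export
setMethod("sampleIds", "SyntheticCohort", function(x) rownames(x@genotype@mac))

#' @rdname macMatrix
#' @export
setMethod("macMatrix", "GenotypeTable", function(x) x@mac)

#' @rdname snpInfo
#' @export
setMethod("snpInfo", "GenotypeTable", function(x) x@snpInfo)

#' @rdname countsMatrix
#' @export
setMethod("countsMatrix", "MicrobiomeCounts", function(x) x@counts)

#' @rdname ageYears
#' @export
setMethod("ageYears", "MicrobiomeCounts", function(x) x@age)

#' @rdname ageYears
#' @export
setMethod("ageYears", "MicrobiomeFeatures", function(x) x@age)

#' @rdname abundanceMatrix
#' @export
setMethod("abundanceMatrix", "MetaboliteTable", function(x) x@abundance)

#' @rdname metaboliteInfo
#' @export
setMethod("metaboliteInfo", "MetaboliteTable", function(x) x@metabInfo)

#' @rdname bmiPercentile
#' @export
setMethod("bmiPercentile", "PhenotypeSeries", function(x) x@percentile)

#' @rdname bmiCategory
#' @export
setMethod("bmiCategory", "PhenotypeSeries", function(x) x@category)

#' @rdname covariates
#' @export
setMethod("covariates", "PhenotypeSeries", function(x) x@covariates)

#' @rdname phenotypeAges
#' @export
setMethod("phenotypeAges", "PhenotypeSeries", function(x) x@ages)

#' @rdname networkNodes
#' @export
setMethod("networkNodes", "OmicsNetwork", function(x) x@nodes)

#' @rdname networkEdges
#' @export
setMethod("networkEdges", "OmicsNetwork", function(x) x@edges)

#' @rdname featureTable
#' @export
setMethod("featureTable", "MicrobiomeFeatures", function(x) x@features)

#' @rdname mcpcLoadings
#' @export
setMethod("mcpcLoadings", "MicrobiomeFeatures", function(x) x@loadings)

#' @rdname cvResults
#' @export
setMethod("cvResults", "CvReport", function(x) x@results)

#' Accessors for slots of a SyntheticCohort
#'
#' @param x a \code{SyntheticCohort}.
#' @return the corresponding component: the \code{GenotypeTable}, the named
#'   list of per-age \code{MicrobiomeCounts}, the \code{MetaboliteTable}, the
#'   \code{PhenotypeSeries}, or the data.frame of planted ground-truth
#'   effects.
#' @name cohort-accessors
NULL

#' @rdname cohort-accessors
#' @export
genotype <- function(x) x@genotype

#' @rdname cohort-accessors
#' @export
microbiome <- function(x) x@microbiome

#' @rdname cohort-accessors
#' @export
metabolome <- function(x) x@metabolome

#' @rdname cohort-accessors
#' @export
phenotypes <- function(x) x@phenotypes

#' @rdname cohort-accessors
#' @export
plantedTruth <- function(x) x@truth

setMethod("show", "GenotypeTable", function(object) {
  cat(sprintf(
    "GenotypeTable: %d samples x %d SNPs (%d genes)\n",
    nrow(object@mac), ncol(object@mac), length(unique(object@snpInfo$gene))
  ))
})

setMethod("show", "MicrobiomeCounts", function(object) {
  cat(sprintf(
    "MicrobiomeCounts (age %g y): %d samples x %d genera, median depth %g\n",
    object@age, nrow(object@counts), ncol(object@counts),
    if (nrow(object@counts)) stats::median(rowSums(object@counts)) else NA
  ))
})

setMethod("show", "MetaboliteTable", function(object) {
  cat(sprintf(
    "MetaboliteTable: %d samples x %d metabolites in %d pathways\n",
    nrow(object@abundance), ncol(object@abundance),
    length(unique(object@metabInfo$pathway))
  ))
})

setMethod("show", "PhenotypeSeries", function(object) {
  cat(sprintf(
    "PhenotypeSeries: %d samples, BMI at ages %s\n",
    nrow(object@percentile), paste(object@ages, collapse = ", ")
  ))
})

setMethod("show", "SyntheticCohort", function(object) {
  cat(sprintf(
    "SyntheticCohort: %d samples; %d planted effects\n",
    nrow(object@genotype@mac), nrow(object@truth)
  ))
  show(object@genotype)
  for (mb in object@microbiome) show(mb)
  show(object@metabolome)
  show(object@phenotypes)
})

setMethod("show", "MicrobiomeFeatures", function(object) {
  k <- ncol(object@loadings)
  cat(sprintf(
    "MicrobiomeFeatures (age %g y): %d samples, %d MCPCs%s\n",
    object@age, nrow(object@features), k,
    if (isTRUE(object@converged)) "" else " [completion not converged]"
  ))
})

setMethod("show", "OmicsNetwork", function(object) {
  tab <- table(factor(object@nodes$type, levels = OMIC_TYPES))
  cat(sprintf(
    "OmicsNetwork: %d nodes (%s), %d signed edges\n",
    nrow(object@nodes),
    paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
    nrow(object@edges)
  ))
})

setMethod("show", "CvReport", function(object) {
  cat(sprintf(
    "CvReport: %d models, %d train / %d test samples, complete-case fraction %.2f\n",
    nrow(object@results), length(object@trainIds), length(object@testIds),
    object@completeFraction
  ))
})
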