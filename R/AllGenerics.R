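#' @include AllClasses.R
NULL

#' Sample identifiers of an omic table
#' @param x an omic table object.
#' @return character vector of sample ids.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Minor-allele-count matrix of a GenotypeTable
#' @param x a \code{GenotypeTable}.
#' @return numeric samples x SNPs matrix.
#' @export
setGeneric("macMatrix", function(x) standardGeneric("macMatrix"))

#' Per-SNP annotation of a GenotypeTable
#' @param x a \code{GenotypeTable}.
#' @return data.frame with snp_id, chrom, position, gene.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' Count matrix of a MicrobiomeCounts table
#' @param x a \code{MicrobiomeCounts}.
#' @return numeric samples x genera matrix.
#' @export
setGeneric("countsMatrix", function(x) standardGeneric("countsMatrix"))

#' Sampling age of a per-age table
#' @param x an object with an age slot.
#' @return numeric age in years.
#' @export
setGeneric("ageYears", function(x) standardGeneric("ageYears"))

#' Abundance matrix of a MetaboliteTable
#' @param x a \code{MetaboliteTable}.
#' @return numeric samples x metabolites matrix.
#' @export
setGeneric("abundanceMatrix", function(x) standardGeneric("abundanceMatrix"))

#' Metabolite-to-pathway annotation of a MetaboliteTable
#' @param x a \code{MetaboliteTable}.
#' @return data.frame with metabolite_id, pathway, super_pathway.
#' @export
setGeneric("metaboliteInfo", function(x) standardGeneric("metaboliteInfo"))

#' BMI percentile matrix of a PhenotypeSeries
#' @param x a \code{PhenotypeSeries}.
#' @return numeric samples x ages matrix.
#' @export
setGeneric("bmiPercentile", function(x) standardGeneric("bmiPercentile"))

#' Ordinal BMI category matrix of a PhenotypeSeries
#' @param x a \code{PhenotypeSeries}.
#' @return numeric samples x ages matrix with values 0-3.
#' @export
setGeneric("bmiCategory", function(x) standardGeneric("bmiCategory"))

#' Adjustment covariates of a PhenotypeSeries
#' @param x a \code{PhenotypeSeries}.
#' @return data.frame with factor columns race, sex, site.
#' @export
setGeneric("covariates", function(x) standardGeneric("covariates"))

#' Phenotype ages of a PhenotypeSeries
#' @param x a \code{PhenotypeSeries}.
#' @return numeric vector of ages in years.
#' @export
setGeneric("phenotypeAges", function(x) standardGeneric("phenotypeAges"))

#' Nodes of an OmicsNetwork
#' @param x an \code{OmicsNetwork}.
#' @return data.frame with columns id, type.
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))

#' Edges of an OmicsNetwork
#' @param x an \code{OmicsNetwork}.
#' @return data.frame of association edges.
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))

#' Feature table of a MicrobiomeFeatures object
#' @param x a \code{MicrobiomeFeatures}.
#' @return data.frame with richness, shannon and MCPC score columns.
#' @export
setGeneric("featureTable", function(x) standardGeneric("featureTable"))

#' Genus loadings of the MCPC components
#' @param x a \code{MicrobiomeFeatures}.
#' @return genera x k numeric matrix.
#' @export
setGeneric("mcpcLoadings", function(x) standardGeneric("mcpcLoadings"))

#' Per-response results of a CvReport
#' @param x a \code{CvReport}.
#' @return data.frame, one row per response variable.
#' @export
setGeneric("cvResults", function(x) standardGeneric("cvResults"))
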