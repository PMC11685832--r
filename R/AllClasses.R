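#' @import methods
NULL

#' Genotype table: minor allele counts with SNP annotation
#'
#' Samples-by-SNP matrix of minor allele counts (MAC; 0, 1, 2 or \code{NA})
#' together with per-SNP annotation (chromosome, 1-based position, gene
#' symbol). Row names are sample identifiers, column names SNP identifiers;
#' the annotation holds one row per SNP in matrix column order.
#'
#' @slot mac numeric matrix of minor allele counts in \{0, 1, 2, NA\}.
#' @slot snpInfo data.frame with columns \code{snp_id}, \code{chrom},
#'   \code{position}, \code{gene}.
#' @export
setClass("GenotypeTable",
  representation(mac = "matrix", snpInfo = "data.frame")
)

setValidity("GenotypeTable", function(object) {
  m <- object@mac
  info <- object@snpInfo
  msg <- character()
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)) > 0) {
    msg <- c(msg, "sample ids (rownames) must be unique and non-NULL")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) > 0) {
    msg <- c(msg, "snp ids (colnames) must be unique and non-NULL")
  }
  bad <- !is.na(m) & !(m %in% c(0, 1, 2))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1L, ]
    msg <- c(msg, sprintf(
      "minor allele counts must be 0/1/2 or NA; offending cell [%s, %s] = %s",
      rownames(m)[idx[1L]], colnames(m)[idx[2L]], m[idx[1L], idx[2L]]
    ))
  }
  need <- c("snp_id", "chrom", "position", "gene")
  if (!all(need %in% names(info))) {
    msg <- c(msg, paste("snpInfo must have columns", paste(need, collapse = ", ")))
  } else if (!identical(as.character(info$snp_id), colnames(m))) {
    msg <- c(msg, "snpInfo rows must match mac columns (same SNPs, same order)")
  }
  if (length(msg)) msg else TRUE
})

#' Genus-level microbiome count table at one age
#'
#' Samples-by-genus matrix of non-negative integer 16S read counts for a
#' single sampling age. Samples missing this omic at this age are absent from
#' the table (missingness is represented by absence, never by zeros).
#'
#' @slot counts numeric matrix of non-negative integer counts; rownames are
#'   sample ids, colnames genus ids.
#' @slot age numeric scalar, age in years.
#' @export
setClass("MicrobiomeCounts",
  representation(counts = "matrix", age = "numeric")
)

setValidity("MicrobiomeCounts", function(object) {
  m <- object@counts
  msg <- character()
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)) > 0) {
    msg <- c(msg, "sample ids (rownames) must be unique and non-NULL")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) > 0) {
    msg <- c(msg, "genus ids (colnames) must be unique and non-NULL")
  }
  if (anyNA(m) || any(m < 0) || any(m != round(m))) {
    msg <- c(msg, "counts must be non-negative integers with no NA")
  }
  if (nrow(m) > 0 && any(rowSums(m) == 0)) {
    msg <- c(msg, "retained samples must have per-sample total > 0")
  }
  if (length(object@age) != 1L || is.na(object@age) || object@age < 0) {
    msg <- c(msg, "age must be a single non-negative number")
  }
  if (length(msg)) msg else TRUE
})

#' Metabolite relative-abundance table with pathway annotation
#'
#' Samples-by-metabolite matrix of non-negative relative abundances, plus a
#' map from each metabolite to exactly one pathway and one super-pathway.
#'
#' @slot abundance numeric matrix of non-negative abundances.
#' @slot metabInfo data.frame with columns \code{metabolite_id},
#'   \code{pathway}, \code{super_pathway}.
#' @export
setClass("MetaboliteTable",
  representation(abundance = "matrix", metabInfo = "data.frame")
)

setValidity("MetaboliteTable", function(object) {
  m <- object@abundance
  info <- object@metabInfo
  msg <- character()
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)) > 0) {
    msg <- c(msg, "sample ids (rownames) must be unique and non-NULL")
  }
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)) > 0) {
    msg <- c(msg, "metabolite ids (colnames) must be unique and non-NULL")
  }
  if (any(!is.na(m) & m < 0)) msg <- c(msg, "abundances must be non-negative")
  need <- c("metabolite_id", "pathway", "super_pathway")
  if (!all(need %in% names(info))) {
    msg <- c(msg, paste("metabInfo must have columns", paste(need, collapse = ", ")))
  } else if (!identical(as.character(info$metabolite_id), colnames(m))) {
    msg <- c(msg, "metabInfo rows must match abundance columns")
  }
  if (length(msg)) msg else TRUE
})

#' Longitudinal BMI phenotypes and adjustment covariates
#'
#' Per-sample BMI percentile and ordinal BMI category (0-3, CDC-style
#' cutpoints at the 5th, 85th and 95th percentiles) at each phenotype age,
#' plus the categorical covariates (race, sex, site) used as adjustment in
#' every model. Missing measurements are \code{NA}; covariates are complete.
#'
#' @slot percentile numeric matrix (samples x ages) of BMI percentiles in
#'   [0, 100], \code{NA} where unmeasured.
#' @slot category numeric matrix of ordinal categories in \{0, 1, 2, 3\}.
#' @slot ages numeric vector of ages in years (matrix column order).
#' @slot covariates data.frame with factor columns \code{race}, \code{sex},
#'   \code{site}; rownames are sample ids.
#' @export
setClass("PhenotypeSeries",
  representation(
    percentile = "matrix", category = "matrix",
    ages = "numeric", covariates = "data.frame"
  )
)

setValidity("PhenotypeSeries", function(object) {
  msg <- character()
  p <- object@percentile
  k <- object@category
  if (is.null(rownames(p)) || anyDuplicated(rownames(p)) > 0) {
    msg <- c(msg, "sample ids (rownames) must be unique and non-NULL")
  }
  if (!identical(dim(p), dim(k)) || !identical(rownames(p), rownames(k))) {
    msg <- c(msg, "percentile and category matrices must be conformable")
  }
  if (ncol(p) != length(object@ages)) {
    msg <- c(msg, "one column per age required")
  }
  if (any(!is.na(p) & (p < 0 | p > 100))) {
    msg <- c(msg, "percentiles must lie in [0, 100]")
  }
  if (any(!is.na(k) & !(k %in% 0:3))) {
    msg <- c(msg, "categories must be ordinal 0-3")
  }
  cov <- object@covariates
  need <- c("race", "sex", "site")
  if (!all(need %in% names(cov))) {
    msg <- c(msg, "covariates must include race, sex, site")
  } else if (anyNA(cov[need])) {
    msg <- c(msg, "covariates must be present for every sample")
  }
  if (!identical(rownames(cov), rownames(p))) {
    msg <- c(msg, "covariate rows must match phenotype rows")
  }
  if (length(msg)) msg else TRUE
})

#' A simulated multi-omic cohort with ground truth
#'
#' The output of \code{\link{simulateCohort}}: the four omic tables on one
#' shared sample namespace, plus the list of planted cross-omic effects that
#' generated them (the ground truth downstream stages are tested against).
#'
#' @slot genotype a \code{GenotypeTable}.
#' @slot microbiome named list of \code{MicrobiomeCounts}, one per age
#'   (names are the ages).
#' @slot metabolome a \code{MetaboliteTable}.
#' @slot phenotypes a \code{PhenotypeSeries}.
#' @slot truth data.frame of planted effects (source/target/effect size/ages).
#' @slot config the \code{CohortConfig} the cohort was generated from.
#' @export
setClass("SyntheticCohort",
  representation(
    genotype = "GenotypeTable", microbiome = "list",
    metabolome = "MetaboliteTable", phenotypes = "PhenotypeSeries",
    truth = "data.frame", config = "list"
  )
)

setValidity("SyntheticCohort", function(object) {
  msg <- character()
  ids <- rownames(object@genotype@mac)
  others <- c(
    lapply(object@microbiome, function(x) rownames(x@counts)),
    list(rownames(object@metabolome@abundance), rownames(object@phenotypes@percentile))
  )
  if (!all(vapply(others, function(x) all(x %in% ids), logical(1)))) {
    msg <- c(msg, "all tables must share one sample-identifier namespace")
  }
  if (!all(vapply(object@microbiome, is, logical(1), "MicrobiomeCounts"))) {
    msg <- c(msg, "microbiome must be a list of MicrobiomeCounts")
  }
  if (length(msg)) msg else TRUE
})

#' Per-age microbiome features used as mGWAS phenotypes
#'
#' Alpha diversity (richness and Shannon entropy in nats) and robust
#' Aitchison principal-component scores (MCPCs) for the samples of one
#' microbiome age, with the genus loadings and the fraction of the observed
#' squared norm captured by each component.
#'
#' @slot age numeric age in years.
#' @slot features data.frame with columns \code{sample_id}, \code{richness},
#'   \code{shannon} and \code{mcpc1}..\code{mcpck}.
#' @slot loadings genera x k loading matrix (sign convention: largest-
#'   magnitude loading of each component is positive).
#' @slot explainedNormFraction numeric, per-component fraction of observed
#'   squared norm explained.
#' @slot converged logical, whether the matrix-completion iteration met its
#'   tolerance within the iteration cap.
#' @export
setClass("MicrobiomeFeatures",
  representation(
    age = "numeric", features = "data.frame", loadings = "matrix",
    explainedNormFraction = "numeric", converged = "logical"
  )
)

#' Typed, signed co-association network
#'
#' Undirected network whose nodes are omic variables (typed genotype /
#' microbiome / metabolite / bmi) and whose edges are the significant
#' cross-omic associations found by the testing stages; at most one edge per
#' node pair (smallest p retained, provenance of all merged stages kept).
#'
#' @slot nodes data.frame with columns \code{id}, \code{type}.
#' @slot edges data.frame of association edges (see
#'   \code{\link{associationEdges}} for the column contract).
#' @export
setClass("OmicsNetwork",
  representation(nodes = "data.frame", edges = "data.frame")
)

setValidity("OmicsNetwork", function(object) {
  msg <- character()
  e <- object@edges
  if (nrow(e)) {
    if (any(e$node_a == e$node_b)) msg <- c(msg, "self-edges are not allowed")
    key <- ifelse(e$node_a < e$node_b,
      paste(e$node_a, e$node_b), paste(e$node_b, e$node_a)
    )
    if (anyDuplicated(key) > 0) msg <- c(msg, "duplicate node pairs are not allowed")
    if (!all(c(e$node_a, e$node_b) %in% object@nodes$id)) {
      msg <- c(msg, "every edge endpoint must exist in nodes")
    }
  }
  if (anyDuplicated(object@nodes$id) > 0) msg <- c(msg, "node ids must be unique")
  if (!all(object@nodes$type %in% OMIC_TYPES)) {
    msg <- c(msg, paste("node types must be one of", paste(OMIC_TYPES, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Cross-validation report
#'
#' Per-response results of the leave-one-variable-out predictive validation:
#' training/test sizes, min-max-normalised mean squared error (reported x100
#' as percent) and fitted coefficients, plus the split bookkeeping.
#'
#' @slot results data.frame, one row per response variable.
#' @slot models named list of fitted models (coefficients, predictors,
#'   excluded predictors, training bounds).
#' @slot trainIds,testIds character sample ids of the split.
#' @slot completeFraction numeric, fraction of the test set with complete
#'   measurements across all loop variables and covariates.
#' @slot seed numeric, split seed.
#' @export
setClass("CvReport",
  representation(
    results = "data.frame", models = "list",
    trainIds = "character", testIds = "character",
    completeFraction = "numeric", seed = "numeric"
  )
)
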