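#' @include linear-model.R edges.R
NULL

#' Total-sum-scaled, pseudocounted, log-transformed genus abundances
#'
#' The normalisation used by the differential-abundance stage and wherever a
#' genus enters a linear model as a continuous variable: counts are divided
#' by the per-sample total (TSS), zeros are replaced per genus by half of
#' that genus's smallest nonzero proportion, and the result is
#' log-transformed. Genera with no nonzero count at all remain \code{NA}.
#'
#' @param counts a \code{\linkS4class{MicrobiomeCounts}} or count matrix.
#' @return numeric matrix of log-proportions, same dimensions.
#' @export
tssLogAbundance <- function(counts) {
  m <- asCountMatrix(counts)
  prop <- m / rowSums(m)
  for (j in seq_len(ncol(prop))) {
    nz <- prop[, j] > 0
    if (any(nz)) {
      prop[!nz, j] <- min(prop[nz, j]) / 2
    } else {
      prop[, j] <- NA_real_
    }
  }
  log(prop)
}

#' Genus-level differential abundance against SNPs of interest
#'
#' A multivariable association recipe for genus counts: genera are filtered
#' to a minimum prevalence, TSS-normalised with a per-genus half-minimum
#' pseudocount, log-transformed, and each genus is regressed on the minor
#' allele count of each SNP of interest with covariate adjustment.
#' Benjamini-Hochberg correction is applied across genera within each
#' (age, SNP) family and edges are emitted at \code{q < qThreshold}, signed
#' by the fitted slope.
#'
#' @param counts a \code{\linkS4class{MicrobiomeCounts}} (one age).
#' @param genotype a \code{\linkS4class{GenotypeTable}}.
#' @param snpIds SNPs of interest (exposures); must exist in the genotype.
#' @param covariates covariate data.frame with sample-id rownames.
#' @param qThreshold BH q-value cutoff (default 0.05).
#' @param prevalenceMin minimum fraction of samples with a nonzero count for
#'   a genus to enter testing and the BH family (default 0.1).
#' @return list with \code{edges} (genotype-microbiome edges, stage
#'   \code{"diffabund"}) and \code{tests} (full table with q-values).
#' @export
differentialAbundance <- function(counts, genotype, snpIds, covariates,
                                  qThreshold = 0.05, prevalenceMin = 0.1) {
  stopifnot(is(counts, "MicrobiomeCounts"), is(genotype, "GenotypeTable"))
  missing_snps <- setdiff(snpIds, colnames(genotype@mac))
  if (length(missing_snps)) {
    stop("unknown SNP id(s): ", paste(missing_snps, collapse = ", "), call. = FALSE)
  }
  m <- counts@counts
  prev <- colMeans(m > 0)
  keep <- prev >= prevalenceMin
  if (!any(keep)) {
    warning("no genus passes the prevalence filter at age ", counts@age,
      call. = FALSE
    )
    return(list(edges = emptyEdges(), tests = NULL))
  }
  la <- tssLogAbundance(m)[, keep, drop = FALSE]
  ids <- intersect(rownames(la), rownames(genotype@mac))
  C <- dummyEncode(covariates[ids, , drop = FALSE])
  la <- la[ids, , drop = FALSE]
  mac <- genotype@mac[ids, , drop = FALSE]
  tests <- list()
  for (snp in snpIds) {
    fam <- list()
    for (g in colnames(la)) {
      fit <- .fitLM(la[, g], mac[, snp], C, warnCollinear = FALSE)
      if (fit$degenerate) next
      fam[[length(fam) + 1L]] <- data.frame(
        snp = snp, genus = g, age = counts@age,
        beta = fit$beta, se = fit$se, p = fit$p, n_used = fit$n_used,
        stringsAsFactors = FALSE
      )
    }
    if (length(fam)) {
      fam <- do.call(rbind, fam)
      fam$q <- bhAdjust(fam$p)
      tests[[length(tests) + 1L]] <- fam
    }
  }
  if (!length(tests)) {
    return(list(edges = emptyEdges(), tests = NULL))
  }
  tests <- do.call(rbind, tests)
  hits <- tests[tests$q < qThreshold, , drop = FALSE]
  edges <- if (nrow(hits)) {
    associationEdges(
      node_a = hits$snp, type_a = "genotype",
      node_b = hits$genus, type_b = "microbiome",
      age = as.character(hits$age), beta = hits$beta, se = hits$se,
      p = hits$p, q = hits$q, stage = "diffabund",
      tier = NA_character_, n_used = hits$n_used
    )
  } else {
    emptyEdges()
  }
  list(edges = orderEdges(edges), tests = tests)
}
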