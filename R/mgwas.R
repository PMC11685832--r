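#' @include linear-model.R edges.R microbiome-features.R
NULL

#' Group SNPs with highly correlated minor allele counts
#'
#' Single-linkage grouping: two SNPs are linked when the absolute Pearson
#' correlation of their minor allele counts (pairwise-complete) reaches
#' \code{rThreshold}, and groups are the connected components of that link
#' graph. Group members are treated as interchangeable tags of one signal:
#' they are excluded from serving as each other's predictors in the
#' cross-validation stage.
#'
#' @param genotype a \code{\linkS4class{GenotypeTable}}.
#' @param rThreshold absolute-correlation threshold in (0, 1] (default 0.9).
#' @return an object of class \code{SnpGroups}: list with \code{membership}
#'   (named integer vector, SNP id -> group index) and \code{groups} (list of
#'   member id vectors; singletons included).
#' @export
collapseCorrelatedSnps <- function(genotype, rThreshold = 0.9) {
  stopifnot(is(genotype, "GenotypeTable"))
  if (rThreshold <= 0 || rThreshold > 1) {
    stop("rThreshold must lie in (0, 1]", call. = FALSE)
  }
  m <- genotype@mac
  snps <- colnames(m)
  p <- length(snps)
  parent <- seq_len(p)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  if (p > 1L) {
    cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
    cc[is.na(cc)] <- 0
    for (i in seq_len(p - 1L)) {
      for (j in (i + 1L):p) {
        if (abs(cc[i, j]) >= rThreshold) {
          ri <- find(i)
          rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(p), find, integer(1))
  membership <- match(roots, unique(roots))
  names(membership) <- snps
  groups <- split(snps, membership)
  names(groups) <- NULL
  structure(list(membership = membership, groups = groups), class = "SnpGroups")
}

#' @export
print.SnpGroups <- function(x, ...) {
  multi <- Filter(function(g) length(g) > 1L, x$groups)
  cat(sprintf(
    "SnpGroups: %d SNPs in %d groups (%d with >1 member)\n",
    length(x$membership), length(x$groups), length(multi)
  ))
  for (g in multi) cat("  {", paste(g, collapse = ", "), "}\n")
  invisible(x)
}

#' Targeted microbiome GWAS over candidate-gene SNPs
#'
#' Fits one covariate-adjusted linear model per (SNP, microbiome feature,
#' age), with the feature (richness, Shannon, MCPC scores) as response and
#' the SNP's minor allele count as exposure. The Bonferroni family size
#' \code{m} is the number of tests actually performed (degenerate fits are
#' excluded), so the significance threshold is \code{alpha / m}; tests below
#' \code{suggestive} that miss Bonferroni are emitted in a separate
#' "suggestive" tier.
#'
#' @param genotype a \code{\linkS4class{GenotypeTable}} restricted to the
#'   candidate-gene panel.
#' @param featuresList list of \code{\linkS4class{MicrobiomeFeatures}}, one
#'   per microbiome age.
#' @param covariates data.frame of adjustment covariates with sample ids as
#'   rownames (race, sex, site).
#' @param alpha family-wise error target for the Bonferroni tier (default
#'   0.05).
#' @param suggestive p-value cutoff of the suggestive tier (default 1e-5).
#' @param featureNames which feature columns to test (default richness,
#'   shannon and all MCPC columns present).
#' @return list with \code{edges} (genotype-microbiome association edges,
#'   both tiers), \code{tests} (the full test table, for audit), \code{m}
#'   (family size) and \code{bonferroni_threshold}.
#' @export
targetedMgwas <- function(genotype, featuresList, covariates,
                          alpha = 0.05, suggestive = 1e-5,
                          featureNames = NULL) {
  stopifnot(is(genotype, "GenotypeTable"), length(featuresList) > 0)
  mac <- genotype@mac
  rows <- list()
  for (fe in featuresList) {
    stopifnot(is(fe, "MicrobiomeFeatures"))
    ft <- fe@features
    fn <- featureNames %||% setdiff(names(ft), "sample_id")
    fn <- intersect(fn, names(ft))
    ids <- intersect(ft$sample_id, rownames(mac))
    if (length(ids) == 0L) {
      warning("age ", fe@age, ": no overlap between features and genotype; skipped",
        call. = FALSE
      )
      next
    }
    C <- dummyEncode(covariates[ids, , drop = FALSE])
    fmat <- ft[match(ids, ft$sample_id), fn, drop = FALSE]
    for (feat in fn) {
      y <- fmat[[feat]]
      for (snp in colnames(mac)) {
        fit <- .fitLM(y, mac[ids, snp], C, warnCollinear = FALSE)
        if (fit$degenerate) next
        rows[[length(rows) + 1L]] <- data.frame(
          snp = snp, feature = feat, age = fe@age,
          beta = fit$beta, se = fit$se, p = fit$p, n_used = fit$n_used,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  tests <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      snp = character(), feature = character(), age = numeric(),
      beta = numeric(), se = numeric(), p = numeric(), n_used = integer(),
      stringsAsFactors = FALSE
    )
  }
  m <- nrow(tests)
  thr <- if (m > 0) alpha / m else NA_real_
  sig <- tests[!is.na(tests$p) & tests$p < (thr %||% 0), , drop = FALSE]
  sug <- tests[!is.na(tests$p) & tests$p < suggestive & tests$p >= (thr %||% 0), ,
    drop = FALSE
  ]
  mkEdges <- function(tt, tier) {
    if (nrow(tt) == 0L) {
      return(emptyEdges())
    }
    associationEdges(
      node_a = tt$snp, type_a = "genotype",
      node_b = paste0(tt$feature, "@", tt$age), type_b = "microbiome",
      age = as.character(tt$age), beta = tt$beta, se = tt$se, p = tt$p,
      q = NA_real_, stage = "mgwas", tier = tier, n_used = tt$n_used
    )
  }
  edges <- orderEdges(rbind(mkEdges(sig, "significant"), mkEdges(sug, "suggestive")))
  list(edges = edges, tests = tests, m = m, bonferroni_threshold = thr)
}
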