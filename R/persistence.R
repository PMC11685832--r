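#' @include linear-model.R edges.R
NULL

# maximal runs of TRUE in `ok`, split further wherever `sgn` changes (when
# sign consistency is required); returns list of index vectors
consecutiveRuns <- function(ok, sgn = NULL) {
  runs <- list()
  start <- NULL
  for (i in seq_along(ok)) {
    open <- !is.null(start)
    if (ok[i] && (!open || is.null(sgn) || sgn[i] == sgn[i - 1L])) {
      if (!open) start <- i
    } else {
      if (open) runs[[length(runs) + 1L]] <- start:(i - 1L)
      start <- if (ok[i]) i else NULL
    }
  }
  if (!is.null(start)) runs[[length(runs) + 1L]] <- start:length(ok)
  runs
}

#' Persistent SNP-BMI association scan across consecutive ages
#'
#' For every SNP and each BMI measure (percentile and ordinal category,
#' scanned separately), fits one covariate-adjusted model per age with the
#' measure as response and the minor allele count as exposure. A SNP-BMI
#' edge is emitted whenever the per-age p-values stay below \code{alpha} for
#' at least \code{kConsecutive} consecutive ages (and, by default, the slope
#' keeps one sign across the run). The emitted edge carries the slope and
#' p-value of the age with the smallest p inside the run and records the
#' run's age range.
#'
#' @param genotype a \code{\linkS4class{GenotypeTable}}.
#' @param phenotypes a \code{\linkS4class{PhenotypeSeries}}.
#' @param alpha per-age significance threshold (default 0.01).
#' @param kConsecutive minimum run length in ages (default 5).
#' @param requireConsistentSign if \code{TRUE} (default) a run must keep one
#'   slope sign throughout.
#' @return list with \code{edges} (genotype-bmi edges, stage
#'   \code{"persistence"}) and \code{tests} (the full per-age test table).
#' @export
persistentBmiScan <- function(genotype, phenotypes, alpha = 0.01,
                              kConsecutive = 5L, requireConsistentSign = TRUE) {
  stopifnot(is(genotype, "GenotypeTable"), is(phenotypes, "PhenotypeSeries"))
  ages <- phenotypes@ages
  if (length(ages) < kConsecutive) {
    warning(
      "only ", length(ages), " BMI ages available; at least ", kConsecutive,
      " are needed for a persistent run",
      call. = FALSE
    )
    return(list(edges = emptyEdges(), tests = NULL))
  }
  ids <- intersect(rownames(genotype@mac), rownames(phenotypes@percentile))
  mac <- genotype@mac[ids, , drop = FALSE]
  C <- dummyEncode(phenotypes@covariates[ids, , drop = FALSE])
  measures <- list(
    bmi_percentile = phenotypes@percentile[ids, , drop = FALSE],
    bmi_category = phenotypes@category[ids, , drop = FALSE]
  )
  ord <- order(ages)
  tests <- list()
  edges <- emptyEdges()
  for (meas in names(measures)) {
    ymat <- measures[[meas]]
    for (snp in colnames(mac)) {
      beta <- se <- p <- rep(NA_real_, length(ages))
      nu <- rep(NA_integer_, length(ages))
      for (j in seq_along(ages)) {
        fit <- .fitLM(ymat[, j], mac[, snp], C, warnCollinear = FALSE)
        if (!fit$degenerate) {
          beta[j] <- fit$beta
          se[j] <- fit$se
          p[j] <- fit$p
          nu[j] <- fit$n_used
        }
      }
      tests[[length(tests) + 1L]] <- data.frame(
        snp = snp, measure = meas, age = ages, beta = beta, se = se, p = p,
        n_used = nu, stringsAsFactors = FALSE
      )
      ok <- !is.na(p[ord]) & p[ord] < alpha
      sgn <- sign(beta[ord])
      runs <- consecutiveRuns(ok, if (requireConsistentSign) sgn else NULL)
      for (run in Filter(function(r) length(r) >= kConsecutive, runs)) {
        best <- run[which.min(p[ord][run])]
        j <- ord[best]
        edges <- rbind(edges, associationEdges(
          node_a = snp, type_a = "genotype",
          node_b = meas, type_b = "bmi",
          age = paste0(ages[ord][run[1L]], "-", ages[ord][run[length(run)]]),
          beta = beta[j], se = se[j], p = p[j], q = NA_real_,
          stage = "persistence", tier = NA_character_, n_used = nu[j]
        ))
      }
    }
  }
  list(edges = orderEdges(edges), tests = do.call(rbind, tests))
}
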