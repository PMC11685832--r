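#' @include AllClasses.R
NULL

asCountMatrix <- function(counts) {
  if (is(counts, "MicrobiomeCounts")) counts@counts else as.matrix(counts)
}

#' Alpha diversity: richness and Shannon entropy
#'
#' Richness is the number of genera with a nonzero count; Shannon entropy is
#' \eqn{-\sum_i p_i \log p_i} (nats) over the nonzero proportions of each
#' sample. Samples whose total count is zero cannot be scored and are
#' excluded with a warning.
#'
#' @param counts a \code{\linkS4class{MicrobiomeCounts}} or a samples x
#'   genera count matrix.
#' @return data.frame with columns \code{sample_id}, \code{richness},
#'   \code{shannon}.
#' @export
#' @examples
#' alphaDiversity(matrix(c(3, 0, 1, 5, 5, 0), 2, byrow = TRUE,
#'   dimnames = list(c("a", "b"), NULL)
#' ))
alphaDiversity <- function(counts) {
  m <- asCountMatrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) {
    warning(
      sum(tot == 0), " all-zero sample(s) excluded from alpha diversity: ",
      paste(utils::head(rownames(m)[tot == 0], 5L), collapse = ", "),
      call. = FALSE
    )
    m <- m[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  p <- m / tot
  shannon <- -rowSums(ifelse(p > 0, p * log(p), 0))
  data.frame(
    sample_id = rownames(m),
    richness = as.integer(rowSums(m > 0)),
    shannon = shannon,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Robust centred log-ratio transform
#'
#' For each sample, nonzero counts are log-transformed and centred by the
#' mean log over that sample's nonzero genera only; zero counts become
#' \code{NA} (structural missingness under the robust clr, not small
#' values). The transform is invariant to multiplying a sample's counts by
#' any positive scalar.
#'
#' @param counts a \code{\linkS4class{MicrobiomeCounts}} or count matrix
#'   with per-sample totals > 0.
#' @return numeric matrix, same dimensions, with \code{NA} at zero cells.
#' @export
#' @examples
#' rclrTransform(matrix(c(1, exp(1), exp(2)), 1))
rclrTransform <- function(counts) {
  m <- asCountMatrix(counts)
  if (any(rowSums(m) == 0)) {
    stop("rclr requires per-sample total > 0", call. = FALSE)
  }
  lg <- ifelse(m > 0, log(m), NA_real_)
  lg - rowMeans(lg, na.rm = TRUE)
}

#' Robust Aitchison PCA by iterative SVD matrix completion
#'
#' Fits a rank-\code{k} principal-component model to an rclr matrix using
#' only its observed (non-missing) cells. Missing cells are initialised at
#' zero; the algorithm then alternates a column-centred rank-\code{k} SVD
#' with refilling the missing cells from the low-rank reconstruction, until
#' the relative change of the reconstruction (Frobenius norm over observed
#' cells) drops below \code{tol} (default 1e-4, at which point the scores are stable to well under one percent) or \code{maxIter} is reached. On a dense
#' matrix the iteration terminates immediately and the scores equal
#' classical PCA scores of the column-centred matrix up to component sign.
#' Each component's loading vector is flipped so that its largest-magnitude
#' loading is positive.
#'
#' @param x numeric matrix with \code{NA} for missing cells (e.g. the output
#'   of \code{\link{rclrTransform}}).
#' @param k number of components (>= 1, at most \code{min(dim(x)) - 1}).
#' @param maxIter iteration cap (default 500).
#' @param tol relative convergence tolerance (default 1e-4).
#' @return list with \code{scores} (samples x k), \code{loadings}
#'   (features x k), \code{d} (singular values),
#'   \code{explained_norm_fraction}, \code{converged}, \code{iterations}.
#' @export
robustAitchisonPCA <- function(x, k = 2L, maxIter = 500L, tol = 1e-4) {
  x <- as.matrix(x)
  if (k < 1L) stop("k must be >= 1", call. = FALSE)
  if (k > min(dim(x)) - 1L) {
    stop(
      "k = ", k, " exceeds the maximum fittable rank ", min(dim(x)) - 1L,
      " for a ", nrow(x), " x ", ncol(x), " matrix",
      call. = FALSE
    )
  }
  if (nrow(x) < k + 1L) stop("need at least k + 1 samples", call. = FALSE)
  obs <- !is.na(x)
  if (any(rowSums(obs) == 0L)) {
    stop("every sample needs at least one observed cell", call. = FALSE)
  }
  X <- x
  X[!obs] <- 0
  obsNorm <- sqrt(sum(x[obs]^2))
  if (obsNorm == 0) obsNorm <- 1
  prevRecon <- NULL
  converged <- FALSE
  iter <- 0L
  dense <- all(obs)
  repeat {
    iter <- iter + 1L
    mu <- colMeans(X)
    Xc <- sweep(X, 2L, mu)
    sv <- svd(Xc, nu = k, nv = k)
    recon <- sv$u %*% (sv$d[seq_len(k)] * t(sv$v)) # rank-k, centred scale
    reconFull <- sweep(recon, 2L, mu, `+`)
    if (!is.null(prevRecon)) {
      delta <- sqrt(sum((reconFull[obs] - prevRecon[obs])^2)) / obsNorm
      if (delta < tol) {
        converged <- TRUE
        break
      }
    }
    if (dense) {
      converged <- TRUE
      break
    }
    if (iter >= maxIter) break
    prevRecon <- reconFull
    X[!obs] <- reconFull[!obs]
  }
  if (!converged) {
    warning("matrix completion did not converge within ", maxIter,
      " iterations; returning the last iterate",
      call. = FALSE
    )
  }
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v
  flip <- vapply(
    seq_len(k),
    function(j) sign(loadings[which.max(abs(loadings[, j])), j]),
    numeric(1)
  )
  flip[flip == 0] <- 1
  scores <- sweep(scores, 2L, flip, `*`)
  loadings <- sweep(loadings, 2L, flip, `*`)
  rownames(scores) <- rownames(x)
  rownames(loadings) <- colnames(x)
  colnames(scores) <- colnames(loadings) <- paste0("mcpc", seq_len(k))
  totalNorm <- sum(Xc^2)
  list(
    scores = scores, loadings = loadings, d = sv$d[seq_len(k)],
    explained_norm_fraction = if (totalNorm > 0) sv$d[seq_len(k)]^2 / totalNorm else rep(0, k),
    converged = converged, iterations = iter
  )
}

#' Per-age microbiome features for the targeted mGWAS
#'
#' Computes richness, Shannon entropy and the first \code{k} robust
#' Aitchison principal-component scores (MCPCs) for one age's genus count
#' table. These per-sample features are the phenotypes of the targeted
#' microbiome GWAS.
#'
#' @param counts a \code{\linkS4class{MicrobiomeCounts}}.
#' @param k number of MCPCs (default 2; components beyond the second are
#'   rarely interpretable at genus level).
#' @param maxIter,tol matrix-completion controls, see
#'   \code{\link{robustAitchisonPCA}}.
#' @return a \code{\linkS4class{MicrobiomeFeatures}}.
#' @export
#' @examples
#' cfg <- cohortConfig(nSamples = 40, nGenera = 12, seed = 3)
#' mb <- microbiome(simulateCohort(cfg))[["3"]]
#' microbiomeFeatures(mb)
microbiomeFeatures <- function(counts, k = 2L, maxIter = 500L, tol = 1e-4) {
  stopifnot(is(counts, "MicrobiomeCounts"))
  alpha <- alphaDiversity(counts)
  rc <- rclrTransform(counts@counts[alpha$sample_id, , drop = FALSE])
  pca <- robustAitchisonPCA(rc, k = k, maxIter = maxIter, tol = tol)
  feats <- cbind(alpha, as.data.frame(pca$scores))
  rownames(feats) <- NULL
  new("MicrobiomeFeatures",
    age = counts@age, features = feats, loadings = pca$loadings,
    explainedNormFraction = pca$explained_norm_fraction,
    converged = pca$converged
  )
}
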