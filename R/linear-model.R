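#' @include utils.R
NULL

# dummy-encode a covariate data.frame (first level of each factor is the
# reference); returns a plain numeric matrix aligned to the input rows
dummyEncode <- function(covariates) {
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0L) {
    return(NULL)
  }
  covariates <- as.data.frame(covariates)
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (!is.factor(v)) v <- factor(v)
    lv <- levels(v)
    if (length(lv) < 2L) {
      return(NULL)
    }
    m <- vapply(lv[-1L], function(l) as.numeric(v == l), numeric(length(v)))
    colnames(m) <- paste0(nm, lv[-1L])
    m
  })
  cols <- Filter(Negate(is.null), cols)
  if (!length(cols)) {
    return(NULL)
  }
  out <- do.call(cbind, cols)
  rownames(out) <- rownames(covariates)
  out
}

#' Covariate-adjusted ordinary least squares for one exposure
#'
#' Fits \code{response ~ exposure + covariates} by QR least squares after
#' listwise deletion and reports the exposure coefficient's slope, standard
#' error and two-sided t-test p-value. Categorical covariates are
#' dummy-encoded with the first level as reference; covariate columns that
#' are collinear in the retained rows are dropped with a warning. A constant
#' exposure (after deletion) or fewer than \code{minN} complete rows yields a
#' degenerate fit (\code{degenerate = TRUE}) rather than numbers.
#'
#' @param response numeric response vector.
#' @param exposure numeric exposure vector (same length).
#' @param covariates optional data.frame of categorical adjustment covariates
#'   (same rows), or a pre-built numeric dummy matrix.
#' @param minN minimum number of complete rows required (default 10).
#' @return an object of class \code{LinearFit}: a list with \code{beta},
#'   \code{se}, \code{p} (the exposure coefficient), \code{coefficients},
#'   \code{se_all}, \code{p_all} (all terms), \code{df}, \code{n_used} and
#'   \code{degenerate}.
#' @export
#' @examples
#' fit <- fitLM(rnorm(50), rnorm(50))
#' fit$p
fitLM <- function(response, exposure, covariates = NULL, minN = 10L) {
  C <- if (is.matrix(covariates)) covariates else dummyEncode(covariates)
  .fitLM(as.numeric(response), as.numeric(exposure), C, minN = minN)
}

# internal engine; C is NULL or a numeric dummy matrix (rows aligned)
.fitLM <- function(y, x, C = NULL, minN = 10L, warnCollinear = TRUE) {
  degenerate <- function(reason) {
    structure(
      list(
        beta = NA_real_, se = NA_real_, p = NA_real_,
        coefficients = NULL, se_all = NULL, p_all = NULL,
        df = NA_integer_, n_used = 0L, degenerate = TRUE, reason = reason
      ),
      class = "LinearFit"
    )
  }
  keep <- !is.na(y) & !is.na(x)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  n <- sum(keep)
  if (n < minN) {
    return(degenerate(sprintf("only %d complete rows (minimum %d)", n, minN)))
  }
  y <- y[keep]
  x <- x[keep]
  if (stats::var(x) == 0) {
    return(degenerate("exposure is constant after listwise deletion"))
  }
  X <- cbind(`(Intercept)` = 1, exposure = x)
  if (!is.null(C)) X <- cbind(X, C[keep, , drop = FALSE])
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    if ("exposure" %in% dropped) {
      return(degenerate("exposure collinear with covariates"))
    }
    if (warnCollinear) {
      warning(
        "dropping collinear covariate column(s): ",
        paste(dropped, collapse = ", "),
        call. = FALSE
      )
    }
    X <- X[, setdiff(colnames(X), dropped), drop = FALSE]
    qrX <- qr(X)
  }
  p <- ncol(X)
  df <- n - p
  if (df < 1L) {
    return(degenerate("no residual degrees of freedom"))
  }
  coefs <- qr.coef(qrX, y)
  res <- y - qr.fitted(qrX, y)
  sigma2 <- sum(res^2) / df
  XtXinv <- chol2inv(chol(crossprod(X)))
  se <- sqrt(pmax(diag(XtXinv) * sigma2, 0))
  tval <- coefs / se
  pval <- 2 * stats::pt(-abs(tval), df)
  structure(
    list(
      beta = unname(coefs["exposure"]),
      se = unname(se[match("exposure", colnames(X))]),
      p = unname(pval[match("exposure", colnames(X))]),
      coefficients = coefs,
      se_all = stats::setNames(se, colnames(X)),
      p_all = stats::setNames(pval, colnames(X)),
      df = df, n_used = n, degenerate = FALSE, reason = NA_character_
    ),
    class = "LinearFit"
  )
}

#' @export
print.LinearFit <- function(x, ...) {
  if (isTRUE(x$degenerate)) {
    cat("LinearFit: degenerate (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf(
      "LinearFit: beta = %.4g (se %.3g), p = %.3g, n = %d, df = %d\n",
      x$beta, x$se, x$p, x$n_used, x$df
    ))
  }
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up q-values with monotonicity enforcement, as implemented by
#' \code{\link[stats]{p.adjust}} with \code{method = "BH"}.
#'
#' @param p numeric vector of raw p-values in (0, 1].
#' @return q-values, same length and order as \code{p}.
#' @export
#' @examples
#' bhAdjust(c(0.01, 0.02, 0.03, 0.04))
bhAdjust <- function(p) {
  if (length(p) == 0L) {
    return(numeric(0))
  }
  stats::p.adjust(p, method = "BH")
}
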