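#' @include linear-model.R AllClasses.R
NULL

#' Deterministic train/test split of sample ids
#'
#' Uniform random partition without replacement: \code{floor(n * fraction)}
#' samples train, the rest test; disjoint and exhaustive, identical under a
#' fixed seed.
#'
#' @param sampleIds character vector of sample ids (>= 20).
#' @param trainFraction fraction of samples to train on, in (0, 1).
#' @param seed integer seed.
#' @return list with \code{train} and \code{test} id vectors.
#' @export
#' @examples
#' splitSamples(sprintf("S%03d", 1:100), 0.7, seed = 1)$train[1:5]
splitSamples <- function(sampleIds, trainFraction = 0.7, seed = 1L) {
  if (trainFraction <= 0 || trainFraction >= 1) {
    stop("trainFraction must lie in (0, 1)", call. = FALSE)
  }
  if (length(sampleIds) < 20L) {
    stop("need at least 20 samples to split", call. = FALSE)
  }
  # ceiling keeps the test side at exactly floor(n * (1 - trainFraction))
  nTrain <- ceiling(length(sampleIds) * trainFraction - 1e-9)
  train <- withSeed(seed, sort(sample(sampleIds, nTrain)))
  list(train = train, test = sort(setdiff(sampleIds, train)))
}

#' Fit one leave-one-variable-out model per loop variable
#'
#' For each variable appearing in the meaningful loops, fits an ordinary
#' least-squares model on the training samples with that variable as
#' response and all other loop variables as predictors -- except members of
#' the response's correlated-SNP group, which tag the same genetic signal
#' and are excluded -- always adjusted for the covariates. Each model uses
#' its own complete training rows and is skipped (with a warning) when fewer
#' than \code{predictors + 5} remain.
#'
#' @param loopData numeric data.frame/matrix of per-sample loop-variable
#'   values (rownames are sample ids, one column per variable).
#' @param varTypes named character vector, variable -> omic type.
#' @param covariates covariate data.frame (sample-id rownames).
#' @param trainIds training sample ids.
#' @param snpGroups optional \code{SnpGroups} from
#'   \code{\link{collapseCorrelatedSnps}}; drives the correlated-SNP
#'   exclusion.
#' @return an object of class \code{LoopModelSet}.
#' @export
fitLoopModels <- function(loopData, varTypes, covariates, trainIds,
                          snpGroups = NULL) {
  loopData <- as.data.frame(loopData)
  vars <- colnames(loopData)
  stopifnot(all(vars %in% names(varTypes)))
  C <- dummyEncode(covariates[rownames(loopData), , drop = FALSE])
  train <- intersect(trainIds, rownames(loopData))
  models <- list()
  for (v in vars) {
    excluded <- character()
    if (!is.null(snpGroups) && v %in% names(snpGroups$membership)) {
      grp <- snpGroups$membership[v]
      mates <- names(snpGroups$membership)[snpGroups$membership == grp]
      excluded <- setdiff(intersect(mates, vars), v)
    }
    preds <- setdiff(vars, c(v, excluded))
    stopifnot(!v %in% preds) # the response can never serve as its own predictor
    X <- cbind(as.matrix(loopData[train, preds, drop = FALSE]), C[train, , drop = FALSE])
    y <- loopData[train, v]
    keep <- stats::complete.cases(X) & !is.na(y)
    if (sum(keep) < ncol(X) + 1L + 5L) {
      warning(
        "model for '", v, "' skipped: ", sum(keep),
        " complete training rows for ", ncol(X), " predictors",
        call. = FALSE
      )
      next
    }
    Xk <- cbind(`(Intercept)` = 1, X[keep, , drop = FALSE])
    fit <- stats::lm.fit(Xk, y[keep])
    models[[v]] <- list(
      response = v, predictors = preds, excluded = excluded,
      coefficients = fit$coefficients, n_train = sum(keep)
    )
  }
  structure(
    list(
      models = models, loopData = loopData, varTypes = varTypes,
      covariates = covariates, trainIds = train
    ),
    class = "LoopModelSet"
  )
}

#' @export
print.LoopModelSet <- function(x, ...) {
  cat(sprintf(
    "LoopModelSet: %d models over %d loop variables, %d training samples\n",
    length(x$models), ncol(x$loopData), length(x$trainIds)
  ))
  invisible(x)
}

#' Evaluate loop models on the held-out samples (normalised MSE)
#'
#' Restricts the test set to complete cases across all loop variables and
#' covariates, predicts every response from its fitted model, and reports
#' the mean squared error after min-max normalising each variable to [0, 1]
#' with bounds taken from the training samples (so errors are dimensionless
#' and comparable across omics); \code{mse_percent} is 100 times that MSE.
#' The mean-predictor baseline (training mean, same normalisation) is
#' reported alongside.
#'
#' @param models a \code{LoopModelSet} from \code{\link{fitLoopModels}}.
#' @param testIds held-out sample ids.
#' @param normalization only \code{"minmax"} is implemented.
#' @param seed split seed recorded in the report.
#' @return a \code{\linkS4class{CvReport}}; when no complete test case
#'   exists the MSE columns are \code{NA} and the report flags it.
#' @export
evaluateMse <- function(models, testIds, normalization = "minmax", seed = NA_real_) {
  stopifnot(inherits(models, "LoopModelSet"))
  normalization <- match.arg(normalization, "minmax")
  dat <- models$loopData
  C <- dummyEncode(models$covariates[rownames(dat), , drop = FALSE])
  test <- intersect(testIds, rownames(dat))
  complete <- test[stats::complete.cases(dat[test, , drop = FALSE]) &
    stats::complete.cases(C[test, , drop = FALSE])]
  train <- models$trainIds
  lo <- vapply(dat[train, , drop = FALSE], min, numeric(1), na.rm = TRUE)
  hi <- vapply(dat[train, , drop = FALSE], max, numeric(1), na.rm = TRUE)
  rngWidth <- pmax(hi - lo, .Machine$double.eps)
  norm <- function(v, var) (v - lo[var]) / rngWidth[var]
  rows <- lapply(models$models, function(m) {
    v <- m$response
    out <- data.frame(
      response = v, type = unname(models$varTypes[v]),
      n_train = m$n_train, n_test_complete = length(complete),
      mse_percent = NA_real_, baseline_mse_percent = NA_real_,
      excluded_predictors = paste(m$excluded, collapse = ","),
      stringsAsFactors = FALSE
    )
    if (length(complete) == 0L) {
      return(out)
    }
    X <- cbind(
      `(Intercept)` = 1,
      as.matrix(dat[complete, m$predictors, drop = FALSE]),
      C[complete, , drop = FALSE]
    )
    beta <- m$coefficients
    beta[is.na(beta)] <- 0
    yhat <- drop(X[, names(beta), drop = FALSE] %*% beta)
    y <- dat[complete, v]
    out$mse_percent <- 100 * mean((norm(y, v) - norm(yhat, v))^2)
    trainMean <- mean(dat[train, v], na.rm = TRUE)
    out$baseline_mse_percent <- 100 * mean((norm(y, v) - norm(trainMean, v))^2)
    out
  })
  results <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      response = character(), type = character(), n_train = integer(),
      n_test_complete = integer(), mse_percent = numeric(),
      baseline_mse_percent = numeric(), excluded_predictors = character(),
      stringsAsFactors = FALSE
    )
  }
  rownames(results) <- NULL
  if (nrow(results) && all(results$n_test_complete == 0)) {
    warning("no complete test case; MSE not computable", call. = FALSE)
  }
  new("CvReport",
    results = results, models = models$models,
    trainIds = train, testIds = test,
    completeFraction = if (length(test)) length(complete) / length(test) else NA_real_,
    seed = as.numeric(seed)
  )
}
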