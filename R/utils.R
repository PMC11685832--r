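#' @importFrom stats setNames
NULL

OMIC_TYPES <- c("genotype", "microbiome", "metabolite", "bmi")

# Generation order of the latent chains; planted effects always point from an
# earlier omic to a later one (correlation sign is all that is observable).
OMIC_ORDER <- c(snp = 1L, genus = 2L, metabolite = 3L, bmi = 4L)

#' Derive a reproducible substream seed from a global seed and a stream name
#'
#' Every stochastic stage of the generator and pipeline draws its own seed
#' from the global seed plus a fixed stream label, so adding or reordering a
#' stage never perturbs the draws of another.
#'
#' @param seed integer global seed.
#' @param stream character stream label.
#' @return an integer seed in [0, 2^31 - 2].
#' @keywords internal
stageSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  m <- 2147483629
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 131 + ch) %% m
  s <- as.numeric(seed) %% m
  # 69621 * m + s stays well below 2^53, so the arithmetic is exact
  as.integer((h * 69621 + s * 40014 + 12345) %% m)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# shared sample-identifier namespace
makeSampleIds <- function(n) sprintf("S%04d", seq_len(n))

`%||%` <- function(a, b) if (is.null(a)) b else a
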