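#' @include utils.R
NULL

EDGE_COLUMNS <- c(
  "node_a", "type_a", "node_b", "type_b", "age", "beta", "se",
  "p", "q", "sign", "stage", "tier", "n_used"
)

#' Build a validated association-edge table
#'
#' Association edges are the common currency of all testing stages and of
#' the network builder: one row per (variable pair, age) with the fitted
#' exposure slope, its p-value (and BH q-value where the stage applies one),
#' the slope's sign, and the stage that produced it. \code{age} is a
#' character column so it can carry a single age ("3") or an age range
#' ("2-6", as emitted by the persistence scan).
#'
#' @param node_a,node_b variable identifiers.
#' @param type_a,type_b omic types (genotype, microbiome, metabolite, bmi).
#' @param age character or numeric age / age range.
#' @param beta,se,p,q numeric fit results (q may be NA where no FDR family
#'   applies).
#' @param stage provenance tag (mgwas, persistence, diffabund, metabolite).
#' @param tier optional tier label (e.g. significant vs suggestive).
#' @param n_used complete-case sample count of the fit.
#' @return a data.frame with the canonical edge columns; \code{sign} is
#'   always \code{sign(beta)}.
#' @export
associationEdges <- function(node_a = character(), type_a = character(),
                             node_b = character(), type_b = character(),
                             age = character(), beta = numeric(),
                             se = numeric(), p = numeric(), q = NA_real_,
                             stage = character(), tier = NA_character_,
                             n_used = integer()) {
  n <- length(node_a)
  out <- data.frame(
    node_a = as.character(node_a), type_a = as.character(type_a),
    node_b = as.character(node_b), type_b = as.character(type_b),
    age = as.character(age), beta = as.numeric(beta), se = as.numeric(se),
    p = as.numeric(p), q = rep_len(as.numeric(q), n),
    sign = sign(as.numeric(beta)),
    stage = rep_len(as.character(stage), n),
    tier = rep_len(as.character(tier), n),
    n_used = as.integer(n_used),
    stringsAsFactors = FALSE
  )
  validateEdges(out)
  out
}

emptyEdges <- function() {
  associationEdges()
}

validateEdges <- function(edges) {
  stopifnot(all(EDGE_COLUMNS %in% names(edges)))
  if (nrow(edges)) {
    if (!all(edges$type_a %in% OMIC_TYPES) || !all(edges$type_b %in% OMIC_TYPES)) {
      stop("edge omic types must be one of ", paste(OMIC_TYPES, collapse = ", "),
        call. = FALSE
      )
    }
    if (any(is.na(edges$p) | edges$p <= 0 | edges$p > 1)) {
      stop("edge p-values must lie in (0, 1]", call. = FALSE)
    }
    if (!all(edges$sign == sign(edges$beta))) {
      stop("edge sign must equal sign(beta)", call. = FALSE)
    }
  }
  invisible(edges)
}

# stable ordering used by write/merge: ascending p, then ids
orderEdges <- function(edges) {
  edges[order(edges$p, edges$node_a, edges$node_b, method = "radix"), ,
    drop = FALSE
  ]
}
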