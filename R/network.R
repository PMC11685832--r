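#' @include edges.R AllClasses.R
NULL

#' Assemble the typed, signed co-association network
#'
#' Nodes are the union of edge endpoints; only cross-omic edges are
#' admissible (an edge whose endpoints share an omic type is rejected).
#' Parallel edges for the same node pair -- e.g. found by different stages
#' or at different ages -- are merged into a single undirected edge that
#' keeps the smallest-p slope, sign and age, and concatenates the provenance
#' of all merged stages.
#'
#' @param edges association-edge data.frame (rows from any stages, in the
#'   \code{\link{associationEdges}} column contract).
#' @return an \code{\linkS4class{OmicsNetwork}}.
#' @export
buildNetwork <- function(edges) {
  validateEdges(edges)
  if (nrow(edges)) {
    same <- edges$type_a == edges$type_b
    if (any(same)) {
      bad <- edges[same, , drop = FALSE][1L, ]
      stop(
        "only cross-omic edges are admissible; got a ", bad$type_a, "-",
        bad$type_b, " edge (", bad$node_a, " -- ", bad$node_b, ")",
        call. = FALSE
      )
    }
    if (any(edges$node_a == edges$node_b)) {
      stop("self-edges are not admissible", call. = FALSE)
    }
  }
  nodes <- unique(data.frame(
    id = c(edges$node_a, edges$node_b),
    type = c(edges$type_a, edges$type_b),
    stringsAsFactors = FALSE
  ))
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL
  if (anyDuplicated(nodes$id) > 0) {
    dup <- nodes$id[duplicated(nodes$id)][1L]
    stop("node '", dup, "' appears with two different omic types", call. = FALSE)
  }
  merged <- emptyEdges()
  if (nrow(edges)) {
    edges <- orderEdges(edges) # min-p row comes first within each pair
    key <- ifelse(edges$node_a < edges$node_b,
      paste(edges$node_a, edges$node_b, sep = "\r"),
      paste(edges$node_b, edges$node_a, sep = "\r")
    )
    provenance <- vapply(
      split(edges$stage, key),
      function(s) paste(unique(s), collapse = "+"), character(1)
    )
    merged <- edges[!duplicated(key), , drop = FALSE]
    merged$stage <- provenance[key[!duplicated(key)]]
    # orient merged edges canonically (node_a < node_b); sign is symmetric
    flipped <- merged$node_a > merged$node_b
    tmp <- merged[flipped, c("node_a", "type_a"), drop = FALSE]
    merged[flipped, c("node_a", "type_a")] <- merged[flipped, c("node_b", "type_b")]
    merged[flipped, c("node_b", "type_b")] <- tmp
    merged <- orderEdges(merged)
    rownames(merged) <- NULL
  }
  new("OmicsNetwork", nodes = nodes, edges = merged)
}

# canonical form of a cycle: lexicographically smallest node sequence over
# all rotations and both directions
canonicalCycle <- function(nodes) {
  k <- length(nodes)
  best <- NULL
  for (dir in list(nodes, rev(nodes))) {
    for (r in seq_len(k)) {
      rot <- dir[c(r:k, seq_len(r - 1L))]
      if (is.null(best) ||
        paste(rot, collapse = "\r") < paste(best, collapse = "\r")) {
        best <- rot
      }
    }
  }
  best
}

loopTypeAdmissible <- function(types, distinctTypes) {
  if (!distinctTypes) {
    return(TRUE)
  }
  k <- length(types)
  tab <- table(types)
  if (k == 3L) {
    all(tab == 1L)
  } else {
    # four-node loops: at most one omic type may repeat (and at most twice)
    sum(tab == 2L) <= 1L && all(tab <= 2L)
  }
}

#' Enumerate 3- and 4-node cycles and flag sign-coherent ("meaningful") loops
#'
#' Enumerates every simple cycle of the requested sizes, reporting each once
#' under a canonical rotation/reflection (lexicographically smallest node-id
#' sequence). A loop is meaningful when the product of its edge signs is +1:
#' the unique formalisation under which an increase in one variable
#' propagates consistently around the cycle (a triangle with two negative
#' links and one positive link is coherent; a single negative link is not).
#'
#' With \code{distinctTypes = TRUE} (default), 3-node loops must span three
#' distinct omic types, and 4-node loops may repeat at most one type --
#' which admits, e.g., a SNP-amino acid-genus-amino acid cycle whose two
#' same-type nodes sit on opposite corners, while every edge remains
#' cross-omic by network construction.
#'
#' @param network an \code{\linkS4class{OmicsNetwork}}.
#' @param sizes cycle sizes to enumerate (subset of \code{c(3, 4)}).
#' @param distinctTypes enforce the omic-type distinctness rule above.
#' @return data.frame with one row per loop: \code{n_nodes}, \code{nodes}
#'   (list column, canonical cycle order), \code{types} and \code{signs}
#'   (list columns aligned to nodes/edges), \code{sign_product} and
#'   \code{meaningful}; sorted canonically.
#' @export
findLoops <- function(network, sizes = c(3L, 4L), distinctTypes = TRUE) {
  stopifnot(is(network, "OmicsNetwork"))
  sizes <- as.integer(sizes)
  if (!all(sizes %in% c(3L, 4L))) {
    stop("only 3- and 4-node loops are supported", call. = FALSE)
  }
  e <- network@edges
  nodeType <- stats::setNames(network@nodes$type, network@nodes$id)
  empty <- data.frame(
    n_nodes = integer(), nodes = I(list()), types = I(list()),
    signs = I(list()), sign_product = numeric(), meaningful = logical()
  )
  if (nrow(e) < 3L) {
    return(empty)
  }
  signOf <- stats::setNames(
    e$sign,
    paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b), sep = "\r")
  )
  adj <- list()
  for (i in seq_len(nrow(e))) {
    adj[[e$node_a[i]]] <- c(adj[[e$node_a[i]]], e$node_b[i])
    adj[[e$node_b[i]]] <- c(adj[[e$node_b[i]]], e$node_a[i])
  }
  edgeSign <- function(a, b) unname(signOf[paste(min(a, b), max(a, b), sep = "\r")])

  cycles <- list()
  if (3L %in% sizes) {
    for (i in seq_len(nrow(e))) {
      a <- e$node_a[i]
      b <- e$node_b[i]
      common <- intersect(adj[[a]], adj[[b]])
      for (c3 in common[common > max(a, b)]) {
        cycles[[length(cycles) + 1L]] <- c(a, b, c3)
      }
    }
  }
  if (4L %in% sizes) {
    nodes <- network@nodes$id
    seen <- character()
    # opposite corners b, d (not necessarily adjacent) with >= 2 common
    # neighbours a, c give the cycle a-b-c-d
    for (bi in seq_along(nodes)) {
      for (di in seq_len(bi - 1L)) {
        b <- nodes[bi]
        d <- nodes[di]
        common <- intersect(adj[[b]], adj[[d]])
        if (length(common) < 2L) next
        pairs <- utils::combn(sort(common), 2L)
        for (pj in seq_len(ncol(pairs))) {
          a <- pairs[1L, pj]
          c4 <- pairs[2L, pj]
          cyc <- canonicalCycle(c(a, b, c4, d))
          key <- paste(cyc, collapse = "\r")
          if (key %in% seen) next
          seen <- c(seen, key)
          cycles[[length(cycles) + 1L]] <- cyc
        }
      }
    }
  }
  if (!length(cycles)) {
    return(empty)
  }
  rows <- lapply(cycles, function(cyc) {
    cyc <- canonicalCycle(cyc)
    types <- unname(nodeType[cyc])
    if (!loopTypeAdmissible(types, distinctTypes)) {
      return(NULL)
    }
    k <- length(cyc)
    sgns <- vapply(
      seq_len(k),
      function(i) edgeSign(cyc[i], cyc[if (i == k) 1L else i + 1L]),
      numeric(1)
    )
    sp <- prod(sgns)
    data.frame(
      n_nodes = k, nodes = I(list(cyc)), types = I(list(types)),
      signs = I(list(sgns)), sign_product = sp, meaningful = sp == 1
    )
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(empty)
  }
  out <- do.call(rbind, rows)
  key <- vapply(out$nodes, paste, character(1), collapse = "\r")
  out <- out[order(out$n_nodes, key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Null distribution of the meaningful-loop count under random edge signs
#'
#' Keeps the network topology fixed and redraws every edge sign
#' independently and uniformly from \{+1, -1\}, recording the number of
#' meaningful loops in each permutation. The exceedance probability of the
#' observed count calibrates whether the observed sign pattern is more
#' coherent than chance.
#'
#' @param network an \code{\linkS4class{OmicsNetwork}}.
#' @param nPermutations number of sign draws (>= 1).
#' @param seed integer seed for reproducibility.
#' @param sizes,distinctTypes passed to \code{\link{findLoops}}.
#' @return list with \code{counts} (length \code{nPermutations}),
#'   \code{observed} (meaningful loops of the real network) and
#'   \code{exceedance} (fraction of permutations with count >= observed).
#' @export
loopNullCount <- function(network, nPermutations, seed = 1L,
                          sizes = c(3L, 4L), distinctTypes = TRUE) {
  stopifnot(nPermutations >= 1)
  loops <- findLoops(network, sizes = sizes, distinctTypes = distinctTypes)
  observed <- sum(loops$meaningful)
  e <- network@edges
  edgeKey <- paste(pmin(e$node_a, e$node_b), pmax(e$node_a, e$node_b), sep = "\r")
  # per loop, indices of its edges in the edge table (sign products are then
  # recomputed directly for each permutation; topology is enumerated once)
  loopEdgeIdx <- lapply(loops$nodes, function(cyc) {
    k <- length(cyc)
    vapply(seq_len(k), function(i) {
      a <- cyc[i]
      b <- cyc[if (i == k) 1L else i + 1L]
      match(paste(min(a, b), max(a, b), sep = "\r"), edgeKey)
    }, integer(1))
  })
  counts <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(r) {
      s <- sample(c(-1, 1), nrow(e), replace = TRUE)
      if (!length(loopEdgeIdx)) {
        return(0L)
      }
      sum(vapply(loopEdgeIdx, function(idx) prod(s[idx]) == 1, logical(1)))
    }, integer(1))
  })
  list(counts = counts, observed = observed, exceedance = mean(counts >= observed))
}
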