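# shared fixtures: small cohorts built in code, cached per test run

tinyConfig <- function(nSamples = 60, nGenera = 12, seed = 42, ...) {
  cohortConfig(
    nSamples = nSamples,
    snpPanel = defaultSnpPanel(nGenes = 3, snpsPerGene = 3),
    ldPairs = data.frame(
      snp_a = "snp001", snp_b = "snp002", r = 0.95,
      stringsAsFactors = FALSE
    ),
    nGenera = nGenera,
    sequencingDepth = 2000,
    metabolitePanel = defaultMetabolitePanel(20),
    seed = seed,
    ...
  )
}

.cohortCache <- new.env(parent = emptyenv())

cachedCohort <- function(key, config) {
  if (is.null(.cohortCache[[key]])) {
    .cohortCache[[key]] <- simulateCohort(config)
  }
  .cohortCache[[key]]
}

# a no-missingness configuration (complete tables simplify equality checks)
completeConfig <- function(...) {
  tinyConfig(
    missingness = list(genotype = 0, microbiome = 0, metabolome = 0, bmi = 0),
    ...
  )
}

# build an edge table quickly for network tests
mkEdge <- function(a, ta, b, tb, beta = 1, p = 0.001, stage = "mgwas",
                   age = "3", q = NA_real_) {
  associationEdges(
    node_a = a, type_a = ta, node_b = b, type_b = tb, age = age,
    beta = beta, se = abs(beta) / 5, p = p, q = q, stage = stage,
    n_used = 100L
  )
}

# independent brute-force loop enumeration used as the oracle for findLoops:
# checks every node triple / quadruple (and for quadruples, all three
# pairings into a cycle) directly against the edge list
bruteForceLoops <- function(network, sizes = c(3L, 4L), distinctTypes = TRUE) {
  e <- networkEdges(network)
  nodes <- networkNodes(network)
  hasEdge <- function(a, b) {
    any((e$node_a == a & e$node_b == b) | (e$node_a == b & e$node_b == a))
  }
  sgn <- function(a, b) {
    e$sign[(e$node_a == a & e$node_b == b) | (e$node_a == b & e$node_b == a)][1L]
  }
  typeOf <- function(id) nodes$type[match(id, nodes$id)]
  admissible <- function(types) {
    if (!distinctTypes) {
      return(TRUE)
    }
    tab <- table(types)
    if (length(types) == 3L) all(tab == 1L) else sum(tab == 2L) <= 1L && all(tab <= 2L)
  }
  out <- list()
  ids <- sort(nodes$id)
  if (3L %in% sizes && length(ids) >= 3L) {
    for (tri in asplit(combn(ids, 3L), 2L)) {
      tri <- as.character(tri)
      if (hasEdge(tri[1], tri[2]) && hasEdge(tri[2], tri[3]) &&
        hasEdge(tri[1], tri[3]) && admissible(typeOf(tri))) {
        signs <- c(sgn(tri[1], tri[2]), sgn(tri[2], tri[3]), sgn(tri[3], tri[1]))
        out[[length(out) + 1L]] <- list(nodes = tri, signs = signs)
      }
    }
  }
  if (4L %in% sizes && length(ids) >= 4L) {
    for (quad in asplit(combn(ids, 4L), 2L)) {
      quad <- as.character(quad)
      # three distinct pairings of 4 nodes into a cycle
      orders <- list(
        quad,
        quad[c(1, 2, 4, 3)],
        quad[c(1, 3, 2, 4)]
      )
      for (cyc in orders) {
        ok <- hasEdge(cyc[1], cyc[2]) && hasEdge(cyc[2], cyc[3]) &&
          hasEdge(cyc[3], cyc[4]) && hasEdge(cyc[4], cyc[1])
        if (ok && admissible(typeOf(cyc))) {
          signs <- c(
            sgn(cyc[1], cyc[2]), sgn(cyc[2], cyc[3]),
            sgn(cyc[3], cyc[4]), sgn(cyc[4], cyc[1])
          )
          out[[length(out) + 1L]] <- list(nodes = cyc, signs = signs)
        }
      }
    }
  }
  out
}

# canonical string key for a cycle (rotation/reflection invariant)
cycleKey <- function(nodes) {
  k <- length(nodes)
  best <- NULL
  for (dir in list(nodes, rev(nodes))) {
    for (r in seq_len(k)) {
      rot <- paste(dir[c(r:k, seq_len(r - 1L))], collapse = "|")
      if (is.null(best) || rot < best) best <- rot
    }
  }
  best
}

# random typed signed network for oracle comparisons
randomTypedNetwork <- function(nNodes, pEdge, seed) {
  set.seed(seed)
  types <- sample(c("genotype", "microbiome", "metabolite", "bmi"),
    nNodes,
    replace = TRUE
  )
  ids <- sprintf("n%02d", seq_len(nNodes))
  rows <- list()
  for (i in seq_len(nNodes - 1L)) {
    for (j in (i + 1L):nNodes) {
      if (types[i] != types[j] && runif(1) < pEdge) {
        rows[[length(rows) + 1L]] <- mkEdge(
          ids[i], types[i], ids[j], types[j],
          beta = sample(c(-1, 1), 1) * runif(1, 0.1, 2),
          p = runif(1, 1e-6, 0.01)
        )
      }
    }
  }
  if (!length(rows)) {
    return(NULL)
  }
  buildNetwork(do.call(rbind, rows))
}
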