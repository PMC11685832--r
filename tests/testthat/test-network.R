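triangleEdges <- function(signs = c(1, 1, 1), p = c(0.001, 0.002, 0.003)) {
  rbind(
    mkEdge("s1", "genotype", "m1", "metabolite", beta = signs[1], p = p[1]),
    mkEdge("m1", "metabolite", "b1", "bmi", beta = signs[2], p = p[2]),
    mkEdge("s1", "genotype", "b1", "bmi", beta = signs[3], p = p[3])
  )
}

test_that("a triangle of edges builds a 3-node, 3-edge network", {
  net <- buildNetwork(triangleEdges())
  expect_equal(nrow(networkNodes(net)), 3L)
  expect_equal(nrow(networkEdges(net)), 3L)
  expect_s4_class(net, "OmicsNetwork")
})

test_that("duplicate node pairs merge keeping the smallest p and all provenance", {
  e <- rbind(
    mkEdge("s1", "genotype", "g1", "microbiome", p = 0.003, stage = "diffabund"),
    mkEdge("g1", "microbiome", "s1", "genotype", p = 0.0004, stage = "mgwas")
  )
  net <- buildNetwork(e)
  expect_equal(nrow(networkEdges(net)), 1L)
  expect_equal(networkEdges(net)$p, 0.0004)
  expect_setequal(
    strsplit(networkEdges(net)$stage, "+", fixed = TRUE)[[1L]],
    c("mgwas", "diffabund")
  )
})

test_that("same-omic edges are rejected", {
  expect_error(
    buildNetwork(mkEdge("g1", "microbiome", "g2", "microbiome")),
    "cross-omic"
  )
})

test_that("the worked sign cases follow the product rule", {
  meaningfulOf <- function(signs) {
    net <- buildNetwork(triangleEdges(signs))
    loops <- findLoops(net)
    expect_equal(nrow(loops), 1L)
    loops$meaningful
  }
  expect_true(meaningfulOf(c(1, 1, 1)))
  expect_true(meaningfulOf(c(-1, -1, 1)))
  expect_false(meaningfulOf(c(-1, 1, 1)))
})

test_that("all sign assignments of 3- and 4-cycles match the product rule", {
  for (k in c(3L, 4L)) {
    types <- c("genotype", "metabolite", "bmi", "microbiome")[seq_len(k)]
    ids <- paste0("n", seq_len(k))
    grid <- expand.grid(rep(list(c(-1, 1)), k))
    for (r in seq_len(nrow(grid))) {
      signs <- as.numeric(grid[r, ])
      edges <- do.call(rbind, lapply(seq_len(k), function(i) {
        j <- if (i == k) 1L else i + 1L
        mkEdge(ids[i], types[i], ids[j], types[j], beta = signs[i], p = 0.001 * i)
      }))
      loops <- findLoops(buildNetwork(edges), sizes = k)
      expect_equal(nrow(loops), 1L)
      expect_equal(loops$sign_product, prod(signs))
      expect_equal(loops$meaningful, prod(signs) == 1)
    }
  }
})

test_that("loop enumeration equals the brute-force oracle on random graphs", {
  checked <- 0L
  for (seed in 1:30) {
    net <- randomTypedNetwork(nNodes = sample(6:12, 1), pEdge = 0.4, seed = seed)
    if (is.null(net)) next
    for (distinct in c(TRUE, FALSE)) {
      got <- findLoops(net, distinctTypes = distinct)
      oracle <- bruteForceLoops(net, distinctTypes = distinct)
      expect_setequal(
        vapply(got$nodes, cycleKey, character(1)),
        unique(vapply(oracle, function(l) cycleKey(l$nodes), character(1)))
      )
      # meaningfulness agrees loop by loop
      oracleMeaning <- vapply(oracle, function(l) prod(l$signs) == 1, logical(1))
      names(oracleMeaning) <- vapply(oracle, function(l) cycleKey(l$nodes), character(1))
      gotKeys <- vapply(got$nodes, cycleKey, character(1))
      expect_identical(
        unname(got$meaningful),
        unname(oracleMeaning[gotKeys])
      )
      checked <- checked + 1L
    }
  }
  expect_gte(checked, 30L)
})

test_that("enumeration is invariant to node relabeling and edge order", {
  net <- randomTypedNetwork(10, 0.5, seed = 99)
  loops1 <- findLoops(net)
  e <- networkEdges(net)
  e2 <- e[rev(seq_len(nrow(e))), ]
  loops2 <- findLoops(buildNetwork(e2))
  expect_identical(
    vapply(loops1$nodes, cycleKey, character(1)),
    vapply(loops2$nodes, cycleKey, character(1))
  )
  # relabel: a bijective prefix flip keeps structure, changes id order
  relabel <- function(x) chartr("n", "z", x)
  e3 <- e
  e3$node_a <- relabel(e3$node_a)
  e3$node_b <- relabel(e3$node_b)
  loops3 <- findLoops(buildNetwork(e3))
  expect_identical(
    sort(vapply(loops1$nodes, function(x) cycleKey(relabel(x)), character(1))),
    sort(vapply(loops3$nodes, cycleKey, character(1)))
  )
})

test_that("flipping an even number of edge signs preserves meaningfulness", {
  for (k in c(3L, 4L)) {
    types <- c("genotype", "metabolite", "bmi", "microbiome")[seq_len(k)]
    ids <- paste0("n", seq_len(k))
    base <- rep(1, k)
    for (nflip in 0:k) {
      for (flipIdx in asplit(combn(k, nflip), 2L)) {
        signs <- base
        signs[unlist(flipIdx)] <- -1
        edges <- do.call(rbind, lapply(seq_len(k), function(i) {
          j <- if (i == k) 1L else i + 1L
          mkEdge(ids[i], types[i], ids[j], types[j], beta = signs[i])
        }))
        loops <- findLoops(buildNetwork(edges), sizes = k)
        expect_equal(loops$meaningful, nflip %% 2L == 0L)
      }
    }
  }
})

test_that("four-node loops may repeat one omic type on opposite corners only", {
  # snp - aa1 - genus - aa2 cycle: two metabolites, non-adjacent
  e <- rbind(
    mkEdge("s1", "genotype", "aa1", "metabolite", beta = -1),
    mkEdge("aa1", "metabolite", "g1", "microbiome", beta = 1),
    mkEdge("g1", "microbiome", "aa2", "metabolite", beta = 1),
    mkEdge("aa2", "metabolite", "s1", "genotype", beta = -1)
  )
  loops <- findLoops(buildNetwork(e), sizes = 4L)
  expect_equal(nrow(loops), 1L)
  expect_true(loops$meaningful)
  # three-node loops never repeat a type under the default rule
  e3 <- rbind(
    mkEdge("s1", "genotype", "aa1", "metabolite", beta = 1),
    mkEdge("aa1", "metabolite", "aa2", "bmi", beta = 1),
    mkEdge("aa2", "bmi", "s1", "genotype", beta = 1)
  )
  net3 <- buildNetwork(e3)
  expect_equal(nrow(findLoops(net3, sizes = 3L)), 1L)
  # same topology, but two nodes sharing a type: filtered out when strict
  e3b <- rbind(
    mkEdge("s1", "genotype", "aa1", "metabolite", beta = 1),
    mkEdge("aa1", "metabolite", "b1", "bmi", beta = 1),
    mkEdge("b1", "bmi", "m2", "metabolite", beta = 1),
    mkEdge("m2", "metabolite", "s1", "genotype", beta = 1),
    mkEdge("s1", "genotype", "b1", "bmi", beta = 1)
  )
  net3b <- buildNetwork(e3b)
  tri <- findLoops(net3b, sizes = 3L)
  types <- lapply(tri$nodes, function(nn) {
    networkNodes(net3b)$type[match(nn, networkNodes(net3b)$id)]
  })
  expect_true(all(vapply(types, function(tt) !anyDuplicated(tt), logical(1))))
})

test_that("the sign-permutation null behaves like the exact enumeration", {
  # no cycles: the null distribution is degenerate at zero
  path <- rbind(
    mkEdge("s1", "genotype", "m1", "metabolite"),
    mkEdge("m1", "metabolite", "b1", "bmi")
  )
  nullPath <- loopNullCount(buildNetwork(path), 50, seed = 1)
  expect_true(all(nullPath$counts == 0))
  # single triangle: 4 of the 8 sign assignments are coherent
  net <- buildNetwork(triangleEdges())
  nullTri <- loopNullCount(net, 4000, seed = 2)
  expect_equal(mean(nullTri$counts), 0.5, tolerance = 0.05)
  expect_equal(nullTri$observed, 1L)
  # determinism under a fixed seed
  again <- loopNullCount(net, 4000, seed = 2)
  expect_identical(nullTri$counts, again$counts)
})
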