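test_that("vertex similarity follows the augmented-cosine definition", {
  # 4-node path a-b-c-d, unit weights: interior rows (1,2,1,0) and
  # (0,1,2,1) give cos = 4/6
  path4 <- netFromEdges(letters[1:4], c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(vertexSimilarity(path4, "b", "c"), 2 / 3)
  expect_equal(vertexSimilarity(path4, "c", "b"), 2 / 3)
  # no mutual edge, no shared neighbour: orthogonal rows
  two <- netFromEdges(c("a", "b", "c", "d"), c("a", "c"), c("b", "d"))
  expect_equal(vertexSimilarity(two, "a", "c"), 0)
  # shared-neighbour twins: rows (k, 0, w) and (0, k, w), cos = w^2/(k^2+w^2)
  star <- netFromEdges(c("u", "v", "h"), c("u", "v"), c("h", "h"), c(2L, 2L))
  expect_equal(vertexSimilarity(star, "u", "v"), 4 / 8)
  expect_error(vertexSimilarity(path4, "a", "zz"), "unknown drug")
})

test_that("similarity is symmetric and bounded in [0,1] on random networks", {
  set.seed(11)
  for (rep in 1:5) {
    net <- projectDDSN(randomTripartite(8, 6, 6, 0.4, 0.4))
    d <- drugNames(net)
    pairs <- t(combn(d, 2))[sample(choose(length(d), 2), 10), , drop = FALSE]
    for (i in seq_len(nrow(pairs))) {
      s1 <- vertexSimilarity(net, pairs[i, 1], pairs[i, 2])
      s2 <- vertexSimilarity(net, pairs[i, 2], pairs[i, 1])
      expect_equal(s1, s2)
      expect_gte(s1, 0)
      expect_lte(s1, 1)
    }
  }
})

test_that("modularity matches hand evaluation and the all-in-one cluster is 0", {
  net <- twoCliquesBridge()
  all_in <- makePartition(list(drugNames(net)))
  expect_equal(modularityScore(net, all_in), 0)

  # 3-node path, singleton clusters: Q = -(1/16 + 4/16 + 1/16)
  p3 <- netFromEdges(c("x", "y", "z"), c("x", "y"), c("y", "z"))
  singles <- makePartition(list("x", "y", "z"))
  expect_equal(modularityScore(p3, singles), -6 / 16)

  # two 4-cliques + bridge at the true split: 24/26 - 2*(13/26)^2
  split <- makePartition(list(paste0("a", 1:4), paste0("b", 1:4)))
  expect_equal(modularityScore(net, split), 24 / 26 - 2 * (13 / 26)^2)
  expect_equal(modularityScore(net, split), handModularity(
    net, list(paste0("a", 1:4), paste0("b", 1:4))))

  bad <- makePartition(list(paste0("a", 1:4)))
  expect_error(modularityScore(net, bad), "cover")
})

test_that("modularity agrees with the hand formula on weighted random networks", {
  set.seed(21)
  for (rep in 1:10) {
    net <- projectDDSN(randomTripartite(9, 6, 7, 0.4, 0.4))
    part <- hierarchicalCommunities(net)
    if (nrow(similarityEdges(net)) == 0L) next
    expect_equal(modularityScore(net, part),
                 handModularity(net, communityList(part)))
  }
})

test_that("hierarchical detection recovers canonical structures", {
  # two 4-cliques joined by one bridge: the cliques are the communities
  part <- hierarchicalCommunities(twoCliquesBridge())
  expect_equal(communityList(part),
               list(paste0("a", 1:4), paste0("b", 1:4)))

  # a single triangle: any split lowers Q
  tri <- netFromEdges(c("x", "y", "z"), c("x", "x", "y"),
                      c("y", "z", "z"))
  expect_equal(communityList(hierarchicalCommunities(tri)),
               list(c("x", "y", "z")))

  # two isolated nodes: components never merge
  iso <- newSimilarityNetwork(c("p", "q"),
    data.frame(from = character(), to = character(), weight = integer()))
  expect_equal(lengths(communityList(hierarchicalCommunities(iso))),
               c(1L, 1L))

  empty <- newSimilarityNetwork(character(0),
    data.frame(from = character(), to = character(), weight = integer()))
  expect_error(hierarchicalCommunities(empty), "empty")
})

test_that("no community ever spans two connected components", {
  set.seed(31)
  for (rep in 1:5) {
    # two disjoint random networks glued as one node set
    n1 <- projectDDSN(randomTripartite(6, 5, 5, 0.5, 0.5))
    g2 <- randomTripartite(6, 5, 5, 0.5, 0.5)
    e2 <- similarityEdges(projectDDSN(g2))
    e2$from <- paste0("Z", e2$from)
    e2$to <- paste0("Z", e2$to)
    net <- newSimilarityNetwork(
      c(drugNames(n1), paste0("Z", drugNames(g2))),
      rbind(similarityEdges(n1), e2))
    part <- hierarchicalCommunities(net)
    for (cl in communityList(part))
      expect_true(all(startsWith(cl, "Z")) || !any(startsWith(cl, "Z")))
  }
})

test_that("the selected dendrogram cut attains the exhaustive-maximum modularity", {
  set.seed(41)
  for (rep in 1:30) {
    net <- projectDDSN(randomTripartite(sample(4:10, 1), 5, 6, 0.35, 0.4))
    if (nrow(similarityEdges(net)) == 0L) next
    part <- hierarchicalCommunities(net)
    chosenQ <- handModularity(net, communityList(part))
    # independent enumeration: every combination of per-component cuts
    g <- ddsnet:::asIgraph(net)
    comp <- igraph::components(g)
    cutsets <- list()
    for (cid in unique(comp$membership)) {
      nodes <- sort(names(comp$membership)[comp$membership == cid])
      if (length(nodes) == 1L) { cutsets[[length(cutsets) + 1L]] <- list(list(nodes)); next }
      S <- ddsnet:::augmentedCosine(net, nodes)
      hc <- hclust(as.dist(1 - S), method = "average")
      cutsets[[length(cutsets) + 1L]] <- lapply(seq_along(nodes), function(k) {
        labs <- cutree(hc, k = k)
        unname(split(nodes, labs))
      })
    }
    bestQ <- -Inf
    idx <- rep(1L, length(cutsets))
    repeat {
      clusters <- unlist(lapply(seq_along(cutsets),
                                function(i) cutsets[[i]][[idx[i]]]),
                         recursive = FALSE)
      bestQ <- max(bestQ, handModularity(net, clusters))
      j <- 1L
      while (j <= length(idx)) {
        idx[j] <- idx[j] + 1L
        if (idx[j] <= length(cutsets[[j]])) break
        idx[j] <- 1L
        j <- j + 1L
      }
      if (j > length(idx)) break
    }
    expect_equal(chosenQ, bestQ, tolerance = 1e-10)
  }
})

test_that("detection is deterministic for a fixed network", {
  set.seed(51)
  net <- projectDDSN(randomTripartite(12, 8, 8, 0.3, 0.4))
  p1 <- hierarchicalCommunities(net, seed = 1L)
  p2 <- hierarchicalCommunities(net, seed = 99L)
  expect_identical(communityList(p1), communityList(p2))
  expect_identical(partitionModularity(p1), partitionModularity(p2))
})

test_that("clusters partition the node set before filtering and are size-ordered", {
  set.seed(61)
  net <- projectDDSN(randomTripartite(12, 8, 8, 0.3, 0.4))
  part <- hierarchicalCommunities(net)
  members <- unlist(communityList(part))
  expect_setequal(members, drugNames(net))
  expect_equal(anyDuplicated(members), 0L)
  sizes <- communitySizes(part)
  expect_true(all(diff(sizes) <= 0))
})

test_that("filtering applies the connectivity rule then the size rule", {
  fx <- rosterFixture()
  filtered <- filterCommunities(fx$partition, fx$network, minSize = 8L,
                                requireMainComponent = TRUE)
  expect_equal(length(communityList(filtered)), 12L)
  exc <- excludedCommunities(filtered)
  expect_equal(nrow(exc), 22L)
  expect_equal(sort(exc$cluster[exc$reason == "disconnected_from_main_component"]),
               c(15:21, 23:31))
  expect_equal(sort(exc$cluster[exc$reason == "below_min_size"]),
               c(13L, 14L, 22L, 32L, 33L, 34L))
  # survivor sizes are the 12 large ones, renumbered descending
  expect_equal(communitySizes(filtered),
               sort(table2Rows()$size, decreasing = TRUE))

  # identity when nothing is filterable
  net <- twoCliquesBridge()
  part <- hierarchicalCommunities(net)
  same <- filterCommunities(part, net, minSize = 1L,
                            requireMainComponent = FALSE)
  expect_equal(communityList(same), communityList(part))
  expect_error(filterCommunities(part, net, minSize = 0L), "minSize")
})
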