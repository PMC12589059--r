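# Shared fixtures and independent oracles for the test suite.

# Tripartite fixture in the style of the worked projection example:
# M1 and M7 each reach, through their own receptor genes, exactly the
# three diseases Paraganglioma, Pheochromocytoma and Adrenocortical
# carcinoma; the other drugs reach private diseases only.
fig2Tripartite <- function() {
  shared <- c("Paraganglioma", "Pheochromocytoma",
              "Adrenocortical carcinoma")
  dg <- data.frame(
    drug_id = c("M1", "M7", "M2", "M3", "M4", "M5", "M6"),
    gene_symbol = c("ADRA1A", "ADRA1B", "G2", "G3", "G4", "G5", "G6"))
  gd <- rbind(
    data.frame(gene_symbol = "ADRA1A", disease_id = shared),
    data.frame(gene_symbol = "ADRA1B", disease_id = shared),
    data.frame(gene_symbol = paste0("G", 2:6),
               disease_id = paste0("D", 2:6)))
  buildTripartite(dg, gd)
}

# Random small tripartite graph for oracle-equivalence checks.
randomTripartite <- function(nDrugs = 8L, nGenes = 6L, nDiseases = 6L,
                             pDG = 0.3, pGD = 0.3) {
  drugs <- sprintf("m%02d", seq_len(nDrugs))
  genes <- sprintf("g%02d", seq_len(nGenes))
  dis <- sprintf("d%02d", seq_len(nDiseases))
  eg <- expand.grid(drug_id = drugs, gene_symbol = genes,
                    stringsAsFactors = FALSE)
  eg <- eg[runif(nrow(eg)) < pDG, , drop = FALSE]
  ed <- expand.grid(gene_symbol = genes, disease_id = dis,
                    stringsAsFactors = FALSE)
  ed <- ed[runif(nrow(ed)) < pGD, , drop = FALSE]
  if (nrow(eg) == 0L)
    eg <- data.frame(drug_id = drugs[1], gene_symbol = genes[1])
  if (nrow(ed) == 0L)
    ed <- data.frame(gene_symbol = genes[1], disease_id = dis[1])
  buildTripartite(eg, ed)
}

# Similarity network from an explicit edge list given as a
# 3-column matrix-like data.frame (from, to, weight).
netFromEdges <- function(drugs, from, to, weight = 1L) {
  newSimilarityNetwork(drugs, data.frame(
    from = from, to = to, weight = as.integer(weight),
    stringsAsFactors = FALSE))
}

# Two 4-cliques joined by a single unit-weight bridge; the classic
# two-community benchmark.
twoCliquesBridge <- function() {
  a <- c("a1", "a2", "a3", "a4")
  b <- c("b1", "b2", "b3", "b4")
  cl <- function(v) t(combn(v, 2))
  e <- rbind(cl(a), cl(b), c("a1", "b1"))
  netFromEdges(c(a, b), e[, 1], e[, 2], 1L)
}

# Independent weighted Newman-Girvan modularity: direct evaluation of
# Q = sum_c [ w_in(c)/2m - (k(c)/2m)^2 ] from the edge list, written
# without igraph so it can serve as an oracle for modularityScore().
handModularity <- function(network, clusters) {
  e <- similarityEdges(network)
  m2 <- 2 * sum(e$weight)
  strength <- setNames(rep(0, length(drugNames(network))),
                       drugNames(network))
  for (i in seq_len(nrow(e))) {
    strength[e$from[i]] <- strength[e$from[i]] + e$weight[i]
    strength[e$to[i]] <- strength[e$to[i]] + e$weight[i]
  }
  q <- 0
  for (cl in clusters) {
    inside <- e$from %in% cl & e$to %in% cl
    q <- q + 2 * sum(e$weight[inside]) / m2 - (sum(strength[cl]) / m2)^2
  }
  q
}

# Partition object from a bare cluster list (sorted by size, largest
# first, ties by smallest member -- the class invariant).
makePartition <- function(clusters) {
  clusters <- lapply(clusters, sort)
  first <- vapply(clusters, `[[`, character(1), 1L)
  new("CommunityPartition",
      clusters = clusters[order(-lengths(clusters), first)])
}

# The 12 labeled-cluster rows of the published accuracy table:
# cluster number, size, % label-matched in the database, % confirmed
# by literature.
table2Rows <- function() {
  data.frame(
    cluster_number = 1:12,
    size = c(105L, 88L, 95L, 85L, 51L, 51L, 51L, 44L, 31L, 24L, 15L, 13L),
    pct_predominant = c(52.4, 52.3, 35.8, 52.9, 54.9, 60.8, 64.7, 61.4,
                        61.3, 87.5, 40, 30.8),
    pct_confirmed = c(26.7, 14.8, 13.7, 30.6, 17.6, 23.5, 15.7, 20.4,
                      16.1, 4.2, 13.3, 46.1))
}

# A 34-cluster roster realizing the published exclusion pattern: the
# 12 large clusters plus clusters 13, 14, 22 and 32-34 (all smaller
# than 8 drugs) sit in the main connected component; clusters 15-21
# and 23-31 are disconnected from it. Cluster sizes descend so that
# roster indices are the partition numbering.
rosterFixture <- function() {
  sizes <- c(sort(table2Rows()$size, decreasing = TRUE),
             rep(7L, 19L), rep(6L, 3L))
  stopifnot(length(sizes) == 34L)
  disconnected <- c(15:21, 23:31)
  clusters <- lapply(seq_along(sizes), function(i)
    sprintf("c%02d_%03d", i, seq_len(sizes[i])))
  pathEdges <- function(v) {
    if (length(v) < 2L) return(NULL)
    data.frame(from = v[-length(v)], to = v[-1L], weight = 1L)
  }
  edges <- do.call(rbind, lapply(clusters, pathEdges))
  main <- setdiff(seq_along(sizes), disconnected)
  anchors <- vapply(clusters[main], `[[`, character(1), 1L)
  bridges <- data.frame(from = anchors[-length(anchors)],
                        to = anchors[-1L], weight = 1L)
  network <- newSimilarityNetwork(unlist(clusters), rbind(edges, bridges))
  list(network = network, partition = makePartition(clusters))
}
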