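test_that("tripartite construction deduplicates edges and checks disjointness", {
  dg <- data.frame(drug_id = "M1", gene_symbol = "ADRA1A")
  gd <- data.frame(gene_symbol = "ADRA1A", disease_id = "Pheochromocytoma")
  g <- buildTripartite(dg, gd)
  expect_equal(length(drugNames(g)), 1L)
  expect_equal(length(geneNames(g)), 1L)
  expect_equal(length(diseaseNames(g)), 1L)
  expect_equal(nrow(g@drugGeneEdges), 1L)
  expect_equal(nrow(g@geneDiseaseEdges), 1L)

  empty <- buildTripartite(data.frame(drug_id = character(),
                                      gene_symbol = character()),
                           data.frame(gene_symbol = character(),
                                      disease_id = character()))
  expect_equal(length(drugNames(empty)), 0L)

  # 12 drug-gene rows (1 duplicated) and 8 gene-disease rows (1
  # duplicated) over 7 drugs, 5 genes, 4 diseases
  dg <- data.frame(
    drug_id = c("m1","m1","m2","m2","m3","m3","m4","m5","m6","m7","m7","m1"),
    gene_symbol = c("g1","g2","g2","g3","g3","g4","g4","g5","g5","g1","g5","g1"))
  gd <- data.frame(
    gene_symbol = c("g1","g1","g2","g3","g4","g5","g5","g1"),
    disease_id  = c("d1","d2","d2","d3","d4","d4","d1","d1"))
  g <- buildTripartite(dg, gd)
  expect_equal(nrow(g@drugGeneEdges), 11L)
  expect_equal(nrow(g@geneDiseaseEdges), 7L)

  expect_error(buildTripartite(
    data.frame(drug_id = "X", gene_symbol = "G"),
    data.frame(gene_symbol = "G", disease_id = "X")), "two vertex roles")
})

test_that("reachable diseases compose drug-gene and gene-disease edges", {
  dg <- data.frame(drug_id = c("m1", "m1", "m2"),
                   gene_symbol = c("g1", "g2", "g9"))
  gd <- data.frame(gene_symbol = c("g1", "g1", "g2", "g2", "g9"),
                   disease_id = c("d1", "d2", "d2", "d3", "d9"))
  g <- buildTripartite(dg, gd)
  expect_equal(reachableDiseases(g, "m1"), c("d1", "d2", "d3"))
  expect_equal(reachableDiseases(g, "m2"), "d9")
  expect_error(reachableDiseases(g, "nope"), "unknown drug")

  lonely <- buildTripartite(data.frame(drug_id = "m1", gene_symbol = "g1"),
                            data.frame(gene_symbol = "g2",
                                       disease_id = "d1"))
  expect_equal(reachableDiseases(lonely, "m1"), character(0))
})

test_that("projection counts shared diseases once per disease (worked example)", {
  g <- fig2Tripartite()
  net <- projectDDSN(g)
  e <- similarityEdges(net)
  edge <- e[e$from == "M1" & e$to == "M7", ]
  expect_equal(nrow(edge), 1L)
  expect_equal(edge$weight, 3L)
  # drugs with disjoint reachable sets get no edge
  expect_false(any(e$from == "M2" & e$to == "M3"))
  # all drugs remain nodes
  expect_setequal(drugNames(net), paste0("M", 1:7))
})

test_that("a disease reached through multiple genes still counts once", {
  dg <- data.frame(drug_id = c("m1", "m1", "m2"),
                   gene_symbol = c("g1", "g2", "g3"))
  gd <- data.frame(gene_symbol = c("g1", "g2", "g3"),
                   disease_id = c("d1", "d1", "d1"))
  net <- projectDDSN(buildTripartite(dg, gd))
  expect_equal(similarityEdges(net)$weight, 1L)
})

test_that("minWeight threshold prunes weak edges but keeps nodes", {
  g <- fig2Tripartite()
  net <- projectDDSN(g, minWeight = 2L)
  e <- similarityEdges(net)
  expect_true(all(e$weight >= 2L))
  expect_setequal(drugNames(net), paste0("M", 1:7))
})

test_that("projection matches the exhaustive path-enumeration oracle", {
  set.seed(101)
  for (rep in 1:100) {
    g <- randomTripartite(nDrugs = sample(2:15, 1),
                          nGenes = sample(2:10, 1),
                          nDiseases = sample(2:10, 1),
                          pDG = runif(1, 0.1, 0.5),
                          pGD = runif(1, 0.1, 0.5))
    fast <- projectDDSN(g)
    slow <- oracleProject(g)
    expect_identical(similarityEdges(fast), similarityEdges(slow))
    expect_setequal(drugNames(fast), drugNames(slow))
  }
})

test_that("oracle handles degenerate graphs", {
  single <- buildTripartite(data.frame(drug_id = "m1", gene_symbol = "g1"),
                            data.frame(gene_symbol = "g1",
                                       disease_id = "d1"))
  net <- oracleProject(single)
  expect_equal(drugNames(net), "m1")
  expect_equal(nrow(similarityEdges(net)), 0L)
})

test_that("weights are bounded by the smaller reachable set, with equality under containment", {
  set.seed(77)
  for (rep in 1:20) {
    g <- randomTripartite(10, 6, 8, 0.4, 0.4)
    net <- projectDDSN(g)
    sets <- sapply(drugNames(g), function(d) length(reachableDiseases(g, d)))
    e <- similarityEdges(net)
    for (i in seq_len(nrow(e)))
      expect_lte(e$weight[i], min(sets[e$from[i]], sets[e$to[i]]))
  }
  # containment forces equality
  dg <- data.frame(drug_id = c("m1", "m2", "m2"),
                   gene_symbol = c("g1", "g1", "g2"))
  gd <- data.frame(gene_symbol = c("g1", "g1", "g2"),
                   disease_id = c("d1", "d2", "d3"))
  net <- projectDDSN(buildTripartite(dg, gd))
  expect_equal(similarityEdges(net)$weight, 2L)
})

test_that("adding a gene-disease edge never decreases any pairwise weight", {
  set.seed(303)
  for (rep in 1:10) {
    g <- randomTripartite(8, 5, 6, 0.4, 0.3)
    base <- similarityEdges(projectDDSN(g))
    gd2 <- rbind(g@geneDiseaseEdges,
                 data.frame(gene = sample(geneNames(g), 1),
                            disease = sample(diseaseNames(g), 1)))
    gd2 <- unique(gd2)
    g2 <- buildTripartite(
      data.frame(drug_id = g@drugGeneEdges$drug,
                 gene_symbol = g@drugGeneEdges$gene),
      data.frame(gene_symbol = gd2$gene, disease_id = gd2$disease))
    grown <- similarityEdges(projectDDSN(g2))
    key <- function(df) paste(df$from, df$to)
    common <- intersect(key(base), key(grown))
    expect_true(all(key(base) %in% key(grown)))
    expect_true(all(grown$weight[match(common, key(grown))] >=
                    base$weight[match(common, key(base))]))
  }
})
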