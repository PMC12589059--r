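#' Build the tripartite drug-gene-disease graph
#'
#' Assembles the directed tripartite graph from interaction and
#' association records. Vertex sets are exactly the identifiers
#' occurring in the records; edges are deduplicated; genes appearing in
#' only one of the two tables are retained as vertices even though they
#' carry no drug-to-disease through-path.
#'
#' @param drugGene data.frame from [readDrugGeneTable()] (columns
#'   \code{drug_id}, \code{gene_symbol}; extra columns ignored).
#' @param geneDisease data.frame from [readGeneDiseaseTable()] (columns
#'   \code{gene_symbol}, \code{disease_id}).
#' @return a [TripartiteGraph-class].
#' @examples
#' dg <- data.frame(drug_id = "M1", gene_symbol = "ADRA1A")
#' gd <- data.frame(gene_symbol = "ADRA1A", disease_id = "Hypertension")
#' buildTripartite(dg, gd)
#' @export
buildTripartite <- function(drugGene, geneDisease) {
  stopifnot(all(c("drug_id", "gene_symbol") %in% names(drugGene)),
            all(c("gene_symbol", "disease_id") %in% names(geneDisease)))
  drugs <- unique(as.character(drugGene$drug_id))
  genes <- unique(c(as.character(drugGene$gene_symbol),
                    as.character(geneDisease$gene_symbol)))
  diseases <- unique(as.character(geneDisease$disease_id))
  clash <- c(intersect(drugs, genes), intersect(drugs, diseases),
             intersect(genes, diseases))
  if (length(clash) > 0L)
    stop("identifier occurs in two vertex roles: ",
         paste(unique(utils::head(clash, 5L)), collapse = ", "))
  eg <- unique(data.frame(drug = as.character(drugGene$drug_id),
                          gene = as.character(drugGene$gene_symbol),
                          stringsAsFactors = FALSE))
  ed <- unique(data.frame(gene = as.character(geneDisease$gene_symbol),
                          disease = as.character(geneDisease$disease_id),
                          stringsAsFactors = FALSE))
  rownames(eg) <- rownames(ed) <- NULL
  new("TripartiteGraph", drugs = drugs, genes = genes, diseases = diseases,
      drugGeneEdges = eg, geneDiseaseEdges = ed)
}

#' Diseases reachable from a drug
#'
#' The set of diseases connected to a drug by at least one
#' drug-to-gene-to-disease path.
#'
#' @param graph a [TripartiteGraph-class].
#' @param drug a drug identifier present in the graph.
#' @return character vector of disease identifiers (possibly empty).
#' @export
reachableDiseases <- function(graph, drug) {
  stopifnot(is(graph, "TripartiteGraph"), length(drug) == 1L)
  if (!drug %in% graph@drugs) stop("unknown drug: ", drug)
  genes <- graph@drugGeneEdges$gene[graph@drugGeneEdges$drug == drug]
  if (length(genes) == 0L) return(character(0))
  ed <- graph@geneDiseaseEdges
  sort(unique(ed$disease[ed$gene %in% genes]))
}

# Reachable-disease sets for all drugs at once (list keyed by drug).
reachableDiseaseSets <- function(graph) {
  eg <- graph@drugGeneEdges
  ed <- graph@geneDiseaseEdges
  gene2dis <- split(ed$disease, factor(ed$gene, levels = graph@genes))
  drug2gene <- split(eg$gene, factor(eg$drug, levels = graph@drugs))
  out <- lapply(drug2gene, function(gs) {
    if (length(gs) == 0L) return(character(0))
    sort(unique(unlist(gene2dis[gs], use.names = FALSE)))
  })
  names(out) <- graph@drugs
  out
}

#' Internal constructor for a similarity network
#'
#' Canonicalises edges (unordered pairs stored with \code{from < to},
#' sorted) and validates the object.
#'
#' @param drugs character node set.
#' @param edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}.
#' @return a [SimilarityNetwork-class].
#' @keywords internal
#' @export
newSimilarityNetwork <- function(drugs, edges) {
  if (nrow(edges) > 0L) {
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]
    edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    edges <- edges[order(edges$from, edges$to), , drop = FALSE]
    edges$weight <- as.integer(edges$weight)
  }
  rownames(edges) <- NULL
  new("SimilarityNetwork", drugs = as.character(drugs), edges = edges)
}

#' Project the tripartite graph onto the drug-drug similarity network
#'
#' For every unordered drug pair the edge weight is the number of
#' distinct diseases reachable (via drug-gene-disease paths) from both
#' drugs; a disease reached through several genes counts once. Pairs
#' with weight below \code{minWeight} are omitted. All drugs remain
#' network nodes, including drugs with no similarity edge.
#'
#' @param graph a [TripartiteGraph-class].
#' @param minWeight minimum shared-disease count for an edge (default 1,
#'   i.e. any shared disease creates an edge).
#' @return a [SimilarityNetwork-class].
#' @export
projectDDSN <- function(graph, minWeight = 1L) {
  stopifnot(is(graph, "TripartiteGraph"))
  stopifnot(length(minWeight) == 1L, minWeight >= 1)
  drugs <- graph@drugs
  empty <- data.frame(from = character(), to = character(),
                      weight = integer(), stringsAsFactors = FALSE)
  if (length(drugs) < 2L) return(newSimilarityNetwork(drugs, empty))
  # incidence matrix drugs x diseases of the reachability relation
  sets <- reachableDiseaseSets(graph)
  alldis <- graph@diseases
  if (length(alldis) == 0L) return(newSimilarityNetwork(drugs, empty))
  inc <- matrix(0L, nrow = length(drugs), ncol = length(alldis),
                dimnames = list(drugs, alldis))
  for (d in drugs) inc[d, sets[[d]]] <- 1L
  shared <- tcrossprod(inc)  # pairwise intersection sizes
  idx <- which(upper.tri(shared) & shared >= minWeight, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(newSimilarityNetwork(drugs, empty))
  edges <- data.frame(from = drugs[idx[, 1L]], to = drugs[idx[, 2L]],
                      weight = as.integer(shared[idx]),
                      stringsAsFactors = FALSE)
  newSimilarityNetwork(drugs, edges)
}

#' Brute-force projection oracle
#'
#' Independent re-computation of [projectDDSN()] by exhaustive
#' enumeration of drug-gene-disease paths, intended for verification on
#' small graphs only (guarded at |drugs| * |diseases| <= 1e6).
#'
#' @inheritParams projectDDSN
#' @return a [SimilarityNetwork-class] that must equal the output of
#'   \code{projectDDSN(graph, 1)} exactly.
#' @export
oracleProject <- function(graph) {
  stopifnot(is(graph, "TripartiteGraph"))
  if (length(graph@drugs) * max(1L, length(graph@diseases)) > 1e6)
    stop("graph too large for the exhaustive oracle")
  drugs <- graph@drugs
  eg <- graph@drugGeneEdges
  ed <- graph@geneDiseaseEdges
  reaches <- function(m, d) {
    # does any path m -> g -> d exist?
    for (g in eg$gene[eg$drug == m])
      if (any(ed$gene == g & ed$disease == d)) return(TRUE)
    FALSE
  }
  rows <- list()
  if (length(drugs) >= 2L) {
    for (i in seq_len(length(drugs) - 1L)) {
      for (j in seq(i + 1L, length(drugs))) {
        w <- 0L
        for (d in graph@diseases)
          if (reaches(drugs[i], d) && reaches(drugs[j], d)) w <- w + 1L
        if (w >= 1L)
          rows[[length(rows) + 1L]] <-
            data.frame(from = drugs[i], to = drugs[j], weight = w,
                       stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(rows)) do.call(rbind, rows) else
    data.frame(from = character(), to = character(), weight = integer())
  newSimilarityNetwork(drugs, edges)
}

# igraph view of a similarity network (undirected, weighted, includes
# isolated drugs).
asIgraph <- function(network) {
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(network@drugs),
                            name = network@drugs)
  e <- network@edges
  if (nrow(e) > 0L) {
    g <- igraph::add_edges(g, rbind(e$from, e$to))
    igraph::E(g)$weight <- e$weight
  }
  g
}
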