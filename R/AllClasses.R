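#' @import methods
NULL

#' Tripartite drug-gene-disease graph
#'
#' Directed graph over three pairwise disjoint vertex classes: drugs,
#' genes and diseases. Edges run only from drugs to genes (interaction
#' records) and from genes to diseases (association records). A drug and
#' a disease are connected when some gene carries both an incoming
#' drug edge and an outgoing disease edge.
#'
#' @slot drugs character vector of drug identifiers.
#' @slot genes character vector of gene symbols.
#' @slot diseases character vector of disease identifiers.
#' @slot drugGeneEdges data.frame with columns \code{drug}, \code{gene};
#'   deduplicated directed edges.
#' @slot geneDiseaseEdges data.frame with columns \code{gene},
#'   \code{disease}; deduplicated directed edges.
#'
#' @seealso [buildTripartite()], [projectDDSN()]
#' @export
setClass("TripartiteGraph",
  representation(
    drugs = "character",
    genes = "character",
    diseases = "character",
    drugGeneEdges = "data.frame",
    geneDiseaseEdges = "data.frame"
  )
)

setValidity("TripartiteGraph", function(object) {
  msgs <- character()
  dup <- intersect(object@drugs, object@genes)
  dup <- union(dup, intersect(object@drugs, object@diseases))
  dup <- union(dup, intersect(object@genes, object@diseases))
  if (length(dup) > 0L)
    msgs <- c(msgs, paste0(
      "vertex classes must be disjoint; identifier(s) in two roles: ",
      paste(utils::head(dup, 5L), collapse = ", ")))
  eg <- object@drugGeneEdges
  ed <- object@geneDiseaseEdges
  if (!all(c("drug", "gene") %in% names(eg)))
    msgs <- c(msgs, "drugGeneEdges needs columns 'drug' and 'gene'")
  else {
    if (!all(eg$drug %in% object@drugs))
      msgs <- c(msgs, "drugGeneEdges references unknown drug")
    if (!all(eg$gene %in% object@genes))
      msgs <- c(msgs, "drugGeneEdges references unknown gene")
    if (anyDuplicated(eg[c("drug", "gene")]))
      msgs <- c(msgs, "duplicate drug-gene edges")
  }
  if (!all(c("gene", "disease") %in% names(ed)))
    msgs <- c(msgs, "geneDiseaseEdges needs columns 'gene' and 'disease'")
  else {
    if (!all(ed$gene %in% object@genes))
      msgs <- c(msgs, "geneDiseaseEdges references unknown gene")
    if (!all(ed$disease %in% object@diseases))
      msgs <- c(msgs, "geneDiseaseEdges references unknown disease")
    if (anyDuplicated(ed[c("gene", "disease")]))
      msgs <- c(msgs, "duplicate gene-disease edges")
  }
  if (anyDuplicated(object@drugs)) msgs <- c(msgs, "duplicated drug ids")
  if (anyDuplicated(object@genes)) msgs <- c(msgs, "duplicated gene symbols")
  if (anyDuplicated(object@diseases)) msgs <- c(msgs, "duplicated disease ids")
  if (length(msgs)) msgs else TRUE
})

#' Weighted drug-drug similarity network
#'
#' Undirected weighted graph over drugs obtained by projecting a
#' [TripartiteGraph-class]. The weight of an edge between two drugs is
#' the number of distinct diseases reachable from both drugs through
#' drug-gene-disease paths. Isolated drugs (no similarity edge) are kept
#' as nodes so that downstream community filtering can discard them by
#' the connectivity rule.
#'
#' @slot drugs character vector of drug identifiers (the node set).
#' @slot edges data.frame with columns \code{from}, \code{to},
#'   \code{weight}; one row per unordered pair, stored with
#'   \code{from < to}; integer weights >= 1.
#'
#' @seealso [projectDDSN()], [hierarchicalCommunities()]
#' @export
setClass("SimilarityNetwork",
  representation(
    drugs = "character",
    edges = "data.frame"
  )
)

setValidity("SimilarityNetwork", function(object) {
  msgs <- character()
  e <- object@edges
  if (!all(c("from", "to", "weight") %in% names(e)))
    return("edges needs columns 'from', 'to', 'weight'")
  if (anyDuplicated(object@drugs)) msgs <- c(msgs, "duplicated drug ids")
  if (nrow(e) > 0L) {
    if (!all(e$from %in% object@drugs) || !all(e$to %in% object@drugs))
      msgs <- c(msgs, "edge endpoint not in node set")
    if (any(e$from == e$to)) msgs <- c(msgs, "self-loop present")
    if (any(e$from >= e$to))
      msgs <- c(msgs, "edges must be stored canonically with from < to")
    if (anyDuplicated(e[c("from", "to")]))
      msgs <- c(msgs, "duplicate edges")
    if (any(e$weight < 1) || any(e$weight != round(e$weight)))
      msgs <- c(msgs, "weights must be positive integers")
  }
  if (length(msgs)) msgs else TRUE
})

#' Community partition of a similarity network
#'
#' Result of hierarchical community detection (and optionally of the
#' connectivity/size filter). Clusters are disjoint drug sets numbered
#' by descending size (ties broken by the lexicographically smallest
#' member). The merge history of the agglomeration is retained per
#' connected component as provenance for the dendrogram cut.
#'
#' @slot clusters list of character vectors; cluster i is element i.
#' @slot modularity numeric scalar; weighted Newman-Girvan modularity of
#'   the partition on the network it was computed from.
#' @slot merges list of per-component merge records (data.frames with
#'   columns \code{a}, \code{b}, \code{similarity}), the dendrogram
#'   provenance.
#' @slot excluded data.frame with columns \code{cluster}, \code{size},
#'   \code{reason}; clusters removed by [filterCommunities()] (empty
#'   before filtering).
#'
#' @seealso [hierarchicalCommunities()], [filterCommunities()]
#' @export
setClass("CommunityPartition",
  representation(
    clusters = "list",
    modularity = "numeric",
    merges = "list",
    excluded = "data.frame"
  ),
  prototype(
    clusters = list(),
    modularity = NA_real_,
    merges = list(),
    excluded = data.frame(cluster = integer(), size = integer(),
                          reason = character())
  )
)

setValidity("CommunityPartition", function(object) {
  msgs <- character()
  all_members <- unlist(object@clusters, use.names = FALSE)
  if (anyDuplicated(all_members))
    msgs <- c(msgs, "clusters are not disjoint")
  sizes <- lengths(object@clusters)
  if (length(sizes) > 1L && any(diff(sizes) > 0L))
    msgs <- c(msgs, "clusters must be numbered by descending size")
  if (length(object@modularity) != 1L)
    msgs <- c(msgs, "modularity must be a scalar")
  else if (!is.na(object@modularity) &&
           (object@modularity < -1 || object@modularity > 1))
    msgs <- c(msgs, "modularity outside [-1, 1]")
  if (length(msgs)) msgs else TRUE
})
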