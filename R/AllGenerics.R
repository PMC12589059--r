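#' Accessors for ddsnet graph objects
#'
#' @param object a [TripartiteGraph-class], [SimilarityNetwork-class] or
#'   [CommunityPartition-class].
#' @return \code{drugNames}: character vector of drug identifiers.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("drugNames", function(object) standardGeneric("drugNames"))

#' @rdname accessors
#' @return \code{geneNames}: character vector of gene symbols.
#' @export
setGeneric("geneNames", function(object) standardGeneric("geneNames"))

#' @rdname accessors
#' @return \code{diseaseNames}: character vector of disease identifiers.
#' @export
setGeneric("diseaseNames", function(object) standardGeneric("diseaseNames"))

#' @rdname accessors
#' @return \code{similarityEdges}: data.frame (from, to, weight).
#' @export
setGeneric("similarityEdges", function(object) standardGeneric("similarityEdges"))

#' @rdname accessors
#' @return \code{communityList}: list of character vectors, one per cluster.
#' @export
setGeneric("communityList", function(object) standardGeneric("communityList"))

#' @rdname accessors
#' @return \code{communitySizes}: integer vector of cluster sizes.
#' @export
setGeneric("communitySizes", function(object) standardGeneric("communitySizes"))

#' @rdname accessors
#' @return \code{excludedCommunities}: data.frame (cluster, size, reason).
#' @export
setGeneric("excludedCommunities",
           function(object) standardGeneric("excludedCommunities"))

#' @rdname accessors
#' @return \code{partitionModularity}: numeric modularity of the partition.
#' @export
setGeneric("partitionModularity",
           function(object) standardGeneric("partitionModularity"))

setMethod("drugNames", "TripartiteGraph", function(object) object@drugs)
setMethod("drugNames", "SimilarityNetwork", function(object) object@drugs)
setMethod("geneNames", "TripartiteGraph", function(object) object@genes)
setMethod("diseaseNames", "TripartiteGraph", function(object) object@diseases)
setMethod("similarityEdges", "SimilarityNetwork", function(object) object@edges)
setMethod("communityList", "CommunityPartition", function(object) object@clusters)
setMethod("communitySizes", "CommunityPartition",
          function(object) lengths(object@clusters))
setMethod("excludedCommunities", "CommunityPartition",
          function(object) object@excluded)
setMethod("partitionModularity", "CommunityPartition",
          function(object) object@modularity)

setMethod("show", "TripartiteGraph", function(object) {
  cat("TripartiteGraph\n")
  cat("  drugs:   ", length(object@drugs), "\n")
  cat("  genes:   ", length(object@genes), "\n")
  cat("  diseases:", length(object@diseases), "\n")
  cat("  drug-gene edges:   ", nrow(object@drugGeneEdges), "\n")
  cat("  gene-disease edges:", nrow(object@geneDiseaseEdges), "\n")
  invisible(NULL)
})

setMethod("show", "SimilarityNetwork", function(object) {
  cat("SimilarityNetwork (drug-drug similarity, weights = shared diseases)\n")
  cat("  drugs:", length(object@drugs), "  edges:", nrow(object@edges), "\n")
  if (nrow(object@edges) > 0L)
    cat("  weight range: [", min(object@edges$weight), ",",
        max(object@edges$weight), "]\n")
  invisible(NULL)
})

setMethod("show", "CommunityPartition", function(object) {
  n <- length(object@clusters)
  cat("CommunityPartition:", n, "cluster(s),",
      sum(lengths(object@clusters)), "drugs\n")
  if (n > 0L) {
    sizes <- lengths(object@clusters)
    cat("  sizes:", paste(utils::head(sizes, 10L), collapse = ", "),
        if (n > 10L) "..." else "", "\n")
  }
  if (!is.na(object@modularity))
    cat("  modularity Q =", format(object@modularity, digits = 4), "\n")
  if (nrow(object@excluded) > 0L)
    cat("  excluded clusters:", nrow(object@excluded), "\n")
  invisible(NULL)
})
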