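# Cosine-similarity matrix over the given nodes, computed from weighted
# adjacency rows augmented with a diagonal self-entry equal to the
# node's weighted degree (so that adjacent nodes without shared
# neighbours still attract).
augmentedCosine <- function(network, nodes) {
  drugs <- sort(network@drugs)
  A <- matrix(0, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  e <- network@edges
  if (nrow(e) > 0L) {
    A[cbind(e$from, e$to)] <- e$weight
    A[cbind(e$to, e$from)] <- e$weight
  }
  diag(A) <- rowSums(A)
  M <- A[nodes, , drop = FALSE]
  nrm <- sqrt(rowSums(M^2))
  S <- tcrossprod(M)
  denom <- outer(nrm, nrm)
  S <- ifelse(denom > 0, S / denom, 0)
  # clamp numerical overshoot
  S[S > 1] <- 1
  S[S < 0] <- 0
  diag(S) <- 1
  S
}

#' Vertex similarity between two drugs
#'
#' Cosine similarity of the two drugs' weighted adjacency vectors, each
#' augmented with a self-entry equal to the drug's weighted degree.
#' This is the pairwise measure driving the hierarchical agglomeration:
#' drugs connected to the same neighbours with similar weights score
#' near 1; drugs with neither a mutual edge nor common neighbours score
#' 0.
#'
#' @param network a [SimilarityNetwork-class].
#' @param drugA,drugB drug identifiers present in the network.
#' @return numeric in [0, 1]; symmetric in its arguments.
#' @export
vertexSimilarity <- function(network, drugA, drugB) {
  stopifnot(is(network, "SimilarityNetwork"))
  miss <- setdiff(c(drugA, drugB), network@drugs)
  if (length(miss) > 0L) stop("unknown drug: ", miss[[1L]])
  S <- augmentedCosine(network, c(drugA, drugB))
  unname(S[drugA, drugB])
}

# Order clusters by descending size; ties broken by the
# lexicographically smallest member. Members sorted within clusters.
orderClusters <- function(clusters) {
  clusters <- lapply(clusters, function(x) sort(as.character(x)))
  first <- vapply(clusters, `[[`, character(1), 1L)
  clusters[order(-lengths(clusters), first)]
}

# Weighted Newman-Girvan modularity contribution of clustering `labels`
# over component nodes, against global total weight m2 = 2m. A is the
# full symmetric adjacency matrix (zero diagonal).
componentQ <- function(A, nodes, labels, m2) {
  q <- 0
  for (lab in unique(labels)) {
    s <- nodes[labels == lab]
    w_in <- sum(A[s, s, drop = FALSE])      # ordered pairs
    k_sum <- sum(A[s, , drop = FALSE])      # strengths
    q <- q + w_in / m2 - (k_sum / m2)^2
  }
  q
}

#' Hierarchical community detection with a modularity-optimal cut
#'
#' Detects drug communities by agglomerative clustering on the
#' augmented-cosine vertex similarity (see [vertexSimilarity()]) with
#' the chosen linkage, restricted to connected components (no merge
#' ever crosses a component). Every cut of the per-component dendrogram
#' is scored by weighted Newman-Girvan modularity
#' \eqn{Q = (1/2m)\sum_{ij}[A_{ij} - k_i k_j/(2m)]\,\delta(c_i,c_j)}
#' and the maximising cut is returned; because Q is additive over
#' clusters, each component's cut is optimised independently against
#' the global degree null model. The procedure is deterministic: nodes
#' are processed in lexicographic order and ties in the cut score are
#' resolved towards fewer clusters.
#'
#' @param network a non-empty [SimilarityNetwork-class].
#' @param linkage agglomeration linkage; only \code{"average"} is
#'   supported.
#' @param seed integer kept for interface stability; the algorithm is
#'   deterministic and does not consume randomness.
#' @return a [CommunityPartition-class] with clusters numbered by
#'   descending size and per-component merge provenance.
#' @export
hierarchicalCommunities <- function(network, linkage = c("average"),
                                    seed = 0L) {
  stopifnot(is(network, "SimilarityNetwork"))
  linkage <- match.arg(linkage)
  if (length(network@drugs) == 0L)
    stop("cannot detect communities in an empty network")
  drugs <- sort(network@drugs)
  A <- matrix(0, length(drugs), length(drugs),
              dimnames = list(drugs, drugs))
  e <- network@edges
  if (nrow(e) > 0L) {
    A[cbind(e$from, e$to)] <- e$weight
    A[cbind(e$to, e$from)] <- e$weight
  }
  m2 <- sum(A)  # = 2m
  g <- asIgraph(network)
  comp <- igraph::components(g)
  membership <- comp$membership[drugs]
  clusters <- list()
  merges <- list()
  for (cid in sort(unique(membership))) {
    nodes <- drugs[membership == cid]
    if (length(nodes) == 1L) {
      clusters[[length(clusters) + 1L]] <- nodes
      next
    }
    S <- augmentedCosine(network, nodes)
    hc <- stats::hclust(stats::as.dist(1 - S), method = linkage)
    bestK <- 1L
    bestQ <- -Inf
    for (k in seq_along(nodes)) {
      labels <- stats::cutree(hc, k = k)
      q <- componentQ(A, nodes, labels, m2)
      if (q > bestQ + 1e-12) {  # ties keep the coarser partition
        bestQ <- q
        bestK <- k
      }
    }
    labels <- stats::cutree(hc, k = bestK)
    for (lab in unique(labels))
      clusters[[length(clusters) + 1L]] <- nodes[labels == lab]
    merges[[length(merges) + 1L]] <- data.frame(
      a = hc$merge[, 1L], b = hc$merge[, 2L],
      similarity = 1 - hc$height)
  }
  clusters <- orderClusters(clusters)
  part <- new("CommunityPartition", clusters = clusters,
              modularity = NA_real_, merges = merges,
              excluded = data.frame(cluster = integer(), size = integer(),
                                    reason = character()))
  part@modularity <- if (m2 > 0) modularityScore(network, part) else NA_real_
  validObject(part)
  part
}

#' Membership vector of a partition
#'
#' @param partition a [CommunityPartition-class].
#' @param drugs drug identifiers to look up.
#' @return named integer vector of cluster numbers (\code{NA} for drugs
#'   in no cluster).
#' @export
membershipVector <- function(partition, drugs) {
  out <- rep(NA_integer_, length(drugs))
  names(out) <- drugs
  for (i in seq_along(partition@clusters))
    out[intersect(drugs, partition@clusters[[i]])] <- i
  out
}

#' Weighted modularity of a partition
#'
#' Weighted Newman-Girvan modularity Q of a partition on a similarity
#' network. Q is 0 when all nodes form a single cluster and negative
#' when the partition is finer than the edge structure supports.
#'
#' @param network a [SimilarityNetwork-class] with at least one edge.
#' @param partition a [CommunityPartition-class] covering the network's
#'   node set exactly.
#' @return numeric Q in [-1, 1].
#' @export
modularityScore <- function(network, partition) {
  stopifnot(is(network, "SimilarityNetwork"),
            is(partition, "CommunityPartition"))
  member <- membershipVector(partition, network@drugs)
  if (anyNA(member))
    stop("partition does not cover the network node set (missing: ",
         paste(utils::head(names(member)[is.na(member)], 3L),
               collapse = ", "), ")")
  if (sum(lengths(partition@clusters)) != length(network@drugs))
    stop("partition contains drugs outside the network node set")
  g <- asIgraph(network)
  if (igraph::ecount(g) == 0L) return(NA_real_)
  igraph::modularity(g, member, weights = igraph::E(g)$weight)
}

#' Filter communities by connectivity and size
#'
#' Applies the exclusion rules used before labeling: clusters lying
#' entirely outside the network's largest connected component are
#' dropped (when \code{requireMainComponent}), then clusters with fewer
#' than \code{minSize} drugs are dropped. Survivors are renumbered by
#' descending size; removed clusters are recorded with their original
#' number and the reason in the \code{excluded} slot.
#'
#' @param partition a [CommunityPartition-class] over \code{network}.
#' @param network the [SimilarityNetwork-class] the partition was
#'   computed on.
#' @param minSize minimum cluster size retained (default 8).
#' @param requireMainComponent drop clusters outside the largest
#'   connected component (default \code{TRUE}; size ties go to the
#'   component containing the lexicographically smallest drug).
#' @return a filtered [CommunityPartition-class].
#' @export
filterCommunities <- function(partition, network, minSize = 8L,
                              requireMainComponent = TRUE) {
  stopifnot(is(partition, "CommunityPartition"),
            is(network, "SimilarityNetwork"))
  if (minSize < 1L) stop("'minSize' must be >= 1")
  mainNodes <- network@drugs
  if (requireMainComponent && length(network@drugs) > 0L) {
    comp <- igraph::components(asIgraph(network))
    sizes <- comp$csize
    best <- which(sizes == max(sizes))
    if (length(best) > 1L) {
      # deterministic tie-break: component of the smallest drug id
      firsts <- vapply(best, function(b)
        min(names(comp$membership)[comp$membership == b]), character(1))
      best <- best[order(firsts)][1L]
    }
    mainNodes <- names(comp$membership)[comp$membership == best]
  }
  keep <- list()
  exc <- list()
  for (i in seq_along(partition@clusters)) {
    cl <- partition@clusters[[i]]
    if (requireMainComponent && !any(cl %in% mainNodes)) {
      exc[[length(exc) + 1L]] <- data.frame(
        cluster = i, size = length(cl),
        reason = "disconnected_from_main_component")
    } else if (length(cl) < minSize) {
      exc[[length(exc) + 1L]] <- data.frame(
        cluster = i, size = length(cl), reason = "below_min_size")
    } else {
      keep[[length(keep) + 1L]] <- cl
    }
  }
  excluded <- if (length(exc)) do.call(rbind, exc) else
    data.frame(cluster = integer(), size = integer(), reason = character())
  rownames(excluded) <- NULL
  out <- new("CommunityPartition", clusters = orderClusters(keep),
             modularity = partition@modularity, merges = partition@merges,
             excluded = rbind(partition@excluded, excluded))
  validObject(out)
  out
}

#' Write a partition as TSV
#'
#' @param partition a [CommunityPartition-class].
#' @param path output TSV path for (drug_id, cluster_number) rows.
#' @param excludedPath optional output path for the excluded-cluster
#'   table (cluster_number, size, exclusion_reason).
#' @export
writePartition <- function(partition, path, excludedPath = NULL) {
  rows <- do.call(rbind, lapply(seq_along(partition@clusters), function(i)
    data.frame(drug_id = partition@clusters[[i]], cluster_number = i)))
  if (is.null(rows))
    rows <- data.frame(drug_id = character(), cluster_number = integer())
  writeTSV(rows, path)
  if (!is.null(excludedPath)) {
    exc <- partition@excluded
    names(exc) <- c("cluster_number", "size", "exclusion_reason")
    writeTSV(exc, excludedPath)
  }
  invisible(path)
}
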