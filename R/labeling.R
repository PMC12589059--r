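#' Per-cluster ATC histogram at a given level
#'
#' Counts, for each ATC prefix at the requested level, how many drugs
#' in the cluster carry at least one code with that prefix. A drug with
#' several codes sharing a prefix contributes once per distinct prefix;
#' drugs without ATC codes contribute nothing. When
#' \code{restrictToLabel} is given (used for levels 2-4 after the
#' cluster label has been assigned), only codes whose level-1 prefix
#' equals the label are counted.
#'
#' @param cluster character vector of drug identifiers.
#' @param annotations named list drug -> character vector of ATC codes
#'   (see [annotationsFor()]).
#' @param level integer in 1..4.
#' @param restrictToLabel optional level-1 letter restricting the
#'   counted codes.
#' @return named integer vector (prefix -> drug count); strictly
#'   positive counts only; sorted by prefix.
#' @export
levelHistogram <- function(cluster, annotations, level,
                           restrictToLabel = NULL) {
  if (!is.numeric(level) || length(level) != 1L || !level %in% 1:4)
    stop("'level' must be an integer in 1..4")
  if (length(cluster) == 0L) stop("cluster is empty")
  ann <- annotationsFor(cluster, annotations)
  counts <- integer(0)
  for (codes in ann) {
    codes <- codes[nchar(codes) >= .atc_level_len[level]]
    if (!is.null(restrictToLabel))
      codes <- codes[substr(codes, 1L, 1L) == restrictToLabel]
    if (length(codes) == 0L) next
    prefixes <- unique(atcPrefix(codes, level))
    for (p in prefixes)
      counts[p] <- if (p %in% names(counts)) counts[[p]] + 1L else 1L
  }
  if (length(counts) == 0L) return(structure(integer(0), names = character(0)))
  counts[order(names(counts))]
}

#' Dominant code of a histogram
#'
#' The prefix with the maximal drug count; ties are broken towards the
#' lexicographically smallest prefix with a warning.
#'
#' @param histogram named integer vector from [levelHistogram()].
#' @return the dominant prefix (character scalar).
#' @export
dominantCode <- function(histogram) {
  if (length(histogram) == 0L)
    stop("empty histogram: cluster cannot be labeled")
  top <- names(histogram)[histogram == max(histogram)]
  top <- sort(top)
  if (length(top) > 1L)
    warning("dominant-code tie between ", paste(top, collapse = ", "),
            "; choosing ", top[[1L]])
  top[[1L]]
}

#' Split a cluster into label-matched drugs and repositioning candidates
#'
#' A drug is matched when any of its ATC codes has level-1 prefix equal
#' to the cluster label; every other cluster drug (including drugs with
#' no ATC codes) is a repositioning candidate for the label's
#' therapeutic area.
#'
#' @param cluster character vector of drug identifiers.
#' @param annotations named list drug -> ATC codes.
#' @param label a level-1 ATC letter.
#' @return list with character vectors \code{matched} and
#'   \code{candidates}; disjoint, jointly covering the cluster.
#' @export
classifyCluster <- function(cluster, annotations, label) {
  if (!(is.character(label) && length(label) == 1L && validateATC(label) &&
        nchar(label) == 1L))
    stop("'label' must be a valid level-1 ATC letter")
  ann <- annotationsFor(cluster, annotations)
  matched <- vapply(ann, function(codes)
    length(codes) > 0L && any(substr(codes, 1L, 1L) == label), logical(1))
  list(matched = sort(cluster[matched]),
       candidates = sort(cluster[!matched]))
}

#' Top level-4 ATC codes of a cluster
#'
#' Level-4 histogram of the cluster restricted to the label's codes,
#' ranked by drug count (codes sharing a count share a rank, then
#' lexicographic order within a rank). Codes occupying the top \code{k}
#' rank positions are returned; when several codes tie on one of those
#' counts the list may exceed \code{k} entries, with a message.
#'
#' @inheritParams classifyCluster
#' @param k number of top codes requested (default 3).
#' @return character vector of level-4 prefixes (possibly empty).
#' @export
topLevel4 <- function(cluster, annotations, label, k = 3L) {
  if (k < 1L) stop("'k' must be >= 1")
  h <- levelHistogram(cluster, annotations, 4L, restrictToLabel = label)
  if (length(h) == 0L) return(character(0))
  ord <- order(-h, names(h))
  h <- h[ord]
  ranks <- sort(unique(unname(h)), decreasing = TRUE)
  cutoff <- ranks[[min(k, length(ranks))]]
  keep <- h >= cutoff
  if (sum(keep) > k)
    message("count tie within the top ", k, " ranks expands the list to ",
            sum(keep), " codes")
  names(h)[keep]
}

#' Targets for level-4 ATC codes
#'
#' Restriction of an ATC-to-target map to the requested codes; codes
#' absent from the map return empty target sets with a warning.
#'
#' @param codes character vector of level-4 ATC prefixes.
#' @param atcTargetMap named list code -> character vector of target
#'   names (see [readAtcTargetTable()]).
#' @return named list over \code{codes}.
#' @export
targetsForCodes <- function(codes, atcTargetMap) {
  if (length(codes) == 0L) return(structure(list(), names = character(0)))
  ok <- validateATC(codes) & nchar(codes) == 5L
  if (any(!ok))
    stop("not a level-4 ATC prefix: ", codes[!ok][[1L]])
  out <- atcTargetMap[codes]
  names(out) <- codes
  missing <- vapply(out, is.null, logical(1))
  if (any(missing)) {
    warning("no targets mapped for code(s): ",
            paste(codes[missing], collapse = ", "))
    out[missing] <- list(character(0))
  }
  out
}

#' Full report for one labeled cluster
#'
#' Convenience wrapper producing histograms at levels 1-4, the dominant
#' level-1 label, the matched/candidate split, the percentage of
#' label-matched drugs and the top level-4 codes with mapped targets.
#'
#' @param clusterNumber integer cluster number.
#' @param cluster character vector of drug identifiers.
#' @param annotations named list drug -> ATC codes.
#' @param atcTargetMap named list level-4 code -> targets.
#' @param k top-k level-4 codes (default 3).
#' @return list with elements \code{cluster_number}, \code{size},
#'   \code{label}, \code{histograms}, \code{matched}, \code{candidates},
#'   \code{pct_predominant}, \code{top_level4}, \code{targets}.
#' @export
clusterReport <- function(clusterNumber, cluster, annotations,
                          atcTargetMap = list(), k = 3L) {
  h1 <- levelHistogram(cluster, annotations, 1L)
  label <- if (length(h1) > 0L) dominantCode(h1) else NA_character_
  if (is.na(label))
    return(list(cluster_number = clusterNumber, size = length(cluster),
                label = NA_character_, histograms = list(h1),
                matched = character(0), candidates = sort(cluster),
                pct_predominant = 0, top_level4 = character(0),
                targets = list()))
  hs <- list(h1,
             levelHistogram(cluster, annotations, 2L, label),
             levelHistogram(cluster, annotations, 3L, label),
             levelHistogram(cluster, annotations, 4L, label))
  cls <- classifyCluster(cluster, annotations, label)
  top4 <- topLevel4(cluster, annotations, label, k)
  targets <- if (length(top4) > 0L && length(atcTargetMap) > 0L)
    suppressWarnings(targetsForCodes(top4, atcTargetMap))
  else structure(vector("list", length(top4)), names = top4)
  list(cluster_number = clusterNumber, size = length(cluster),
       label = label, histograms = hs, matched = cls$matched,
       candidates = cls$candidates,
       pct_predominant = roundHalfAway(
         100 * length(cls$matched) / length(cluster), 1L),
       top_level4 = top4, targets = targets)
}

#' Accuracy summary over labeled clusters
#'
#' Aggregates per-cluster percentages of label-matched
#' (database-predominant) and literature-confirmed drugs into weighted
#' totals. Because the per-cluster percentages are reported rounded,
#' the underlying integer counts are first reconstructed as
#' nearest-integers of size x pct / 100; the weighted totals and
#' per-row accuracies are computed from those counts and rounded
#' half-away-from-zero to one decimal. The overall accuracy is the sum
#' of the two rounded weighted totals and the candidate percentage its
#' complement to 100.
#'
#' @param rows data.frame with columns \code{cluster_number},
#'   \code{size}, \code{pct_predominant}, \code{pct_confirmed}
#'   (percentages in [0, 100]).
#' @return list with \code{per_cluster} (the input plus
#'   \code{pct_accuracy}) and scalars \code{weighted_pct_predominant},
#'   \code{weighted_pct_confirmed}, \code{total_accuracy},
#'   \code{pct_candidates}.
#' @export
accuracySummary <- function(rows) {
  req <- c("cluster_number", "size", "pct_predominant", "pct_confirmed")
  stopifnot(all(req %in% names(rows)), nrow(rows) >= 1L)
  if (any(rows$size < 1L)) stop("cluster sizes must be >= 1")
  if (any(rows$pct_predominant < 0 | rows$pct_predominant > 100 |
          rows$pct_confirmed < 0 | rows$pct_confirmed > 100))
    stop("percentages must lie in [0, 100]")
  n_pred <- roundHalfAway(rows$size * rows$pct_predominant / 100)
  n_conf <- roundHalfAway(rows$size * rows$pct_confirmed / 100)
  over <- which(n_pred + n_conf > rows$size)
  if (length(over) > 0L)
    stop("reconstructed counts exceed cluster size for cluster ",
         rows$cluster_number[[over[[1L]]]])
  rows$pct_accuracy <- roundHalfAway(100 * (n_pred + n_conf) / rows$size, 1L)
  wp <- roundHalfAway(100 * sum(n_pred) / sum(rows$size), 1L)
  wc <- roundHalfAway(100 * sum(n_conf) / sum(rows$size), 1L)
  list(per_cluster = rows,
       weighted_pct_predominant = wp,
       weighted_pct_confirmed = wc,
       total_accuracy = wp + wc,
       pct_candidates = roundHalfAway(100 - (wp + wc), 1L))
}
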