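#' Build a PubMed validation query
#'
#' Composes the Boolean query used to look for literature evidence that
#' a repositioning candidate already exhibits the pharmacological
#' property of its community label. The template is fixed: the drug
#' name is an exact MeSH clause, AND-combined with the category clause
#' (the first category term as a MeSH clause, OR-combined with its
#' synonyms as Title/Abstract clauses), AND-combined with
#' publication-type filters restricting results to research articles
#' and clinical trials.
#'
#' @param drugTerm drug name (MeSH-intended), non-empty.
#' @param categoryTerms character vector: the ATC category name followed
#'   by any synonyms; must be non-empty.
#' @param filters publication-type filter tags (default clinical trials
#'   and classical research articles); empty vector omits the clause.
#' @return the query string; a pure function of its arguments.
#' @examples
#' buildQuery("chloramphenicol", c("antineoplastic agents", "anticancer"))
#' @export
buildQuery <- function(drugTerm,
                       categoryTerms,
                       filters = c("clinicaltrial", "classicalarticle")) {
  stopifnot(is.character(drugTerm), length(drugTerm) == 1L,
            nzchar(drugTerm))
  if (length(categoryTerms) == 0L || any(!nzchar(categoryTerms)))
    stop("'categoryTerms' must be a non-empty vector of non-empty terms")
  drug <- sprintf('"%s"[MeSH Terms]', drugTerm)
  cat1 <- sprintf('"%s"[MeSH Terms]', categoryTerms[[1L]])
  category <- if (length(categoryTerms) == 1L) cat1 else
    paste0("(", paste(c(cat1, sprintf('"%s"[Title/Abstract]',
                                      categoryTerms[-1L])),
                      collapse = " OR "), ")")
  parts <- c(drug, category)
  if (length(filters) > 0L) {
    fl <- sprintf("%s[Filter]", filters)
    parts <- c(parts, if (length(fl) == 1L) fl else
      paste0("(", paste(fl, collapse = " OR "), ")"))
  }
  paste(parts, collapse = " AND ")
}

#' Queries for all candidates of a hint table
#'
#' @param hints data.frame of repositioning hints (see
#'   [makeHints()]); rows with status \code{"candidate"} get a query
#'   built from the drug id and the label's anatomical group name.
#' @param synonyms optional named list: level-1 letter -> character
#'   vector of synonym terms appended to the category name.
#' @return data.frame (drug_id, cluster_number, query).
#' @export
candidateQueries <- function(hints, synonyms = list()) {
  cand <- hints[hints$status == "candidate", , drop = FALSE]
  if (nrow(cand) == 0L)
    return(data.frame(drug_id = character(), cluster_number = integer(),
                      query = character()))
  q <- vapply(seq_len(nrow(cand)), function(i) {
    letter <- cand$predicted_level1[[i]]
    terms <- c(unname(atcLevel1Names[letter]), synonyms[[letter]])
    terms <- terms[!is.na(terms)]
    if (length(terms) == 0L) terms <- letter
    buildQuery(cand$drug_id[[i]], terms)
  }, character(1))
  data.frame(drug_id = cand$drug_id, cluster_number = cand$cluster_number,
             query = q, stringsAsFactors = FALSE)
}

#' Fold literature evidence into repositioning hints
#'
#' Candidates with confirming evidence (a screened record with
#' \code{confirmed = TRUE}) are promoted to status
#' \code{"literature-confirmed"}; all other statuses are untouched
#' (evidence for a db-matched drug raises a consistency warning, never
#' a demotion). Per-cluster confirmed percentages are recomputed for
#' the accuracy summary.
#'
#' @param hints data.frame with columns \code{drug_id},
#'   \code{cluster_number}, \code{status} (among \code{"db-matched"},
#'   \code{"literature-confirmed"}, \code{"candidate"}).
#' @param evidence data.frame with columns \code{drug_id},
#'   \code{cluster_number}, \code{pmids} (semicolon-joined string),
#'   \code{confirmed} (logical). A confirmed record must carry at least
#'   one PMID.
#' @return list with \code{hints} (updated statuses) and
#'   \code{confirmed_counts} (data.frame cluster_number, n_confirmed).
#' @export
applyValidation <- function(hints, evidence) {
  stopifnot(all(c("drug_id", "cluster_number", "status") %in% names(hints)))
  stopifnot(all(c("drug_id", "cluster_number", "confirmed") %in%
                names(evidence)))
  if (nrow(evidence) > 0L) {
    key_h <- paste(hints$drug_id, hints$cluster_number)
    key_e <- paste(evidence$drug_id, evidence$cluster_number)
    unknown <- setdiff(key_e, key_h)
    if (length(unknown) > 0L)
      stop("evidence refers to unknown hint: ", unknown[[1L]])
    if ("pmids" %in% names(evidence)) {
      nopmid <- evidence$confirmed & !nzchar(trimws(evidence$pmids))
      if (any(nopmid))
        stop("confirmed evidence without a PMID for drug ",
             evidence$drug_id[nopmid][[1L]])
    }
    for (i in seq_len(nrow(evidence))) {
      j <- which(key_h == key_e[[i]])
      if (hints$status[[j]] == "db-matched") {
        warning("evidence supplied for db-matched drug ",
                evidence$drug_id[[i]], "; ignored")
        next
      }
      if (isTRUE(evidence$confirmed[[i]]) &&
          hints$status[[j]] == "candidate")
        hints$status[[j]] <- "literature-confirmed"
    }
  }
  conf <- hints[hints$status == "literature-confirmed", , drop = FALSE]
  counts <- as.data.frame(table(factor(conf$cluster_number,
                                       levels = sort(unique(hints$cluster_number)))),
                          stringsAsFactors = FALSE)
  names(counts) <- c("cluster_number", "n_confirmed")
  counts$cluster_number <- as.integer(counts$cluster_number)
  counts$n_confirmed <- as.integer(counts$n_confirmed)
  list(hints = hints, confirmed_counts = counts)
}

#' Assemble the repositioning-hint table for labeled clusters
#'
#' One row per drug of every surviving cluster: the cluster number, the
#' predicted level-1 property (the cluster label), the initial status
#' (\code{"db-matched"} for label-matched drugs, \code{"candidate"}
#' otherwise), the cluster's top level-4 codes and the union of their
#' mapped targets.
#'
#' @param reports list of [clusterReport()] results.
#' @return data.frame (drug_id, cluster_number, predicted_level1,
#'   status, top_level4_codes, targets).
#' @export
makeHints <- function(reports) {
  rows <- lapply(reports, function(r) {
    drugs <- c(r$matched, r$candidates)
    if (length(drugs) == 0L) return(NULL)
    data.frame(
      drug_id = drugs,
      cluster_number = r$cluster_number,
      predicted_level1 = r$label,
      status = c(rep("db-matched", length(r$matched)),
                 rep("candidate", length(r$candidates))),
      top_level4_codes = paste(r$top_level4, collapse = ";"),
      targets = paste(sort(unique(unlist(r$targets, use.names = FALSE))),
                      collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(drug_id = character(), cluster_number = integer(),
                      predicted_level1 = character(), status = character(),
                      top_level4_codes = character(), targets = character())
  rownames(out) <- NULL
  out
}

#' Read an evidence table
#'
#' TSV with columns drug_id, cluster_number, pmids (semicolon-joined),
#' confirmed (true/false).
#'
#' @param path TSV file path.
#' @return data.frame suitable for [applyValidation()].
#' @export
readEvidenceTable <- function(path) {
  df <- readTSV(path)
  requireColumns(df, c("drug_id", "cluster_number", "confirmed"), path)
  df$cluster_number <- as.integer(df$cluster_number)
  df$confirmed <- tolower(df$confirmed) %in% c("true", "t", "1", "yes")
  if (!"pmids" %in% names(df)) df$pmids <- ""
  df
}
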