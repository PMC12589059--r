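#' Table dialect descriptor
#'
#' The pipeline's four input tables are UTF-8 TSV files with a header
#' row; column names vary between upstream exports, so every reader
#' takes a dialect descriptor mapping the logical field names to the
#' columns of the file at hand. The defaults are the names the
#' synthetic-data generator emits.
#'
#' @param drug_id,drug_name,gene_symbol,relation_type,disease_id,disease_name,score,atc_code,target_name
#'   column names for the corresponding logical fields.
#' @return a named list of class \code{"tableDialect"}.
#' @export
tableDialect <- function(drug_id = "drug_id", drug_name = "drug_name",
                         gene_symbol = "gene_symbol",
                         relation_type = "relation_type",
                         disease_id = "disease_id",
                         disease_name = "disease_name",
                         score = "score", atc_code = "atc_code",
                         target_name = "target_name") {
  structure(list(drug_id = drug_id, drug_name = drug_name,
                 gene_symbol = gene_symbol, relation_type = relation_type,
                 disease_id = disease_id, disease_name = disease_name,
                 score = score, atc_code = atc_code,
                 target_name = target_name),
            class = "tableDialect")
}

#' Default vocabulary of drug-gene relation types
#'
#' The DrugBank-style interaction classes a drug-gene record may carry.
#' @export
relationVocabulary <- c("target", "enzyme", "transporter", "carrier")

#' Read a drug-gene interaction table
#'
#' One row per drug-gene interaction (DrugBank-like). Exact duplicate
#' (drug_id, gene_symbol, relation_type) rows are collapsed to one
#' record with a warning, so that duplicated upstream exports cannot
#' inflate projection weights.
#'
#' @param path TSV file path.
#' @param dialect a [tableDialect()] mapping logical fields to columns.
#' @param relationTypes closed vocabulary of admissible relation types.
#' @param relationWhitelist optional subset of relation types to retain;
#'   \code{NULL} (default) keeps all.
#' @return data.frame with columns \code{drug_id}, \code{drug_name},
#'   \code{gene_symbol}, \code{relation_type}, in file order.
#' @export
readDrugGeneTable <- function(path, dialect = tableDialect(),
                              relationTypes = relationVocabulary,
                              relationWhitelist = NULL) {
  df <- readTSV(path)
  cols <- c(dialect$drug_id, dialect$drug_name, dialect$gene_symbol,
            dialect$relation_type)
  requireColumns(df, cols, path)
  out <- data.frame(drug_id = df[[dialect$drug_id]],
                    drug_name = df[[dialect$drug_name]],
                    gene_symbol = df[[dialect$gene_symbol]],
                    relation_type = df[[dialect$relation_type]],
                    stringsAsFactors = FALSE)
  # data rows are 1-based below the header, so file line = row + 1
  bad <- which(out$drug_id == "" | out$gene_symbol == "")
  if (length(bad) > 0L)
    stop("empty drug_id or gene_symbol at line ", bad[[1L]] + 1L,
         " of ", path)
  badrel <- which(!out$relation_type %in% relationTypes)
  if (length(badrel) > 0L)
    stop("relation_type '", out$relation_type[[badrel[[1L]]]],
         "' at line ", badrel[[1L]] + 1L, " of ", path,
         " is not in the declared vocabulary")
  if (!is.null(relationWhitelist))
    out <- out[out$relation_type %in% relationWhitelist, , drop = FALSE]
  key <- paste(out$drug_id, out$gene_symbol, out$relation_type, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    warning(sum(dup), " duplicate drug-gene row(s) collapsed in ", path)
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a gene-disease association table
#'
#' One row per gene-disease association (DisGeNET-like), with an
#' optional confidence score in [0, 1]. When \code{scoreThreshold} is
#' supplied, rows with a score below it are dropped; rows with no score
#' always pass.
#'
#' @inheritParams readDrugGeneTable
#' @param scoreThreshold optional numeric in [0, 1].
#' @return data.frame with columns \code{gene_symbol},
#'   \code{disease_id}, \code{disease_name}, \code{score} (numeric,
#'   \code{NA} when absent).
#' @export
readGeneDiseaseTable <- function(path, scoreThreshold = NULL,
                                 dialect = tableDialect()) {
  df <- readTSV(path)
  cols <- c(dialect$gene_symbol, dialect$disease_id, dialect$disease_name)
  requireColumns(df, cols, path)
  score <- if (dialect$score %in% names(df)) {
    s <- df[[dialect$score]]
    s[s == ""] <- NA_character_
    suppressWarnings(as.numeric(s))
  } else rep(NA_real_, nrow(df))
  out <- data.frame(gene_symbol = df[[dialect$gene_symbol]],
                    disease_id = df[[dialect$disease_id]],
                    disease_name = df[[dialect$disease_name]],
                    score = score, stringsAsFactors = FALSE)
  bad <- which(out$gene_symbol == "" | out$disease_id == "")
  if (length(bad) > 0L)
    stop("empty gene_symbol or disease_id at line ", bad[[1L]] + 1L,
         " of ", path)
  badscore <- which(!is.na(out$score) & (out$score < 0 | out$score > 1))
  if (length(badscore) > 0L)
    stop("score outside [0, 1] at line ", badscore[[1L]] + 1L,
         " of ", path)
  if (!is.null(scoreThreshold)) {
    stopifnot(is.numeric(scoreThreshold), length(scoreThreshold) == 1L)
    keep <- is.na(out$score) | out$score >= scoreThreshold
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Read a drug-ATC annotation table
#'
#' One row per (drug, ATC code) pair; codes are grouped per drug and
#' normalised to uppercase. A syntactically invalid code (including an
#' empty string) is a row-level error naming the offending string.
#'
#' @inheritParams readDrugGeneTable
#' @return named list: drug_id to character vector of distinct valid
#'   ATC codes.
#' @seealso [annotationsFor()] for lookups that return empty sets for
#'   unannotated drugs.
#' @export
readDrugAtcTable <- function(path, dialect = tableDialect()) {
  df <- readTSV(path)
  cols <- c(dialect$drug_id, dialect$atc_code)
  requireColumns(df, cols, path)
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  drug <- df[[dialect$drug_id]]
  code <- toupper(df[[dialect$atc_code]])
  bad <- which(drug == "")
  if (length(bad) > 0L)
    stop("empty drug_id at line ", bad[[1L]] + 1L, " of ", path)
  invalid <- which(!validateATC(code))
  if (length(invalid) > 0L)
    stop("invalid ATC code '", code[[invalid[[1L]]]], "' at line ",
         invalid[[1L]] + 1L, " of ", path)
  lapply(split(code, factor(drug, levels = unique(drug))), unique)
}

#' Look up ATC annotations with empty-set defaults
#'
#' @param drugs character vector of drug identifiers.
#' @param annotations named list from [readDrugAtcTable()].
#' @return named list over \code{drugs}; drugs absent from
#'   \code{annotations} map to \code{character(0)}.
#' @export
annotationsFor <- function(drugs, annotations) {
  out <- annotations[drugs]
  names(out) <- drugs
  out[vapply(out, is.null, logical(1))] <- list(character(0))
  out
}

#' Read an ATC level-4 to target mapping table
#'
#' One row per (level-4 ATC code, target name) pair; targets grouped
#' per code.
#'
#' @inheritParams readDrugGeneTable
#' @return named list: level-4 ATC prefix to character vector of target
#'   names.
#' @export
readAtcTargetTable <- function(path, dialect = tableDialect()) {
  df <- readTSV(path)
  cols <- c(dialect$atc_code, dialect$target_name)
  requireColumns(df, cols, path)
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  code <- toupper(df[[dialect$atc_code]])
  bad <- which(!(validateATC(code) & nchar(code) == 5L))
  if (length(bad) > 0L)
    stop("invalid level-4 ATC code '", code[[bad[[1L]]]], "' at line ",
         bad[[1L]] + 1L, " of ", path)
  lapply(split(df[[dialect$target_name]],
               factor(code, levels = unique(code))), unique)
}

#' Export / import a similarity network as GraphML
#'
#' Writes one node per drug (attributes \code{drug_id} and, when a
#' partition is supplied, \code{cluster}) and one undirected edge per
#' similarity link with an integer \code{weight} attribute. Re-reading
#' the file reproduces an isomorphic weighted graph.
#'
#' @param network a [SimilarityNetwork-class].
#' @param path output file path.
#' @param partition optional [CommunityPartition-class]; cluster numbers
#'   are stored as a node attribute.
#' @return \code{writeDDSNGraphML}: the path, invisibly.
#' @export
writeDDSNGraphML <- function(network, path, partition = NULL) {
  stopifnot(is(network, "SimilarityNetwork"))
  validObject(network)
  g <- asIgraph(network)
  igraph::V(g)$drug_id <- igraph::V(g)$name
  if (!is.null(partition)) {
    member <- membershipVector(partition, network@drugs)
    igraph::V(g)$cluster <- as.integer(member)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' @rdname writeDDSNGraphML
#' @return \code{readDDSNGraphML}: a [SimilarityNetwork-class].
#' @export
readDDSNGraphML <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  drugs <- igraph::V(g)$name
  if (is.null(drugs)) drugs <- igraph::V(g)$drug_id
  el <- igraph::as_data_frame(g, what = "edges")
  if (nrow(el) == 0L)
    return(newSimilarityNetwork(drugs,
      data.frame(from = character(), to = character(), weight = integer())))
  newSimilarityNetwork(drugs,
    data.frame(from = el$from, to = el$to,
               weight = as.integer(round(el$weight)),
               stringsAsFactors = FALSE))
}

#' Write a similarity-network edge list as TSV
#'
#' @inheritParams writeDDSNGraphML
#' @export
writeEdgeList <- function(network, path) {
  stopifnot(is(network, "SimilarityNetwork"))
  e <- network@edges
  writeTSV(data.frame(drug_a = e$from, drug_b = e$to, weight = e$weight),
           path)
}
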