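#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run. Defaults mirror the
#' analysis conditions: no score filtering, any shared disease creates
#' a similarity edge (\code{min_weight = 1}), clusters below 8 drugs or
#' outside the main connected component are excluded, and the top 3
#' level-4 codes are reported per cluster.
#'
#' @param drug_gene_path,gene_disease_path,drug_atc_path,atc_target_path
#'   paths of the four input TSV tables (\code{atc_target_path} may be
#'   \code{NULL}).
#' @param out_dir output directory for all artifacts.
#' @param evidence_path optional literature-evidence TSV (see
#'   [readEvidenceTable()]).
#' @param dialect a [tableDialect()].
#' @param min_weight minimum projected edge weight.
#' @param min_size minimum retained cluster size.
#' @param require_main_component drop clusters outside the largest
#'   component.
#' @param top_k_level4 number of top level-4 codes per cluster.
#' @param score_threshold optional gene-disease score threshold.
#' @param relation_whitelist optional drug-gene relation-type subset.
#' @param seed integer passed to community detection.
#' @return a list of class \code{"pipelineConfig"}.
#' @export
pipelineConfig <- function(drug_gene_path, gene_disease_path,
                           drug_atc_path, out_dir,
                           atc_target_path = NULL, evidence_path = NULL,
                           dialect = tableDialect(), min_weight = 1L,
                           min_size = 8L, require_main_component = TRUE,
                           top_k_level4 = 3L, score_threshold = NULL,
                           relation_whitelist = NULL, seed = 0L) {
  paths <- c(drug_gene_path, gene_disease_path, drug_atc_path,
             atc_target_path, evidence_path)
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0L)
    stop("input file not found: ", missing[[1L]])
  structure(list(drug_gene_path = drug_gene_path,
                 gene_disease_path = gene_disease_path,
                 drug_atc_path = drug_atc_path,
                 atc_target_path = atc_target_path,
                 evidence_path = evidence_path, out_dir = out_dir,
                 dialect = dialect, min_weight = min_weight,
                 min_size = min_size,
                 require_main_component = require_main_component,
                 top_k_level4 = top_k_level4,
                 score_threshold = score_threshold,
                 relation_whitelist = relation_whitelist, seed = seed),
            class = "pipelineConfig")
}

# run `expr`, aborting with the stage name on error and logging a
# structured record on success
runStage <- function(stage, expr) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
  message(sprintf("[%s] done in %.2fs", stage,
                  proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full repositioning pipeline
#'
#' Ingests the input tables, builds the tripartite graph, projects the
#' drug-drug similarity network, detects and filters communities,
#' labels each surviving cluster by its dominant ATC level-1 code,
#' classifies drugs as db-matched or repositioning candidates, folds in
#' optional literature evidence, builds PubMed queries for the
#' remaining candidates, and writes all artifacts (GraphML + edge list,
#' partition and excluded-cluster tables, per-cluster report, hint
#' table, query log, JSON manifest) under \code{config$out_dir}.
#'
#' @param config a [pipelineConfig()].
#' @return the run manifest (list), invisibly identical to the JSON
#'   written at \code{<out_dir>/manifest.json}: input/output paths,
#'   entity counts, cluster counts pre/post filter and the weighted
#'   accuracy fields.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "pipelineConfig"))
  if (!dir.exists(config$out_dir))
    dir.create(config$out_dir, recursive = TRUE)

  drugGene <- runStage("ingest", readDrugGeneTable(
    config$drug_gene_path, config$dialect,
    relationWhitelist = config$relation_whitelist))
  geneDisease <- runStage("ingest", readGeneDiseaseTable(
    config$gene_disease_path, config$score_threshold, config$dialect))
  annotations <- runStage("ingest", readDrugAtcTable(
    config$drug_atc_path, config$dialect))
  atcTargets <- if (!is.null(config$atc_target_path))
    runStage("ingest", readAtcTargetTable(config$atc_target_path,
                                          config$dialect))
  else list()

  graph <- runStage("tripartite", {
    if (nrow(drugGene) == 0L)
      stop("no drug-gene records; cannot build the tripartite graph")
    buildTripartite(drugGene, geneDisease)
  })
  network <- runStage("projection",
                      projectDDSN(graph, config$min_weight))
  partition <- runStage("communities",
                        hierarchicalCommunities(network,
                                                seed = config$seed))
  nPre <- length(communityList(partition))
  filtered <- runStage("filtering", filterCommunities(
    partition, network, config$min_size, config$require_main_component))

  reports <- runStage("labeling", lapply(
    seq_along(filtered@clusters), function(i)
      clusterReport(i, filtered@clusters[[i]], annotations, atcTargets,
                    config$top_k_level4)))
  hints <- runStage("hints", makeHints(reports))

  confirmed <- data.frame(cluster_number = integer(), n_confirmed = integer())
  if (!is.null(config$evidence_path)) {
    res <- runStage("validation", applyValidation(
      hints, readEvidenceTable(config$evidence_path)))
    hints <- res$hints
    confirmed <- res$confirmed_counts
  }
  queries <- runStage("queries", candidateQueries(hints))

  summary <- runStage("accuracy", {
    rows <- do.call(rbind, lapply(reports, function(r) {
      nc <- confirmed$n_confirmed[confirmed$cluster_number ==
                                    r$cluster_number]
      if (length(nc) == 0L) nc <- 0L
      data.frame(cluster_number = r$cluster_number, size = r$size,
                 label = r$label, pct_predominant = r$pct_predominant,
                 pct_confirmed = roundHalfAway(100 * nc / r$size, 1L))
    }))
    if (is.null(rows) || nrow(rows) == 0L) NULL else accuracySummary(rows)
  })

  out <- function(f) file.path(config$out_dir, f)
  runStage("write", {
    writeDDSNGraphML(network, out("ddsn.graphml"), filtered)
    writeEdgeList(network, out("ddsn_edges.tsv"))
    writePartition(filtered, out("partition.tsv"),
                   out("excluded_clusters.tsv"))
    report_tsv <- if (!is.null(summary)) {
      df <- summary$per_cluster
      df$top_level4 <- vapply(reports, function(r)
        paste(r$top_level4, collapse = ";"), character(1))
      df
    } else data.frame()
    writeTSV(report_tsv, out("cluster_report.tsv"))
    writeTSV(hints, out("hints.tsv"))
    writeTSV(queries, out("query_log.tsv"))
  })

  manifest <- list(
    inputs = list(drug_gene = config$drug_gene_path,
                  gene_disease = config$gene_disease_path,
                  drug_atc = config$drug_atc_path),
    outputs = list(graphml = out("ddsn.graphml"),
                   edge_list = out("ddsn_edges.tsv"),
                   partition = out("partition.tsv"),
                   excluded = out("excluded_clusters.tsv"),
                   cluster_report = out("cluster_report.tsv"),
                   hints = out("hints.tsv"),
                   query_log = out("query_log.tsv")),
    n_drugs = length(drugNames(graph)),
    n_genes = length(geneNames(graph)),
    n_diseases = length(diseaseNames(graph)),
    n_ddsn_edges = nrow(similarityEdges(network)),
    n_clusters_pre_filter = nPre,
    n_clusters_post_filter = length(communityList(filtered)),
    modularity = partitionModularity(partition),
    n_hints = nrow(hints),
    n_candidates = sum(hints$status == "candidate"),
    weighted_pct_predominant =
      if (is.null(summary)) NA else summary$weighted_pct_predominant,
    weighted_pct_confirmed =
      if (is.null(summary)) NA else summary$weighted_pct_confirmed,
    total_accuracy =
      if (is.null(summary)) NA else summary$total_accuracy,
    pct_candidates =
      if (is.null(summary)) NA else summary$pct_candidates)
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
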