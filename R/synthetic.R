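#' Configuration of the planted-structure data generator
#'
#' Describes a synthetic corpus of the four pipeline input tables with
#' known community structure: drug clusters that share cluster-private
#' genes (each gene linked to its own private diseases), a dominant ATC
#' level-1 letter per cluster, and a controlled fraction of
#' "mislabeled" drugs that carry a foreign cluster's ATC profile while
#' keeping their own cluster's gene links -- the planted repositioning
#' candidates.
#'
#' Drug-gene links are Bernoulli: a drug links to each gene of its own
#' cluster with probability \code{p_within} and to each gene of every
#' other cluster with probability \code{p_between}; recoverable
#' structure requires \code{p_between < p_within}.
#'
#' @param n_clusters number of planted drug communities.
#' @param drugs_per_cluster integer, or integer vector of length
#'   \code{n_clusters}.
#' @param genes_per_cluster genes private to each cluster.
#' @param diseases_per_gene diseases private to each gene.
#' @param p_within,p_between Bernoulli link probabilities.
#' @param mislabel_fraction fraction of each cluster's drugs given a
#'   foreign ATC profile (nearest integer count, lexicographically
#'   first drug ids).
#' @param dominant_atc level-1 letters, one per cluster, all distinct.
#' @param level4_weights sampling weights over each cluster's three
#'   level-4 codes.
#' @param seed integer seed; generation is deterministic given the
#'   configuration (Mersenne-Twister RNG).
#' @return a list of class \code{"generatorConfig"}.
#' @export
generatorConfig <- function(n_clusters = 4L, drugs_per_cluster = 12L,
                            genes_per_cluster = 6L, diseases_per_gene = 3L,
                            p_within = 0.7, p_between = 0.02,
                            mislabel_fraction = 0.1,
                            dominant_atc = c("N", "C", "L", "A", "B", "D",
                                             "G", "H", "J", "M")[seq_len(n_clusters)],
                            level4_weights = c(0.5, 0.3, 0.2),
                            seed = 1L) {
  if (n_clusters < 1L) stop("need at least one cluster")
  if (length(drugs_per_cluster) == 1L)
    drugs_per_cluster <- rep(as.integer(drugs_per_cluster), n_clusters)
  if (length(drugs_per_cluster) != n_clusters)
    stop("drugs_per_cluster must have length 1 or n_clusters")
  if (any(drugs_per_cluster < 1L)) stop("empty cluster in configuration")
  if (length(dominant_atc) != n_clusters ||
      anyDuplicated(dominant_atc) ||
      !all(validateATC(dominant_atc) & nchar(dominant_atc) == 1L))
    stop("dominant_atc must be n_clusters distinct level-1 letters")
  probs <- c(p_within, p_between, mislabel_fraction)
  if (any(probs < 0) || any(probs > 1))
    stop("probabilities must lie in [0, 1]")
  if (n_clusters > 1L && p_between >= p_within)
    warning("p_between >= p_within: planted structure is not recoverable")
  structure(list(n_clusters = as.integer(n_clusters),
                 drugs_per_cluster = drugs_per_cluster,
                 genes_per_cluster = as.integer(genes_per_cluster),
                 diseases_per_gene = as.integer(diseases_per_gene),
                 p_within = p_within, p_between = p_between,
                 mislabel_fraction = mislabel_fraction,
                 dominant_atc = toupper(dominant_atc),
                 level4_weights = level4_weights / sum(level4_weights),
                 seed = as.integer(seed)),
            class = "generatorConfig")
}

# three valid level-4 codes under a level-1 letter
clusterLevel4Profile <- function(letter) {
  sprintf("%s0%dA%s", letter, 1:3, c("A", "B", "C"))
}

#' Generate a planted-structure dataset
#'
#' Emits the four pipeline input tables and the planted ground truth.
#' Deterministic given the configuration (the seed is applied with the
#' Mersenne-Twister RNG and the previous RNG state is restored).
#'
#' @param config a [generatorConfig()].
#' @return list with data.frames \code{drug_gene},
#'   \code{gene_disease}, \code{drug_atc}, \code{atc_target} (the TSV
#'   dialects consumed by the readers) and \code{truth}
#'   (drug_id, cluster, is_planted_candidate, atc_code), plus attribute
#'   \code{"profiles"} (per-cluster level-4 codes).
#' @export
generateDataset <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed, kind = "Mersenne-Twister")
  K <- config$n_clusters
  g <- config$genes_per_cluster
  d <- config$diseases_per_gene
  genes <- lapply(seq_len(K), function(i) sprintf("G%02d_%02d", i, seq_len(g)))
  profiles <- lapply(config$dominant_atc, clusterLevel4Profile)

  gene_disease <- do.call(rbind, lapply(seq_len(K), function(i) {
    do.call(rbind, lapply(seq_len(g), function(j) {
      data.frame(gene_symbol = genes[[i]][j],
                 disease_id = sprintf("DIS%02d_%02d_%02d", i, j, seq_len(d)),
                 disease_name = sprintf("Disease %02d-%02d-%02d", i, j,
                                        seq_len(d)),
                 score = 1, stringsAsFactors = FALSE)
    }))
  }))

  drug_gene <- list(); drug_atc <- list(); truth <- list()
  for (i in seq_len(K)) {
    n_i <- config$drugs_per_cluster[i]
    drugs <- sprintf("DRG%02d_%03d", i, seq_len(n_i))
    n_mis <- as.integer(roundHalfAway(config$mislabel_fraction * n_i))
    mislabeled <- sort(drugs)[seq_len(n_mis)]
    for (dr in drugs) {
      for (j in seq_len(K)) {
        p <- if (j == i) config$p_within else config$p_between
        hit <- genes[[j]][stats::runif(g) < p]
        if (length(hit) > 0L)
          drug_gene[[length(drug_gene) + 1L]] <-
            data.frame(drug_id = dr, drug_name = paste0("Drug ", dr),
                       gene_symbol = hit, relation_type = "target",
                       stringsAsFactors = FALSE)
      }
      src <- if (dr %in% mislabeled && K > 1L) (i %% K) + 1L else i
      code <- sample(profiles[[src]], 1L, prob = config$level4_weights)
      drug_atc[[length(drug_atc) + 1L]] <-
        data.frame(drug_id = dr, atc_code = code, stringsAsFactors = FALSE)
      truth[[length(truth) + 1L]] <-
        data.frame(drug_id = dr, cluster = i,
                   is_planted_candidate = dr %in% mislabeled,
                   atc_code = code, stringsAsFactors = FALSE)
    }
  }
  atc_target <- do.call(rbind, lapply(unlist(profiles), function(code)
    data.frame(atc_code = code,
               target_name = sprintf("T_%s_%d", code, 1:2),
               stringsAsFactors = FALSE)))
  out <- list(drug_gene = do.call(rbind, drug_gene),
              gene_disease = gene_disease,
              drug_atc = do.call(rbind, drug_atc),
              atc_target = atc_target,
              truth = do.call(rbind, truth))
  out <- lapply(out, function(x) { rownames(x) <- NULL; x })
  attr(out, "profiles") <- profiles
  attr(out, "dominant_atc") <- config$dominant_atc
  out
}

#' Write a generated dataset as TSV files
#'
#' @param dataset result of [generateDataset()].
#' @param dir output directory (created if needed).
#' @return named character vector of the five file paths.
#' @export
writeDataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(drug_gene = file.path(dir, "drug_gene.tsv"),
             gene_disease = file.path(dir, "gene_disease.tsv"),
             drug_atc = file.path(dir, "drug_atc.tsv"),
             atc_target = file.path(dir, "atc_target.tsv"),
             truth = file.path(dir, "planted_truth.tsv"))
  for (nm in names(paths)) writeTSV(dataset[[nm]], paths[[nm]])
  paths
}

#' Expected projected edge weights under the generator
#'
#' Closed-form expectations of the similarity-network edge weight for a
#' same-cluster and a different-cluster drug pair under the Bernoulli
#' link scheme: each gene shared by both drugs contributes its
#' \code{diseases_per_gene} private diseases, so the expected weight is
#' \code{diseases_per_gene} times the expected number of co-linked
#' genes.
#'
#' @param config a [generatorConfig()].
#' @return named numeric vector \code{c(within = ..., between = ...)};
#'   \code{between} is \code{NA} for a single-cluster configuration.
#' @export
expectedWeightBounds <- function(config) {
  stopifnot(inherits(config, "generatorConfig"))
  K <- config$n_clusters
  g <- config$genes_per_cluster
  d <- config$diseases_per_gene
  pw <- config$p_within
  pb <- config$p_between
  within <- d * g * (pw^2 + (K - 1L) * pb^2)
  between <- if (K >= 2L) d * g * (2 * pw * pb + (K - 2L) * pb^2) else NA_real_
  c(within = within, between = between)
}
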