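# EggNOG-derived annotation of genes and taxonomic-range contamination
# scoring. The predicted taxonomic range of a gene's protein cluster is
# compared against two configurable taxon lists: ranges that cannot contain
# the family of interest indicate contamination (score 1), ranges consistent
# with it score 0, and missing or uninformative ranges score 0.5.

#' Taxon-list configuration for contamination scoring
#'
#' The default lists encode the Lachnospiraceae study configuration:
#' taxonomic ranges that exclude Lachnospiraceae score 1
#' (contamination-indicating), ranges that can contain Lachnospiraceae
#' score 0 (consistent). The mechanism is family-of-interest dependent and
#' fully configurable; a YAML/JSON file with fields `contamination` and
#' `consistent` can be supplied instead.
#'
#' @param contamination character vector of contamination-indicating groups.
#' @param consistent character vector of consistent groups.
#' @return A `score_config` list.
#' @export
score_config <- function(
    contamination = c("Paenibacillaceae", "Pasteurellales", "Negativicutes",
                      "Desulfovibrionales", "Erysipelotrichia", "Oscillospiraceae"),
    consistent = c("Clostridia", "Clostridiales", "Clostridiaceae",
                   "Ruminococcaceae", "Eubacteriaceae", "Lachnospiraceae",
                   "Lachnospira", "Blautia", "Butyrivibrio", "Oribacterium",
                   "unclassified Lachnospiraceae", "unclassified Clostridiales")) {
  structure(list(contamination = contamination, consistent = consistent),
            class = "score_config")
}

#' Read a score configuration from YAML or JSON
#' @param path file with fields `contamination` and `consistent`.
#' @return A [score_config()].
#' @export
read_score_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("YAML score configs need the 'yaml' package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  score_config(contamination = cfg$contamination, consistent = cfg$consistent)
}

#' Contamination score of predicted taxonomic ranges
#'
#' Scores each predicted taxonomic group 1 (contamination-indicating),
#' 0 (consistent with the family of interest), or 0.5 (missing, `"Bacteria"`,
#' or an unlisted group — the latter with a warning, since EggNOG emits an
#' open vocabulary).
#'
#' @param predicted_tax_group character vector (NA allowed).
#' @param config a [score_config()].
#' @return Numeric vector with values in \{0, 0.5, 1\}.
#' @export
eggnog_contamination_score <- function(predicted_tax_group,
                                       config = score_config()) {
  g <- as.character(predicted_tax_group)
  out <- rep(0.5, length(g))
  known <- !is.na(g) & g != "Bacteria"
  out[known & g %in% config$contamination] <- 1
  out[known & g %in% config$consistent] <- 0
  unknown <- unique(g[known & !(g %in% c(config$contamination, config$consistent))])
  if (length(unknown) > 0) {
    warning("unlisted taxonomic group(s) scored 0.5: ",
            paste(unknown, collapse = ", "))
  }
  out
}

#' Annotate genes with their protein-cluster metadata
#'
#' Resolves each gene to its UHGP-90-style cluster and that cluster's EggNOG
#' annotation. Unresolvable fields are `NA`; unknown genes never error.
#'
#' @param gene_id character vector of gene ids.
#' @param map an [annotation_map()].
#' @return Data frame `gene_id`, `cluster_id`, `predicted_tax_group`,
#'   `protein_name`, `description`.
#' @export
annotate_genes <- function(gene_id, map) {
  cl <- gene_cluster(map, gene_id)
  info <- cluster_info(map, cl)
  data.frame(gene_id = gene_id, cluster_id = cl,
             predicted_tax_group = info$predicted_tax_group,
             protein_name = info$protein_name,
             description = info$description,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate genes and attach contamination scores
#'
#' @inheritParams annotate_genes
#' @param config a [score_config()] for [eggnog_contamination_score()].
#' @return The [annotate_genes()] frame plus a `contamination_score` column.
#' @export
annotate_and_score <- function(gene_id, map, config = score_config()) {
  out <- annotate_genes(gene_id, map)
  out$contamination_score <- eggnog_contamination_score(out$predicted_tax_group, config)
  out
}
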