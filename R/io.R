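# Readers and writers for the TSV dialects used throughout: UTF-8,
# tab-separated, header row; matrices carry row ids in the first column.

read_tsv_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = NA)
  if (ncol(df) < 2) stop("malformed matrix file (need id column + >=1 sample): ", path)
  ids <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2, as.numeric))),
                 arr.ind = TRUE)
    if (length(bad) > 0) {
      stop(sprintf("non-numeric cell at row '%s', column '%s' in %s",
                   ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]], path))
    }
    stop("non-numeric matrix in ", path)
  }
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

write_tsv_matrix <- function(m, path, id_col) {
  df <- data.frame(rownames(m), m, check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a gene quantification matrix from TSV
#'
#' @param path TSV file: header row of sample ids, first column gene ids.
#' @param kind declared quantification kind (`"presence"`, `"reads"`,
#'   `"copynum"`); cells are validated against it.
#' @param species_id species the genes belong to.
#' @return A [gene_matrix()].
#' @export
read_gene_matrix <- function(path, kind = c("presence", "reads", "copynum"),
                             species_id = "species") {
  kind <- match.arg(kind)
  gene_matrix(read_tsv_matrix(path), kind = kind, species_id = species_id)
}

#' Write a gene matrix to TSV
#' @param gm a [gene_matrix()].
#' @param path output file.
#' @export
write_gene_matrix <- function(gm, path) {
  write_tsv_matrix(gm$values, path, "gene_id")
  invisible(path)
}

#' Read a species abundance profile and lineage table
#'
#' @param abundance_path TSV, species x samples relative abundances.
#' @param lineage_path TSV with columns `species_id` and `lineage`
#'   (semicolon-delimited GTDB-style string), or `species_id` plus the seven
#'   rank columns.
#' @return A [species_profile()].
#' @export
read_species_profile <- function(abundance_path, lineage_path) {
  ab <- read_tsv_matrix(abundance_path)
  lin <- utils::read.delim(lineage_path, check.names = FALSE,
                           stringsAsFactors = FALSE, na.strings = c("NA", ""))
  if (!"species_id" %in% names(lin)) names(lin)[1] <- "species_id"
  if (all(GTDB_RANKS %in% names(lin))) {
    ranks <- lin[, GTDB_RANKS, drop = FALSE]
  } else if ("lineage" %in% names(lin) || ncol(lin) >= 2) {
    str_col <- if ("lineage" %in% names(lin)) "lineage" else names(lin)[2]
    ranks <- as.data.frame(parse_lineage(as.character(lin[[str_col]])),
                           stringsAsFactors = FALSE)
  } else {
    stop("lineage table must have a lineage string column or seven rank columns: ",
         lineage_path)
  }
  species_profile(ab, cbind(species_id = as.character(lin$species_id), ranks))
}

#' Write a species profile (abundance + lineage) to TSV
#' @param profile a [species_profile()].
#' @param abundance_path,lineage_path output files.
#' @export
write_species_profile <- function(profile, abundance_path, lineage_path) {
  write_tsv_matrix(profile$abundance, abundance_path, "species_id")
  lin <- profile$lineage
  str <- apply(lin[, GTDB_RANKS, drop = FALSE], 1, function(r) {
    paste0(GTDB_PREFIXES, ifelse(is.na(r), "", r), collapse = ";")
  })
  utils::write.table(data.frame(species_id = lin$species_id, lineage = str),
                     lineage_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(abundance_path, lineage_path))
}

#' Read a sample metadata table from TSV
#' @param path TSV with columns `sample_id`, `subject_id`, `group`.
#' @return A [sample_table()].
#' @export
read_sample_table <- function(path) {
  sample_table(utils::read.delim(path, stringsAsFactors = FALSE))
}

read_table_any <- function(path) {
  if (grepl("\\.parquet$", path, ignore.case = TRUE)) {
    if (!requireNamespace("arrow", quietly = TRUE)) {
      stop("reading Parquet requires the 'arrow' package; supply TSV instead: ", path)
    }
    as.data.frame(arrow::read_parquet(path))
  } else {
    utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                      na.strings = c("NA", ""))
  }
}

#' Read gene-to-cluster and cluster-annotation maps
#'
#' Accepts TSV or Parquet (by file extension; Parquet needs the optional
#' `arrow` package).
#'
#' @param gene_cluster_path two-column file `gene_id`, `cluster_id`.
#' @param cluster_annot_path file keyed by `cluster_id` with annotation
#'   columns (`predicted_tax_group`, `protein_name`, `description`).
#' @return An [annotation_map()].
#' @export
read_annotation_map <- function(gene_cluster_path, cluster_annot_path) {
  g2c <- read_table_any(gene_cluster_path)
  if (!all(c("gene_id", "cluster_id") %in% names(g2c))) {
    names(g2c)[1:2] <- c("gene_id", "cluster_id")
  }
  annotation_map(g2c, read_table_any(cluster_annot_path))
}

#' Write an annotation map to two TSV files
#' @param map an [annotation_map()].
#' @param gene_cluster_path,cluster_annot_path output files.
#' @export
write_annotation_map <- function(map, gene_cluster_path, cluster_annot_path) {
  utils::write.table(data.frame(gene_id = names(map$gene_to_cluster),
                                cluster_id = unname(map$gene_to_cluster)),
                     gene_cluster_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(map$cluster_annotation, cluster_annot_path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(c(gene_cluster_path, cluster_annot_path))
}
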