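#' @keywords internal
"_PACKAGE"

GTDB_RANKS <- c("domain", "phylum", "class", "order", "family", "genus", "species")
GTDB_PREFIXES <- c(domain = "d__", phylum = "p__", class = "c__", order = "o__",
                   family = "f__", genus = "g__", species = "s__")

#' Sample metadata table
#'
#' Validates a data frame of sample metadata into a `sample_table`. Each row is
#' one sequenced sample; several samples may belong to the same subject, and
#' each subject is labelled either `"case"` or `"control"`.
#'
#' @param x data frame with columns `sample_id`, `subject_id`, `group`.
#' @return A `sample_table` (data frame subclass).
#' @export
sample_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("sample_id", "subject_id", "group")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    stop("sample table is missing column(s): ", paste(miss, collapse = ", "))
  }
  x$sample_id <- as.character(x$sample_id)
  x$subject_id <- as.character(x$subject_id)
  x$group <- as.character(x$group)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id in sample table: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "))
  }
  bad <- setdiff(unique(x$group), c("case", "control"))
  if (length(bad) > 0) {
    stop("group labels must be 'case' or 'control'; found: ",
         paste(bad, collapse = ", "))
  }
  class(x) <- c("sample_table", "data.frame")
  x
}

#' Gene quantification matrix
#'
#' A genes-by-samples matrix of one quantification kind for a single pangenome
#' species: presence/absence calls (0/1), mapped read counts (non-negative
#' integers), or estimated copy numbers (non-negative reals).
#'
#' @param values numeric matrix, rows named by gene id, columns by sample id.
#' @param kind one of `"presence"`, `"reads"`, `"copynum"`.
#' @param species_id id of the pangenome species the genes belong to.
#' @return A `gene_matrix` object.
#' @export
gene_matrix <- function(values, kind = c("presence", "reads", "copynum"),
                        species_id = "species") {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("gene matrix must have gene ids as row names and sample ids as column names")
  }
  if (anyDuplicated(rownames(values))) stop("duplicate gene_ids in gene matrix")
  if (anyDuplicated(colnames(values))) stop("duplicate sample_ids in gene matrix")
  check_gene_values(values, kind)
  structure(list(species_id = as.character(species_id), kind = kind,
                 values = values),
            class = "gene_matrix")
}

check_gene_values <- function(values, kind) {
  if (!is.numeric(values)) stop("gene matrix values must be numeric")
  if (any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    stop(sprintf("non-finite value at gene '%s', sample '%s'",
                 rownames(values)[bad[1]], colnames(values)[bad[2]]))
  }
  bad <- switch(kind,
    presence = which(!(values %in% c(0, 1)), arr.ind = FALSE),
    reads = which(values < 0 | values != floor(values)),
    copynum = which(values < 0))
  if (length(bad) > 0) {
    i <- arrayInd(bad[1], dim(values))
    stop(sprintf(
      "value %g at gene '%s', sample '%s' violates kind '%s' (%s)",
      values[bad[1]], rownames(values)[i[1]], colnames(values)[i[2]], kind,
      switch(kind, presence = "must be 0 or 1",
             reads = "must be a non-negative integer",
             copynum = "must be a non-negative real")))
  }
  invisible(values)
}

#' @export
print.gene_matrix <- function(x, ...) {
  cat(sprintf("<gene_matrix> %s: %d genes x %d samples (kind = %s)\n",
              x$species_id, nrow(x$values), ncol(x$values), x$kind))
  invisible(x)
}

#' Parse a GTDB-style lineage string
#'
#' Splits a semicolon-delimited lineage such as
#' `"d__Bacteria;p__Firmicutes_A;...;f__Lachnospiraceae;g__;s__"` into the
#' seven standard ranks, stripping `d__`/`p__`/... prefixes. Empty ranks
#' become `NA`. Plain 7-field strings without prefixes are also accepted.
#'
#' @param x character vector of lineage strings.
#' @return Character matrix with one row per input and columns
#'   `domain` ... `species`.
#' @export
parse_lineage <- function(x) {
  out <- matrix(NA_character_, nrow = length(x), ncol = length(GTDB_RANKS),
                dimnames = list(NULL, GTDB_RANKS))
  for (i in seq_along(x)) {
    parts <- trimws(strsplit(x[[i]], ";", fixed = TRUE)[[1]])
    for (p in parts) {
      hit <- which(startsWith(p, GTDB_PREFIXES))
      if (length(hit) == 1) {
        val <- substring(p, 4)
        out[i, hit] <- if (nzchar(val)) val else NA_character_
      }
    }
    if (all(is.na(out[i, ])) && length(parts) == length(GTDB_RANKS)) {
      # plain 7-column dialect, positional
      out[i, ] <- ifelse(nzchar(parts), parts, NA_character_)
    }
  }
  out
}

#' Species relative-abundance profile
#'
#' Species-by-samples relative abundances together with a lineage per species.
#'
#' @param abundance numeric matrix (species x samples), non-negative, rows
#'   named by species id.
#' @param lineage data frame with column `species_id` plus the seven rank
#'   columns `domain` ... `species` (as produced by [parse_lineage()]).
#' @return A `species_profile` object.
#' @export
species_profile <- function(abundance, lineage) {
  abundance <- as.matrix(abundance)
  if (is.null(rownames(abundance)) || is.null(colnames(abundance))) {
    stop("abundance matrix must have species ids as row names and sample ids as column names")
  }
  if (anyDuplicated(rownames(abundance))) stop("duplicate species_ids in abundance matrix")
  if (!is.numeric(abundance) || any(!is.finite(abundance)) || any(abundance < 0)) {
    stop("abundances must be finite and non-negative")
  }
  lineage <- as.data.frame(lineage, stringsAsFactors = FALSE)
  need <- c("species_id", GTDB_RANKS)
  miss <- setdiff(need, names(lineage))
  if (length(miss) > 0) stop("lineage table missing column(s): ", paste(miss, collapse = ", "))
  absent <- setdiff(rownames(abundance), lineage$species_id)
  if (length(absent) > 0) {
    stop("species missing from lineage table: ", paste(absent, collapse = ", "))
  }
  rownames(lineage) <- lineage$species_id
  structure(list(abundance = abundance,
                 lineage = lineage[rownames(abundance), , drop = FALSE]),
            class = "species_profile")
}

#' @export
print.species_profile <- function(x, ...) {
  cat(sprintf("<species_profile> %d species x %d samples\n",
              nrow(x$abundance), ncol(x$abundance)))
  invisible(x)
}

#' Look up a lineage rank for species in a profile
#'
#' @param profile a [species_profile()].
#' @param species_id character vector of species ids.
#' @param rank one of the seven GTDB ranks, e.g. `"family"`.
#' @return Character vector; `NA` where the rank is unrecorded or the species
#'   is unknown.
#' @export
lineage_rank <- function(profile, species_id, rank = "family") {
  rank <- match.arg(rank, GTDB_RANKS)
  out <- rep(NA_character_, length(species_id))
  hit <- match(species_id, profile$lineage$species_id)
  out[!is.na(hit)] <- profile$lineage[[rank]][hit[!is.na(hit)]]
  out
}

#' Gene-to-cluster and cluster-annotation lookup map
#'
#' Maps gene ids to UHGP-90-style protein cluster ids and clusters to their
#' EggNOG-derived annotation (predicted taxonomic group, protein name, free
#' text description). Lookups on unknown keys return `NA`, never an error.
#'
#' @param gene_to_cluster data frame with columns `gene_id`, `cluster_id`.
#' @param cluster_annotation data frame with columns `cluster_id`,
#'   `predicted_tax_group`, `protein_name`, `description` (annotation fields
#'   may be `NA`).
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(gene_to_cluster, cluster_annotation) {
  g2c <- as.data.frame(gene_to_cluster, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "cluster_id") %in% names(g2c))) {
    stop("gene_to_cluster needs columns gene_id, cluster_id")
  }
  g2c <- unique(g2c[, c("gene_id", "cluster_id")])
  dup <- g2c$gene_id[duplicated(g2c$gene_id)]
  if (length(dup) > 0) {
    stop("gene(s) mapped to conflicting clusters: ", paste(unique(dup), collapse = ", "))
  }
  ann <- as.data.frame(cluster_annotation, stringsAsFactors = FALSE)
  if (!"cluster_id" %in% names(ann)) stop("cluster_annotation needs a cluster_id column")
  for (f in c("predicted_tax_group", "protein_name", "description")) {
    if (!f %in% names(ann)) ann[[f]] <- NA_character_
    ann[[f]][!is.na(ann[[f]]) & !nzchar(ann[[f]])] <- NA_character_
  }
  ann <- ann[!duplicated(ann$cluster_id), c("cluster_id", "predicted_tax_group",
                                            "protein_name", "description")]
  lookup <- g2c$cluster_id
  names(lookup) <- g2c$gene_id
  rownames(ann) <- ann$cluster_id
  structure(list(gene_to_cluster = lookup, cluster_annotation = ann),
            class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map> %d genes -> %d annotated clusters\n",
              length(x$gene_to_cluster), nrow(x$cluster_annotation)))
  invisible(x)
}

#' Cluster id for genes
#' @param map an [annotation_map()].
#' @param gene_id character vector.
#' @return Character vector of cluster ids (`NA` when unmapped).
#' @export
gene_cluster <- function(map, gene_id) {
  unname(map$gene_to_cluster[gene_id])
}

#' Annotation record for clusters
#' @param map an [annotation_map()].
#' @param cluster_id character vector.
#' @return Data frame with one row per queried cluster (`NA` fields when
#'   unknown).
#' @export
cluster_info <- function(map, cluster_id) {
  idx <- match(cluster_id, map$cluster_annotation$cluster_id)
  out <- map$cluster_annotation[idx, , drop = FALSE]
  out$cluster_id <- cluster_id
  rownames(out) <- NULL
  out
}

# samples shared between a gene matrix and any other sample-id carrier;
# alignment is by intersection because upstream quantifiers emit gene
# matrices only for samples where the species passed coverage
shared_samples <- function(gm, sample_ids) {
  intersect(colnames(gm$values), sample_ids)
}
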