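# The correlation-lineage rank test: correlate a gene's read counts with
# every species' relative abundance (Spearman), rank species by correlation,
# and report the best rank at which a species' lineage matches the gene's
# home pangenome. Contaminant genes track their true source taxon, so their
# lineage match occurs far down the ranking.

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks. Returns `NA` when either vector is
#' constant (correlation undefined).
#'
#' @param x,y numeric vectors of equal length >= 3; ties allowed.
#' @return rho in \[-1, 1\], or `NA`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) return(NA_real_)
  stats::cor(x, y, method = "spearman")
}

#' Rank all species by correlation with a gene's counts
#'
#' Computes Spearman's rho between the gene's read counts and every species'
#' relative abundance over the shared samples, then ranks species by
#' descending rho (rank 1 = most correlated). Ties are broken by ascending
#' species id; species with undefined rho are placed last, in species-id
#' order.
#'
#' @param gene_counts named numeric vector of read counts (names = sample ids).
#' @param profile a [species_profile()].
#' @return Data frame `species_id`, `rho`, `rank`, ordered by rank, with the
#'   number of shared samples in attribute `n_samples`.
#' @export
rank_species_correlations <- function(gene_counts, profile) {
  shared <- intersect(names(gene_counts), colnames(profile$abundance))
  if (length(shared) < 3) {
    stop(sprintf("only %d samples shared between gene counts and species profile (need >= 3)",
                 length(shared)))
  }
  g <- gene_counts[shared]
  rho <- apply(profile$abundance[, shared, drop = FALSE], 1, function(ab) {
    if (length(unique(g)) < 2 || length(unique(ab)) < 2) NA_real_
    else stats::cor(g, ab, method = "spearman")
  })
  ord <- order(is.na(rho), -ifelse(is.na(rho), -Inf, rho), names(rho))
  out <- data.frame(species_id = names(rho)[ord], rho = unname(rho[ord]),
                    rank = seq_along(rho), stringsAsFactors = FALSE)
  attr(out, "n_samples") <- length(shared)
  out
}

#' Best rank at which a species lineage matches the home lineage
#'
#' @param ranked output of [rank_species_correlations()].
#' @param home_lineage named character vector (or one-row data frame) with the
#'   home pangenome's ranks, e.g. element `family` = `"Lachnospiraceae"`.
#' @param profile the [species_profile()] supplying each ranked species'
#'   lineage.
#' @param level `"family"` or `"species"`: the rank at which lineages are
#'   compared (exact, case-sensitive string equality; missing lineages never
#'   match).
#' @return 1-based rank of the first match, or `NA` if no ranked species
#'   matches.
#' @export
lineage_match_rank <- function(ranked, home_lineage, profile,
                               level = c("family", "species")) {
  level <- match.arg(level)
  home <- if (is.data.frame(home_lineage)) home_lineage[[level]][1] else home_lineage[[level]]
  if (is.null(home) || is.na(home)) {
    stop("home lineage has no '", level, "' rank")
  }
  lin <- lineage_rank(profile, ranked$species_id, level)
  hit <- which(!is.na(lin) & lin == home)
  if (length(hit) == 0) NA_integer_ else ranked$rank[hit[1]]
}

#' Run the correlation-lineage test for a batch of genes
#'
#' For each gene, ranks all species by Spearman correlation with the gene's
#' read counts and reports the best rank at which the correlated species'
#' lineage matches the gene's home pangenome, at both the family and the
#' species level. Per-gene failures (too few shared samples, constant
#' counts) are returned as flagged rows rather than aborting the batch.
#'
#' @param sig_genes character vector of gene ids to test.
#' @param reads a reads-kind [gene_matrix()].
#' @param profile a [species_profile()] including the home species.
#' @param home_species single species id for all genes, or a named vector
#'   mapping gene id to home species id. Defaults to the matrix's species.
#' @return A `lineage_test` data frame, one row per gene in input order:
#'   `gene_id`, `home_species`, `top_species`, `top_rho`,
#'   `family_match_rank`, `species_match_rank`, `n_samples_used`, `ok`,
#'   `note`. The full per-gene rankings are kept in attribute `rankings`.
#' @export
run_lineage_test <- function(sig_genes, reads, profile, home_species = NULL) {
  stopifnot(inherits(reads, "gene_matrix"), inherits(profile, "species_profile"))
  if (reads$kind != "reads") stop("run_lineage_test needs a reads matrix")
  if (is.null(home_species)) home_species <- reads$species_id
  home_for <- function(g) {
    if (length(home_species) == 1 && is.null(names(home_species))) home_species
    else if (g %in% names(home_species)) home_species[[g]]
    else stop("no home species given for gene ", g)
  }
  rankings <- vector("list", length(sig_genes))
  names(rankings) <- sig_genes
  rows <- lapply(sig_genes, function(g) {
    base <- data.frame(gene_id = g, home_species = NA_character_,
                       top_species = NA_character_, top_rho = NA_real_,
                       family_match_rank = NA_integer_,
                       species_match_rank = NA_integer_,
                       n_samples_used = NA_integer_, ok = FALSE,
                       note = NA_character_, stringsAsFactors = FALSE)
    hs <- tryCatch(home_for(g), error = function(e) NA_character_)
    base$home_species <- hs
    res <- tryCatch({
      if (!g %in% rownames(reads$values)) stop("gene not in reads matrix")
      if (is.na(hs) || !hs %in% profile$lineage$species_id) {
        stop("home species has no lineage entry")
      }
      counts <- reads$values[g, ]
      ranked <- rank_species_correlations(counts, profile)
      if (all(is.na(ranked$rho))) stop("gene counts constant across shared samples")
      home_lin <- profile$lineage[hs, ]
      base$top_species <- ranked$species_id[1]
      base$top_rho <- ranked$rho[1]
      base$family_match_rank <- lineage_match_rank(ranked, home_lin, profile, "family")
      base$species_match_rank <- lineage_match_rank(ranked, home_lin, profile, "species")
      base$n_samples_used <- attr(ranked, "n_samples")
      base$ok <- TRUE
      rankings[[g]] <<- ranked
      base
    }, error = function(e) {
      base$note <- conditionMessage(e)
      base
    })
    res
  })
  out <- do.call(rbind, rows)
  class(out) <- c("lineage_test", "data.frame")
  attr(out, "rankings") <- rankings
  attr(out, "n_species") <- nrow(profile$abundance)
  out
}

#' @export
print.lineage_test <- function(x, ...) {
  if (!is.null(x$ok)) {
    cat(sprintf("<lineage_test> %d genes (%d ok); family-level match at rank 1 for %d\n",
                nrow(x), sum(x$ok),
                sum(x$family_match_rank[x$ok] == 1, na.rm = TRUE)))
  }
  NextMethod()
}
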