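# End-to-end workflow: differential prevalence -> correlation-lineage test
# -> annotation scoring -> per-species co-occurrence, joined into one
# machine-readable report (with optional copy-number cluster association).

#' Assemble a run configuration
#'
#' @param bundle_dir directory in [write_bundle()] layout; alternatively pass
#'   in-memory objects via `data` (a list with `presence`, `reads`,
#'   `profile`, `samples`, `annotation`).
#' @param data optional in-memory inputs (overrides `bundle_dir`).
#' @param alpha FDR significance cutoff for the prevalence screen.
#' @param per_subject collapse replicate samples per subject before testing.
#' @param methods ordination methods for the co-occurrence stage.
#' @param score_cfg a [score_config()] (or path to one).
#' @param eigengene optional list enabling the copy-number stage:
#'   `list(pattern =, extra_genes =, k_min =, k_max =, B =)`.
#' @param seed integer seed for all seeded stages.
#' @param out_dir output directory (`NULL` for in-memory only).
#' @return A `run_config` list.
#' @export
run_config <- function(bundle_dir = NULL, data = NULL, alpha = 0.05,
                       per_subject = FALSE,
                       methods = c("NMDS", "UMAP", "PCoA"),
                       score_cfg = score_config(), eigengene = NULL,
                       seed = 1, out_dir = NULL) {
  if (is.character(score_cfg)) score_cfg <- read_score_config(score_cfg)
  structure(list(bundle_dir = bundle_dir, data = data, alpha = alpha,
                 per_subject = per_subject, methods = methods,
                 score_cfg = score_cfg, eigengene = eigengene, seed = seed,
                 out_dir = out_dir), class = "run_config")
}

#' Read a run configuration from JSON or YAML
#' @param path config file whose fields mirror the [run_config()] arguments
#'   (`score_cfg` may be a nested object with `contamination`/`consistent`).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE)) stop("YAML configs need the 'yaml' package")
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  sc <- if (is.list(cfg$score_cfg)) {
    score_config(contamination = cfg$score_cfg$contamination,
                 consistent = cfg$score_cfg$consistent)
  } else {
    score_config()
  }
  run_config(bundle_dir = cfg$bundle_dir, alpha = cfg$alpha %||% 0.05,
             per_subject = isTRUE(cfg$per_subject),
             methods = cfg$methods %||% c("NMDS", "UMAP", "PCoA"),
             score_cfg = sc, eigengene = cfg$eigengene,
             seed = cfg$seed %||% 1, out_dir = cfg$out_dir)
}

config_hash <- function(config) {
  stripped <- config[setdiff(names(config), c("data", "out_dir"))]
  tf <- tempfile(); on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(stripped, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tf)
  unname(tools::md5sum(tf))
}

#' Run the full contamination-screening workflow
#'
#' Stages, in order: differential prevalence; correlation-lineage test on the
#' significant genes; annotation scoring; Jaccard co-occurrence and
#' ordination (skipped, with a log record, when fewer than 3 genes are
#' significant); optional copy-number cluster association. Stage failures
#' abort with the stage name; an empty significant set yields a zero-row
#' report. Reruns with identical config and inputs are deterministic.
#'
#' @param config a [run_config()].
#' @return A `run_report`: joined per-gene `table`, stage results
#'   (`prevalence`, `lineage`, `annotation`, `cooccur`, `eigengene`), `log`,
#'   and `metadata` (seed, alpha, config hash, package version, output
#'   files).
#' @export
run_all <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  inputs <- stage("load", {
    if (!is.null(config$data)) config$data
    else if (!is.null(config$bundle_dir)) read_bundle(config$bundle_dir)
    else stop("config needs either 'data' or 'bundle_dir'")
  })
  note("inputs: ", nrow(inputs$presence$values), " genes, ",
       ncol(inputs$presence$values), " samples, ",
       nrow(inputs$profile$abundance), " species")

  prev <- stage("prevalence",
                differential_prevalence(inputs$presence, inputs$samples,
                                        alpha = config$alpha,
                                        per_subject = config$per_subject))
  sig <- prev$gene_id[prev$significant]
  note("prevalence: ", length(sig), " of ", nrow(prev),
       " genes significant at q <= ", config$alpha)

  if (length(sig) == 0) {
    tab <- empty_report_table()
    lin <- NULL; ann <- NULL; cooc <- NULL
    note("no significant genes; lineage test and co-occurrence skipped")
  } else {
    lin <- stage("lineage_test",
                 run_lineage_test(sig, inputs$reads, inputs$profile))
    ann <- stage("annotate",
                 annotate_and_score(sig, inputs$annotation, config$score_cfg))
    cooc <- if (length(sig) >= 3) {
      stage("cooccurrence",
            cooccurrence(inputs$presence, sig, methods = config$methods,
                         seed = config$seed))
    } else {
      note("species '", inputs$presence$species_id, "' has ", length(sig),
           " significant gene(s) (< 3); co-occurrence skipped")
      NULL
    }
    species_name <- lineage_rank(inputs$profile,
                                 rep(inputs$presence$species_id, length(sig)),
                                 "species")
    tab <- data.frame(
      gene_id = sig,
      species_id = inputs$presence$species_id,
      species_name = species_name,
      lineage_match = lin$family_match_rank == 1,
      family_match_rank = lin$family_match_rank,
      species_match_rank = lin$species_match_rank,
      top_species = lin$top_species,
      top_rho = lin$top_rho,
      n_samples_used = lin$n_samples_used,
      fdr = prev$q_value[match(sig, prev$gene_id)],
      case_pct = prev$case_pct[match(sig, prev$gene_id)],
      control_pct = prev$control_pct[match(sig, prev$gene_id)],
      cluster_id = ann$cluster_id,
      predicted_tax_group = ann$predicted_tax_group,
      protein_name = ann$protein_name,
      contamination_score = ann$contamination_score,
      stringsAsFactors = FALSE)
  }

  eig <- if (!is.null(config$eigengene) && !is.null(inputs$copynum)) {
    e <- config$eigengene
    stage("eigengene",
          run_cluster_association(inputs$copynum, inputs$annotation,
                                  inputs$samples,
                                  pattern = e$pattern %||% "flag",
                                  extra_genes = e$extra_genes %||% character(),
                                  k_min = e$k_min %||% 2, k_max = e$k_max %||% 25,
                                  B = e$B %||% 500, seed = config$seed))
  } else {
    NULL
  }

  meta <- list(seed = config$seed, alpha = config$alpha,
               config_hash = config_hash(config),
               package_version = as.character(utils::packageVersion("panscreen")),
               n_significant = length(sig))
  report <- structure(list(table = tab, prevalence = prev, lineage = lin,
                           annotation = ann, cooccur = cooc, eigengene = eig,
                           log = log_lines, metadata = meta),
                      class = "run_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

empty_report_table <- function() {
  data.frame(gene_id = character(0), species_id = character(0),
             species_name = character(0), lineage_match = logical(0),
             family_match_rank = integer(0), species_match_rank = integer(0),
             top_species = character(0), top_rho = numeric(0),
             n_samples_used = integer(0), fdr = numeric(0),
             case_pct = numeric(0), control_pct = numeric(0),
             cluster_id = character(0), predicted_tax_group = character(0),
             protein_name = character(0), contamination_score = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write a run report to disk
#'
#' Writes `report.tsv`, `report.json`, `log.txt`, a `cooccur/` directory
#' (similarity matrix, per-method coordinates, stress summary) and an
#' `eigengene/` directory (assignments, silhouette profile, eigengenes,
#' cluster tests, bootstrap t) when those stages ran.
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return The directory, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$table, file.path(dir, "report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  jsonlite::write_json(list(metadata = report$metadata, genes = report$table),
                       file.path(dir, "report.json"), auto_unbox = TRUE,
                       digits = NA, na = "null", pretty = TRUE)
  writeLines(report$log, file.path(dir, "log.txt"))
  if (!is.null(report$cooccur)) {
    cd <- file.path(dir, "cooccur")
    dir.create(cd, showWarnings = FALSE)
    write_tsv_matrix(report$cooccur$jaccard, file.path(cd, "jaccard_similarity.tsv"),
                     "gene_id")
    for (m in names(report$cooccur$embeddings)) {
      emb <- report$cooccur$embeddings[[m]]
      write_tsv_matrix(emb$coords, file.path(cd, paste0("coords_", m, ".tsv")),
                       "gene_id")
    }
    jsonlite::write_json(
      list(leaf_order = report$cooccur$leaf_order,
           stress = lapply(report$cooccur$embeddings, function(e) e$stress),
           params = lapply(report$cooccur$embeddings, function(e) e$params)),
      file.path(cd, "summary.json"), auto_unbox = TRUE, digits = NA, na = "null")
  }
  if (!is.null(report$eigengene)) {
    ed <- file.path(dir, "eigengene")
    dir.create(ed, showWarnings = FALSE)
    eg <- report$eigengene
    utils::write.table(data.frame(gene_id = names(eg$assignments),
                                  cluster = unname(eg$assignments),
                                  bootstrap_t = unname(eg$bootstrap_t[names(eg$assignments)])),
                       file.path(ed, "assignments.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(k = as.integer(names(eg$asw)), asw = unname(eg$asw)),
                       file.path(ed, "asw_per_k.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_tsv_matrix(eg$eigengenes, file.path(ed, "eigengenes.tsv"), "cluster")
    utils::write.table(eg$tests, file.path(ed, "cluster_tests.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d significant genes; %d flagged by lineage mismatch (family rank > 1)\n",
              nrow(x$table), sum(!x$table$lineage_match, na.rm = TRUE)))
  if (nrow(x$table) > 0) {
    print(utils::head(x$table[, c("gene_id", "family_match_rank", "top_species",
                                  "fdr", "predicted_tax_group",
                                  "contamination_score")], 10))
  }
  invisible(x)
}
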