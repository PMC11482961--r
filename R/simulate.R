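# Synthetic case-control metagenome bundles with known contamination ground
# truth. The generator emulates the structures a pangenome quantifier emits:
# species relative abundances, per-gene presence / read-count / copy-number
# matrices for one home species, sample metadata, and an annotation map.
# Contaminant genes are driven by a foreign species whose abundance shifts
# between groups, so their read counts track the wrong taxon; planted
# copy-number modules emulate co-varying gene families.

#' Simulation configuration
#'
#' Defaults emulate the cirrhosis case-control study design: 123 cases and
#' 114 controls (one sample per subject), a home species in the family of
#' interest, and a foreign contamination source whose abundance is shifted
#' upward in cases.
#'
#' @param n_cases,n_controls subjects per group.
#' @param n_species species in the community (home species first; two
#'   same-family relatives; one foreign source species).
#' @param n_home_genes ordinary home-pangenome genes.
#' @param n_diff_home_genes how many home genes are truly differentially
#'   carried (alternating case-/control-enriched).
#' @param diff_case_carriage,diff_control_carriage carriage probabilities for
#'   the truly differential genes (enriched group / depleted group).
#' @param n_flag_background ordinary non-differential home genes given a
#'   flagellar-style free-text annotation (so the copy-number workflow sees
#'   unclustered background).
#' @param n_contaminant_genes genes contributed by the foreign species, one
#'   synthetic MAG each.
#' @param foreign_species_effect natural-log abundance shift of the foreign
#'   species in cases.
#' @param gene_depth_scale expected reads per unit relative abundance per
#'   unit copy number.
#' @param presence_copynum_threshold copy number at or above which a gene is
#'   called present.
#' @param module_spec list of planted copy-number modules, each
#'   `list(size, within_correlation, group_effect_sd)` (effect in latent SD
#'   units, positive = case-enriched).
#' @param sigma_log_abundance sample-to-sample SD of log species abundance.
#' @param seed integer seed; all generation is fully seeded.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cases = 123, n_controls = 114, n_species = 40,
                       n_home_genes = 30, n_diff_home_genes = 5,
                       diff_case_carriage = 0.80, diff_control_carriage = 0.45,
                       n_flag_background = 10, n_contaminant_genes = 8,
                       foreign_species_effect = 1.5, gene_depth_scale = 2000,
                       presence_copynum_threshold = 0.35,
                       module_spec = list(
                         list(size = 10, within_correlation = 0.8, group_effect_sd = 1.5),
                         list(size = 5, within_correlation = 0.8, group_effect_sd = -1.5)),
                       sigma_log_abundance = 1, seed = 1) {
  cfg <- list(n_cases = n_cases, n_controls = n_controls, n_species = n_species,
              n_home_genes = n_home_genes, n_diff_home_genes = n_diff_home_genes,
              diff_case_carriage = diff_case_carriage,
              diff_control_carriage = diff_control_carriage,
              n_flag_background = n_flag_background,
              n_contaminant_genes = n_contaminant_genes,
              foreign_species_effect = foreign_species_effect,
              gene_depth_scale = gene_depth_scale,
              presence_copynum_threshold = presence_copynum_threshold,
              module_spec = module_spec,
              sigma_log_abundance = sigma_log_abundance, seed = seed)
  with(cfg, {
    if (n_cases < 1 || n_controls < 1) stop("need at least one subject per group")
    if (n_species < 5) stop("need at least 5 species")
    if (n_home_genes < 1) stop("need at least one home gene")
    if (n_diff_home_genes > n_home_genes) stop("more differential genes than home genes")
    if (n_flag_background > n_home_genes - n_diff_home_genes) {
      stop("n_flag_background exceeds the non-differential home genes")
    }
    if (presence_copynum_threshold <= 0 || presence_copynum_threshold > 1) {
      stop("presence threshold must lie in (0, 1]")
    }
    for (m in module_spec) {
      if (m$size < 3) stop("planted modules need size >= 3")
      if (m$within_correlation < 0 || m$within_correlation >= 1) {
        stop("within_correlation must lie in [0, 1)")
      }
    }
  })
  structure(cfg, class = "sim_config")
}

#' Generate a synthetic community bundle
#'
#' Species abundances are log-normal per sample around fixed per-species
#' means, with the foreign source species shifted by
#' `foreign_species_effect` (natural log) in cases. Home-gene read counts are
#' Poisson with rate `depth x home-species relative abundance x copy number`;
#' contaminant-gene read counts use the foreign species' abundance instead,
#' so a contaminant's apparent copy number in the home pangenome is the
#' foreign-to-home abundance ratio. Presence is called by thresholding copy
#' number. Planted copy-number modules share a latent factor with the
#' configured within-module correlation and group shift.
#'
#' @param config a [sim_config()].
#' @return A `sim_bundle` list: `profile` ([species_profile()]), `presence`,
#'   `reads`, `copynum` ([gene_matrix()]s), `samples` ([sample_table()]),
#'   `annotation` ([annotation_map()]), `truth` (per-gene ground-truth data
#'   frame), `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  samples <- sample_table(data.frame(
    sample_id = sprintf("S%04d", seq_len(n)),
    subject_id = sprintf("SUBJ%04d", seq_len(n)),
    group = rep(c("case", "control"), c(config$n_cases, config$n_controls))))
  is_case <- samples$group == "case"

  ## --- species and lineages ------------------------------------------------
  sp_ids <- sprintf("SP%03d", seq_len(config$n_species))
  home_sp <- sp_ids[1]
  foreign_sp <- sp_ids[4]
  family <- c("Lachnospiraceae", "Lachnospiraceae", "Lachnospiraceae",
              "Veillonellaceae",
              sprintf("Family%02d", 2 + ceiling(seq_len(config$n_species - 4) / 2)))
  lineage <- data.frame(
    species_id = sp_ids, domain = "Bacteria", phylum = "Firmicutes_A",
    class = "Clostridia", order = "Lachnospirales", family = family,
    genus = paste0("Genus_", sp_ids),
    species = paste0("Species ", sp_ids), stringsAsFactors = FALSE)

  mu <- stats::rnorm(config$n_species, 0, 1)
  mu[1] <- 0.5    # home species comfortably abundant
  mu[4] <- -0.3   # foreign source: moderate, so contaminant presence is not saturated
  log_ab <- matrix(stats::rnorm(config$n_species * n, 0, config$sigma_log_abundance),
                   nrow = config$n_species) + mu
  log_ab[4, is_case] <- log_ab[4, is_case] + config$foreign_species_effect
  ab <- exp(log_ab)
  rel <- sweep(ab, 2, colSums(ab), "/")
  dimnames(rel) <- list(sp_ids, samples$sample_id)
  profile <- species_profile(rel, lineage)
  rel_home <- rel[home_sp, ]
  rel_foreign <- rel[foreign_sp, ]

  ## --- gene roles ----------------------------------------------------------
  home_genes <- sprintf("HG%04d", seq_len(config$n_home_genes))
  diff_genes <- utils::head(home_genes, config$n_diff_home_genes)
  flag_bg <- utils::head(setdiff(home_genes, diff_genes), config$n_flag_background)
  mod_sizes <- vapply(config$module_spec, function(m) m$size, numeric(1))
  mod_genes <- if (length(mod_sizes) > 0) {
    sprintf("MG%04d", seq_len(sum(mod_sizes)))
  } else {
    character(0)
  }
  mod_of <- rep(seq_along(mod_sizes), mod_sizes)
  contam_genes <- if (config$n_contaminant_genes > 0) {
    sprintf("CG%04d", seq_len(config$n_contaminant_genes))
  } else {
    character(0)
  }
  genes <- c(home_genes, mod_genes, contam_genes)

  ## --- copy numbers --------------------------------------------------------
  copynum <- matrix(0, nrow = length(genes), ncol = n,
                    dimnames = list(genes, samples$sample_id))
  for (i in seq_along(home_genes)) {
    g <- home_genes[i]
    if (g %in% diff_genes) {
      up_in_case <- (i %% 2) == 1  # alternate enrichment direction
      pi_case <- if (up_in_case) config$diff_case_carriage else config$diff_control_carriage
      pi_ctrl <- if (up_in_case) config$diff_control_carriage else config$diff_case_carriage
      carried <- stats::rbinom(n, 1, ifelse(is_case, pi_case, pi_ctrl))
    } else {
      carried <- stats::rbinom(n, 1, stats::runif(1, 0.3, 0.9))
    }
    copynum[g, ] <- carried * exp(stats::rnorm(n, 0, 0.15))
  }
  for (m in seq_along(config$module_spec)) {
    spec <- config$module_spec[[m]]
    z <- stats::rnorm(n)
    for (g in mod_genes[mod_of == m]) {
      v <- sqrt(spec$within_correlation) * z +
        sqrt(1 - spec$within_correlation) * stats::rnorm(n) +
        spec$group_effect_sd * is_case
      copynum[g, ] <- pmax(0, 1 + 0.25 * v)
    }
  }
  for (g in contam_genes) {
    # apparent copy number in the home pangenome = foreign/home abundance ratio
    copynum[g, ] <- rel_foreign / rel_home * exp(stats::rnorm(n, 0, 0.1))
  }

  ## --- reads and presence --------------------------------------------------
  # reads = Poisson(depth x home abundance x apparent copy number); for
  # contaminants this equals depth x foreign abundance x (own copy ~ 1)
  depth <- config$gene_depth_scale
  reads <- copynum
  for (g in genes) {
    reads[g, ] <- stats::rpois(n, depth * rel_home * copynum[g, ])
  }
  presence <- (copynum >= config$presence_copynum_threshold) * 1

  ## --- annotation map ------------------------------------------------------
  clusters <- sprintf("CL%04d", seq_along(genes))
  flag_desc <- c("Flagellar hook-basal body protein", "Flagellar motor switch protein",
                 "Flagellin biosynthesis chaperone", "Flagellar assembly ATPase",
                 "Flagellar basal body rod protein")
  plain_desc <- c("ABC transporter permease", "Hypothetical protein",
                  "Ribose-phosphate pyrophosphokinase", "Two-component sensor kinase")
  desc <- character(length(genes))
  grp <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (g %in% c(mod_genes, flag_bg)) {
      desc[i] <- flag_desc[(i %% length(flag_desc)) + 1]
      grp[i] <- "Clostridia"
    } else if (g %in% contam_genes) {
      desc[i] <- NA_character_
      grp[i] <- "Negativicutes"
    } else {
      desc[i] <- plain_desc[(i %% length(plain_desc)) + 1]
      grp[i] <- c("Clostridia", "Eubacteriaceae", NA_character_)[(i %% 3) + 1]
    }
  }
  annotation <- annotation_map(
    data.frame(gene_id = genes, cluster_id = clusters),
    data.frame(cluster_id = clusters, predicted_tax_group = grp,
               protein_name = NA_character_, description = desc))

  ## --- ground truth --------------------------------------------------------
  truth <- data.frame(
    gene_id = genes,
    role = c(ifelse(home_genes %in% diff_genes, "home_diff",
                    ifelse(home_genes %in% flag_bg, "flag_background", "home")),
             rep("module", length(mod_genes)),
             rep("contaminant", length(contam_genes))),
    source_species = c(rep(home_sp, length(home_genes) + length(mod_genes)),
                       rep(foreign_sp, length(contam_genes))),
    true_differential = genes %in% c(diff_genes, contam_genes),
    module = c(rep(NA_integer_, length(home_genes)), mod_of,
               rep(NA_integer_, length(contam_genes))),
    mag_id = c(rep(NA_character_, length(home_genes) + length(mod_genes)),
               if (length(contam_genes) > 0) sprintf("MAG_SYN_%04d", seq_along(contam_genes))),
    stringsAsFactors = FALSE)

  structure(list(
    profile = profile,
    presence = gene_matrix(presence, "presence", home_sp),
    reads = gene_matrix(reads, "reads", home_sp),
    copynum = gene_matrix(copynum, "copynum", home_sp),
    samples = samples, annotation = annotation, truth = truth,
    config = config), class = "sim_bundle")
}

#' @export
print.sim_bundle <- function(x, ...) {
  cat(sprintf("<sim_bundle> %d genes x %d samples; %d species; %d contaminant, %d module, %d differential home genes (seed %d)\n",
              nrow(x$reads$values), ncol(x$reads$values),
              nrow(x$profile$abundance),
              sum(x$truth$role == "contaminant"), sum(x$truth$role == "module"),
              sum(x$truth$role == "home_diff"), x$config$seed))
  invisible(x)
}

BUNDLE_FILES <- c(abundance = "species_abundance.tsv",
                  lineage = "species_lineage.tsv",
                  samples = "samples.tsv",
                  presence = "gene_presence.tsv",
                  reads = "gene_reads.tsv",
                  copynum = "gene_copynum.tsv",
                  gene_cluster = "gene_cluster.tsv",
                  cluster_annotation = "cluster_annotation.tsv",
                  truth = "truth.tsv")

#' Write a simulated bundle to a directory of TSV files
#'
#' Files use exactly the dialects the package readers accept; the ground
#' truth is written separately as `truth.tsv`.
#'
#' @param bundle a `sim_bundle`.
#' @param dir output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  f <- file.path(dir, BUNDLE_FILES)
  names(f) <- names(BUNDLE_FILES)
  write_species_profile(bundle$profile, f["abundance"], f["lineage"])
  utils::write.table(as.data.frame(bundle$samples), f["samples"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_matrix(bundle$presence, f["presence"])
  write_gene_matrix(bundle$reads, f["reads"])
  write_gene_matrix(bundle$copynum, f["copynum"])
  write_annotation_map(bundle$annotation, f["gene_cluster"], f["cluster_annotation"])
  utils::write.table(bundle$truth, f["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(f)
}

#' Read a bundle directory back into memory
#'
#' @param dir directory written by [write_bundle()] (or assembled by hand in
#'   the same layout).
#' @param species_id home species id for the gene matrices; defaults to the
#'   first species of the abundance table.
#' @return List with `profile`, `presence`, `reads`, `copynum`, `samples`,
#'   `annotation`, and `truth` (`NULL` when absent).
#' @export
read_bundle <- function(dir, species_id = NULL) {
  f <- file.path(dir, BUNDLE_FILES)
  names(f) <- names(BUNDLE_FILES)
  profile <- read_species_profile(f["abundance"], f["lineage"])
  if (is.null(species_id)) species_id <- rownames(profile$abundance)[1]
  list(profile = profile,
       presence = read_gene_matrix(f["presence"], "presence", species_id),
       reads = read_gene_matrix(f["reads"], "reads", species_id),
       copynum = read_gene_matrix(f["copynum"], "copynum", species_id),
       samples = read_sample_table(f["samples"]),
       annotation = read_annotation_map(f["gene_cluster"], f["cluster_annotation"]),
       truth = if (file.exists(f["truth"])) {
         utils::read.delim(f["truth"], stringsAsFactors = FALSE, na.strings = "")
       })
}
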