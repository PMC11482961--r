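# Small in-code fixtures shared across test files.

tiny_profile <- function() {
  ab <- matrix(c(0.5, 0.3, 0.2,
                 0.2, 0.5, 0.3,
                 0.3, 0.2, 0.5,
                 0.1, 0.1, 0.8,
                 0.4, 0.4, 0.2),
               nrow = 5, byrow = TRUE,
               dimnames = list(paste0("SP", 1:5), paste0("S", 1:3)))
  lin <- data.frame(species_id = paste0("SP", 1:5),
                    domain = "Bacteria", phylum = "Firmicutes_A",
                    class = "Clostridia", order = "Lachnospirales",
                    family = c("Lachnospiraceae", "Lachnospiraceae",
                               "Veillonellaceae", "Veillonellaceae",
                               "Ruminococcaceae"),
                    genus = paste0("G", 1:5),
                    species = paste0("Species SP", 1:5),
                    stringsAsFactors = FALSE)
  species_profile(ab, lin)
}

tiny_presence <- function() {
  m <- matrix(c(1, 1, 0, 0,
                1, 1, 0, 0,
                0, 0, 1, 1),
              nrow = 3, byrow = TRUE,
              dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  gene_matrix(m, "presence", "SP1")
}

tiny_annotation <- function() {
  annotation_map(
    data.frame(gene_id = c("G1", "G2", "G3"),
               cluster_id = c("C9", "C9", "C7")),
    data.frame(cluster_id = c("C9", "C8"),
               predicted_tax_group = c("Negativicutes", "Clostridia"),
               protein_name = c("prs", NA),
               description = c("Ribose-phosphate pyrophosphokinase", NA)))
}

small_sim <- function(seed = 11, ...) {
  simulate_community(sim_config(seed = seed, ...))
}

# null configuration: no foreign shift, no truly differential genes, no
# group effect in the planted modules
null_config <- function(seed) {
  sim_config(seed = seed, foreign_species_effect = 0, n_diff_home_genes = 0,
             module_spec = list(
               list(size = 10, within_correlation = 0.8, group_effect_sd = 0),
               list(size = 5, within_correlation = 0.8, group_effect_sd = 0)))
}
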