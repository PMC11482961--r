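test_that("Spearman rho handles monotone, reversed, tied and constant input", {
  expect_equal(spearman_rho(1:3, c(10, 20, 30)), 1.0)
  expect_equal(spearman_rho(1:3, c(3, 2, 1)), -1.0)
  x <- c(1, 2, 2, 4); y <- c(2, 1, 3, 4)
  expect_equal(spearman_rho(x, y), spearman_oracle(x, y))
  expect_true(is.na(spearman_rho(c(1, 1, 1), 1:3)))
  expect_error(spearman_rho(1:3, 1:4), "length")
  expect_error(spearman_rho(1:2, 1:2), "at least 3")
})

test_that("species are ranked by descending rho with deterministic tie-breaks", {
  prof <- tiny_profile()
  g <- prof$abundance["SP2", ]  # gene tracking SP2 exactly
  ranked <- rank_species_correlations(g, prof)
  expect_equal(ranked$species_id[1], "SP2")
  expect_equal(ranked$rho[1], 1)
  # output is a permutation of the species set
  expect_setequal(ranked$species_id, rownames(prof$abundance))
  expect_equal(ranked$rank, 1:5)

  # identical abundance vectors -> adjacent ranks in species-id order
  ab <- prof$abundance
  ab["SP4", ] <- ab["SP3", ]
  prof2 <- species_profile(ab, prof$lineage)
  r2 <- rank_species_correlations(ab["SP3", ] + 0, prof2)
  i3 <- which(r2$species_id == "SP3"); i4 <- which(r2$species_id == "SP4")
  expect_equal(abs(i3 - i4), 1)
  expect_lt(i3, i4)
  expect_error(rank_species_correlations(c(S9 = 1, S8 = 2), prof), "shared")
})

test_that("lineage match rank finds the first family/species agreement", {
  prof <- tiny_profile()
  home <- prof$lineage["SP1", ]  # Lachnospiraceae
  ranked <- data.frame(species_id = c("SP3", "SP4", "SP2", "SP1", "SP5"),
                       rho = c(0.9, 0.8, 0.5, 0.4, 0.1), rank = 1:5)
  expect_equal(lineage_match_rank(ranked, home, prof, "family"), 3L)
  expect_equal(lineage_match_rank(ranked, home, prof, "species"), 4L)
  # all entries share the home family -> rank 1
  ranked_l <- data.frame(species_id = c("SP2", "SP1"), rho = c(0.9, 0.2), rank = 1:2)
  expect_equal(lineage_match_rank(ranked_l, home, prof, "family"), 1L)
  # no match anywhere -> NA
  ranked_n <- data.frame(species_id = c("SP3", "SP5"), rho = c(0.9, 0.2), rank = 1:2)
  expect_true(is.na(lineage_match_rank(ranked_n, home, prof, "species")))
})

test_that("batch lineage test matches single-gene calls and flags failures", {
  b <- small_sim(seed = 21)
  genes <- c(head(b$truth$gene_id[b$truth$role == "contaminant"], 3),
             head(b$truth$gene_id[b$truth$role == "home_diff"], 2))
  res <- run_lineage_test(genes, b$reads, b$profile)
  expect_equal(nrow(res), 5)
  expect_true(all(res$ok))
  single <- run_lineage_test(genes[1], b$reads, b$profile)
  expect_equal(single[1, ], res[1, ], ignore_attr = TRUE)
  # family rank 1 iff the top-ranked species shares the home family
  fam <- lineage_rank(b$profile, res$top_species, "family")
  home_fam <- lineage_rank(b$profile, res$home_species, "family")
  expect_equal(res$family_match_rank == 1, fam == home_fam)
  # a constant gene row becomes a flagged row, not an abort
  m <- b$reads$values
  m[genes[1], ] <- 0
  res2 <- run_lineage_test(genes[1:2], gene_matrix(m, "reads", b$reads$species_id),
                           b$profile)
  expect_false(res2$ok[1])
  expect_match(res2$note[1], "constant")
  expect_true(res2$ok[2])
})

test_that("consistent species relabeling leaves all ranks unchanged", {
  b <- small_sim(seed = 22)
  genes <- head(b$truth$gene_id[b$truth$role == "contaminant"], 3)
  res1 <- run_lineage_test(genes, b$reads, b$profile)
  relabel <- function(x) paste0("X_", x)
  ab <- b$profile$abundance
  rownames(ab) <- relabel(rownames(ab))
  lin <- b$profile$lineage
  lin$species_id <- relabel(lin$species_id)
  prof2 <- species_profile(ab, lin)
  reads2 <- gene_matrix(b$reads$values, "reads", relabel(b$reads$species_id))
  res2 <- run_lineage_test(genes, reads2, prof2)
  expect_equal(res2$family_match_rank, res1$family_match_rank)
  expect_equal(res2$species_match_rank, res1$species_match_rank)
  expect_equal(res2$top_species, relabel(res1$top_species))
})

test_that("synthetic contaminants rank their source species above home", {
  b <- small_sim(seed = 23)
  contam <- b$truth[b$truth$role == "contaminant", ]
  for (i in seq_len(nrow(contam))) {
    ranked <- rank_species_correlations(b$reads$values[contam$gene_id[i], ],
                                        b$profile)
    r_src <- ranked$rank[ranked$species_id == contam$source_species[i]]
    r_home <- ranked$rank[ranked$species_id == b$reads$species_id]
    expect_lt(r_src, r_home)
  }
})
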