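test_that("annotation-keyword gene selection is substring, case-insensitive", {
  m <- matrix(runif(4 * 6, 0.5, 1.5), nrow = 4,
              dimnames = list(paste0("G", 1:4), paste0("S", 1:6)))
  gm <- gene_matrix(m, "copynum", "SPX")
  map <- annotation_map(
    data.frame(gene_id = paste0("G", 1:4), cluster_id = paste0("C", 1:4)),
    data.frame(cluster_id = paste0("C", 1:4),
               description = c("Flagellar hook-basal body", "conflagration risk",
                               "ABC transporter", NA)))
  sel <- select_annotated_genes(gm, map, "flag")
  expect_setequal(rownames(sel$values), c("G1", "G2"))  # substring, not word
  sel2 <- select_annotated_genes(gm, map, "flag", extra_genes = "G3")
  expect_setequal(rownames(sel2$values), c("G1", "G2", "G3"))
  expect_error(select_annotated_genes(gm, map, "zzz"), "pattern")
})

test_that("correlation distance matches the direct Pearson formula", {
  expect_equal(correlation_distance(rbind(a = 1:5, b = 1:5))["a", "b"], 0)
  expect_equal(correlation_distance(rbind(a = 1:5, b = 5:1))["a", "b"], 2)
  set.seed(2)
  X <- matrix(rnorm(24), nrow = 4,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  D <- correlation_distance(X)
  for (i in 1:4) for (j in 1:4) {
    expect_equal(D[i, j], 1 - cov(X[i, ], X[j, ]) / (sd(X[i, ]) * sd(X[j, ])))
  }
  X[2, ] <- 7
  expect_error(correlation_distance(X), "g2")
})

test_that("PAM recovers planted groups and attains the brute-force objective", {
  set.seed(13)
  grp <- rep(1:2, each = 5)
  X <- matrix(rnorm(10 * 8, mean = grp * 4), nrow = 10)
  D <- as.matrix(dist(X))
  dimnames(D) <- list(paste0("i", 1:10), paste0("i", 1:10))
  fit <- pam_cluster(D, 2)
  expect_equal(length(unique(fit$assignments[1:5])), 1)
  expect_equal(length(unique(fit$assignments[6:10])), 1)
  expect_false(fit$assignments[1] == fit$assignments[6])
  # k = n - 1 forces exactly one pair
  fit2 <- pam_cluster(D, 9)
  expect_equal(sort(unname(table(fit2$assignments)), decreasing = TRUE)[1], 2)
  expect_error(pam_cluster(D, 10), "smaller")
  # objective equals exhaustive medoid search on small instances
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:8, 1)
    Dr <- as.matrix(dist(matrix(rnorm(n * 3), nrow = n)))
    for (k in 2:3) {
      expect_equal(pam_cluster(Dr, k)$objective, pam_brute_oracle(Dr, k),
                   tolerance = 1e-12)
    }
  }
})

test_that("silhouette-based k selection finds two well-separated blobs", {
  set.seed(15)
  X <- matrix(rnorm(14 * 6), nrow = 14)
  X[1:7, ] <- X[1:7, ] + 8
  D <- as.matrix(dist(X))
  sel <- choose_k_by_asw(D, 2, 10)
  expect_equal(sel$k_selected, 2)
  expect_equal(names(sel$asw), as.character(2:10))
  expect_true(all(sel$asw >= -1 & sel$asw <= 1))
  expect_warning(choose_k_by_asw(D, 2, 20), "reduced")
})

test_that("eigengenes are unit-norm, sign-fixed, and rank-stable", {
  set.seed(16)
  base <- rnorm(10)
  X <- rbind(base + rnorm(10, sd = 0.01), base + rnorm(10, sd = 0.01),
             base + rnorm(10, sd = 0.01))
  dimnames(X) <- list(paste0("g", 1:3), paste0("s", 1:10))
  e <- eigengene(X)
  expect_equal(sum(e^2), 1)
  # rank-1 case: proportional to the standardized common profile
  z <- as.numeric(scale(base))
  expect_gt(abs(cor(e, z)), 0.999)
  # positively oriented to the mean profile
  expect_gt(cor(e, colMeans(t(scale(t(X))))), 0)
  # duplicating rows leaves the eigengene unchanged
  expect_equal(eigengene(rbind(X, X)), e, tolerance = 1e-9)
  expect_error(eigengene(X[1:2, ]), ">= 3")
  X[1, ] <- 5
  expect_error(eigengene(X), "g1")
})

test_that("Wilcoxon group test matches exact enumeration and is rank-invariant", {
  # [1,2,3] vs [4,5,6]: 2 of the 20 rank splits are as extreme
  v <- 1:6; g <- rep(c("case", "control"), each = 3)
  expect_equal(wilcoxon_group_test(v, g), 0.1)
  # identical value multisets -> p = 1
  expect_equal(wilcoxon_group_test(c(1, 2, 3, 1, 2, 3), g), 1)
  # invariant under strictly monotone transforms
  set.seed(17)
  v2 <- rnorm(20); g2 <- rep(c("case", "control"), 10)
  expect_equal(wilcoxon_group_test(exp(v2), g2), wilcoxon_group_test(v2, g2))
  expect_error(wilcoxon_group_test(v, rep("case", 6)), "both groups")
})

test_that("bootstrap mean t is seeded, signed by the group difference, and null-centred", {
  g <- rep(c("case", "control"), each = 10)
  v <- c(rnorm(10, 10, 0.1), rnorm(10, 0, 0.1))
  t1 <- bootstrap_t(v, g, B = 200, seed = 3)
  expect_identical(t1, bootstrap_t(v, g, B = 200, seed = 3))
  expect_gt(t1, 10)
  expect_lt(bootstrap_t(-v, g, B = 200, seed = 3), -10)
  set.seed(18)
  null_ts <- vapply(1:15, function(i) {
    bootstrap_t(rnorm(20), g, B = 60, seed = i)
  }, numeric(1))
  expect_lt(abs(mean(null_ts)), 0.5)
  expect_error(bootstrap_t(v, g, B = 0), "positive")
})

test_that("the copy-number pipeline recovers planted modules with opposite directions", {
  b <- small_sim(seed = 31)
  # 25 selected genes: the default k range is capped at n - 1 with a warning
  expect_warning(
    ca <- run_cluster_association(b$copynum, b$annotation, b$samples,
                                  B = 50, seed = 7),
    "reduced")
  mod <- b$truth[b$truth$role == "module", ]
  sig_genes <- names(ca$assignments)[ca$assignments %in% ca$significant_clusters]
  expect_setequal(sig_genes, mod$gene_id)
  expect_true(all(ca$tests$q_value >= ca$tests$p_value))
  expect_true(all(ca$tests$n_genes >= 3))
  # eigengene directions and bootstrap t agree in sign per planted module
  m1 <- mod$gene_id[mod$module == 1]  # case-enriched
  m2 <- mod$gene_id[mod$module == 2]  # control-enriched
  expect_gt(mean(ca$bootstrap_t[m1]), 0)
  expect_lt(mean(ca$bootstrap_t[m2]), 0)
  # flag-annotated background genes were selected but not called significant
  bg <- b$truth$gene_id[b$truth$role == "flag_background"]
  expect_true(all(bg %in% ca$genes))
  expect_false(any(bg %in% sig_genes))
})

test_that("BH over a single retained cluster equals its raw p", {
  # one tight 5-gene module plus two independent genes: any reasonable k
  # leaves exactly one cluster with >= 3 genes
  set.seed(33)
  n <- 80
  grp <- rep(c("case", "control"), each = n / 2)
  z <- rnorm(n) + (grp == "case") * 1.5
  vals <- rbind(t(sapply(1:5, function(i) z + rnorm(n, sd = 0.2))),
                rnorm(n), rnorm(n))
  cn <- pmax(1 + 0.2 * vals, 0)
  dimnames(cn) <- list(paste0("G", 1:7), paste0("S", 1:n))
  gm <- gene_matrix(cn, "copynum", "SPX")
  samples <- sample_table(data.frame(sample_id = colnames(cn),
                                     subject_id = colnames(cn), group = grp))
  map <- annotation_map(
    data.frame(gene_id = rownames(cn), cluster_id = paste0("C", 1:7)),
    data.frame(cluster_id = paste0("C", 1:7),
               description = "Flagellar assembly protein"))
  ca <- run_cluster_association(gm, map, samples, k_min = 2, k_max = 6,
                                B = 20, seed = 5)
  expect_equal(nrow(ca$tests), 1)
  expect_equal(ca$tests$q_value, ca$tests$p_value)
  expect_true(ca$tests$significant)
})
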