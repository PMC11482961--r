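test_that("pairwise Jaccard similarity follows set arithmetic", {
  expect_equal(jaccard_similarity(c(1, 1, 0), c(1, 1, 0)), 1.0)
  expect_equal(jaccard_similarity(c(1, 0, 0), c(0, 1, 1)), 0.0)
  expect_equal(jaccard_similarity(c(1, 1, 0), c(0, 1, 1)), 1 / 3)
  expect_message(v <- jaccard_similarity(c(0, 0), c(0, 0)), "convention")
  expect_equal(v, 1)
  expect_error(jaccard_similarity(c(1, 0), c(1, 0, 1)), "length")
})

test_that("Jaccard matrices match the pairwise oracle and respect the 3-gene rule", {
  gm <- tiny_presence()
  sim <- jaccard_matrix(gm)
  expect_equal(sim, jaccard_pair_oracle(gm$values))
  expect_equal(diag(sim), setNames(rep(1, 3), rownames(gm$values)))
  expect_true(isSymmetric(sim))
  expect_error(jaccard_matrix(gm, c("G1", "G2")), "skipped",
               class = "panscreen_too_few_genes")

  set.seed(9)
  m <- matrix(rbinom(80, 1, 0.4), nrow = 8,
              dimnames = list(paste0("G", 1:8), paste0("S", 1:10)))
  m[3, ] <- m[2, ]  # duplicate profile
  gm2 <- gene_matrix(m, "presence", "SPX")
  sim2 <- jaccard_matrix(gm2)
  expect_equal(sim2, jaccard_pair_oracle(m))
  # sample permutation invariance
  sim2p <- jaccard_matrix(gene_matrix(m[, sample(10)], "presence", "SPX"))
  expect_equal(sim2p, sim2)
})

test_that("a contig block of identical presence profiles forms an all-ones sub-block", {
  set.seed(4)
  base <- rbinom(30, 1, 0.5)
  block <- matrix(rep(base, 9), nrow = 9, byrow = TRUE)
  other <- matrix(rbinom(4 * 30, 1, 0.5), nrow = 4)
  m <- rbind(block, other)
  dimnames(m) <- list(paste0("G", 1:13), paste0("S", 1:30))
  sim <- jaccard_matrix(gene_matrix(m, "presence", "SPX"))
  expect_true(all(sim[1:9, 1:9] == 1))
})

test_that("Jaccard distance satisfies the triangle inequality on random triples", {
  set.seed(12)
  for (rep in 1:30) {
    m <- matrix(rbinom(3 * 20, 1, runif(1, 0.2, 0.8)), nrow = 3)
    d <- function(i, j) 1 - sum(m[i, ] & m[j, ]) / max(1, sum(m[i, ] | m[j, ]))
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
  }
})

make_two_blocks <- function() {
  # two tight presence blocks over 40 samples
  set.seed(6)
  b1 <- rbinom(40, 1, 0.7); b2 <- 1 - b1
  flip <- function(v, k) { i <- sample(40, k); v[i] <- 1 - v[i]; v }
  m <- rbind(t(sapply(1:6, function(i) flip(b1, 2))),
             t(sapply(1:6, function(i) flip(b2, 2))))
  dimnames(m) <- list(paste0("G", 1:12), paste0("S", 1:40))
  m
}

test_that("ordinations separate well-separated blocks and are seed-deterministic", {
  m <- make_two_blocks()
  D <- 1 - jaccard_matrix(gene_matrix(m, "presence", "SPX"))
  for (method in c("NMDS", "PCoA")) {
    o1 <- suppressWarnings(ordinate(D, method, seed = 17))
    o2 <- suppressWarnings(ordinate(D, method, seed = 17))
    expect_identical(o1$coords, o2$coords)
    cd <- as.matrix(dist(o1$coords))
    within <- c(cd[1:6, 1:6][upper.tri(diag(6))], cd[7:12, 7:12][upper.tri(diag(6))])
    between <- cd[1:6, 7:12]
    expect_gt(min(between), max(within))
    if (method == "NMDS") expect_true(is.finite(o1$stress))
  }
})

test_that("PCoA from planar points preserves pairwise distances up to rigid motion", {
  set.seed(8)
  pts <- matrix(rnorm(20), ncol = 2)
  D <- as.matrix(dist(pts))
  o <- ordinate(D, "PCoA", seed = 1)
  expect_equal(as.matrix(dist(o$coords)), D, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("identical presence profiles land on coincident ordination points", {
  m <- make_two_blocks()
  m[2, ] <- m[1, ]
  D <- 1 - jaccard_matrix(gene_matrix(m, "presence", "SPX"))
  o <- suppressWarnings(ordinate(D, "PCoA", seed = 2))
  expect_lt(sqrt(sum((o$coords[1, ] - o$coords[2, ])^2)), 1e-6)
})

test_that("UMAP embedding is seed-deterministic, 2-D, and validates its parameters", {
  m <- make_two_blocks()
  D <- 1 - jaccard_matrix(gene_matrix(m, "presence", "SPX"))
  o1 <- ordinate(D, "UMAP", list(n_neighbors = 4, min_dist = 0.1), seed = 17)
  o2 <- ordinate(D, "UMAP", list(n_neighbors = 4, min_dist = 0.1), seed = 17)
  expect_identical(o1$coords, o2$coords)
  expect_equal(dim(o1$coords), c(12, 2))
  # n_neighbors bounded by ceiling(n/3); min_dist in [0.1, 0.9]
  expect_error(ordinate(D, "UMAP", list(n_neighbors = 5), seed = 1), "n_neighbors")
  expect_error(ordinate(D, "UMAP", list(n_neighbors = 4, min_dist = 0.95), seed = 1),
               "min_dist")
})
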