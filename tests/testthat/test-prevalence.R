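test_that("contingency tables count presence by group", {
  expect_equal(unname(contingency_table(c(1, 1, 0), c("case", "case", "control"))),
               c(2, 0, 0, 1))
  # printed FliQ-style counts: 41/51 cases, 37/77 controls
  pres <- c(rep(1, 41), rep(0, 10), rep(1, 37), rep(0, 40))
  grp <- rep(c("case", "control"), c(51, 77))
  expect_equal(unname(contingency_table(pres, grp)), c(41, 10, 37, 40))
  expect_error(contingency_table(c(1, 0), c("case", "case")), "each group")

  set.seed(42)
  for (i in 1:10) {
    pres <- rbinom(30, 1, 0.5)
    grp <- sample(rep(c("case", "control"), c(14, 16)))
    expected <- c(sum(pres & grp == "case"), sum(!pres & grp == "case"),
                  sum(pres & grp == "control"), sum(!pres & grp == "control"))
    expect_equal(unname(contingency_table(pres, grp)), expected)
  }
})

test_that("Fisher p-values match the hypergeometric enumeration oracle", {
  expect_equal(fisher_exact_two_sided(10, 10, 10, 10), 1.0)
  expect_equal(fisher_exact_two_sided(0, 0, 0, 0), 1)
  expect_equal(fisher_exact_two_sided(0, 0, 5, 5), 1)
  # the two tables printed for the flagellar genes
  for (tab in list(c(0, 51, 20, 57), c(41, 10, 37, 40))) {
    expect_equal(fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4]),
                 fisher_enum_oracle(tab[1], tab[2], tab[3], tab[4]),
                 tolerance = 1e-12)
  }
})

test_that("BH adjustment is step-up with monotonicity and order preserved", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(numeric(0)), numeric(0))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(1)
  p <- runif(50)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  perm <- sample(50)
  expect_equal(bh_adjust(p[perm])[order(perm)], q)
})

test_that("group prevalences reproduce printed percentages", {
  expect_equal(group_prevalence(41, 10, 37, 40)[c("case_pct", "control_pct")],
               list(case_pct = 80, control_pct = 48))
  expect_equal(group_prevalence(0, 51, 20, 57)[c("case_pct", "control_pct")],
               list(case_pct = 0, control_pct = 26))
  expect_equal(group_prevalence(1, 0, 0, 1)[c("case_pct", "control_pct")],
               list(case_pct = 100, control_pct = 0))
  expect_true(is.na(group_prevalence(0, 0, 3, 4)$case_pct))
})

test_that("the prevalence screen flags constructed separations and not constants", {
  set.seed(3)
  n <- 60
  samples <- sample_table(data.frame(
    sample_id = paste0("S", 1:n), subject_id = paste0("U", 1:n),
    group = rep(c("case", "control"), each = 30)))
  m <- matrix(rbinom(5 * n, 1, 0.5), nrow = 5,
              dimnames = list(paste0("G", 1:5), samples$sample_id))
  m["G1", ] <- rep(c(1, 0), each = 30)  # perfect separation
  m["G2", ] <- 1                        # constant
  gm <- gene_matrix(m, "presence", "SPX")
  res <- differential_prevalence(gm, samples)
  expect_equal(res$gene_id[which.min(res$q_value)], "G1")
  expect_true(res$significant[res$gene_id == "G1"])
  expect_equal(res$p_value[res$gene_id == "G2"], 1)
  expect_false(res$significant[res$gene_id == "G2"])
  # Fisher p agrees with the enumeration oracle for every gene
  for (i in seq_len(nrow(res))) {
    expect_equal(res$p_value[i],
                 fisher_enum_oracle(res$a[i], res$b[i], res$c[i], res$d[i]),
                 tolerance = 1e-12)
  }
  # permutation of sample columns changes nothing
  perm <- sample(n)
  gm2 <- gene_matrix(m[, perm], "presence", "SPX")
  res2 <- differential_prevalence(gm2, samples)
  expect_equal(res2$p_value, res$p_value)
  expect_equal(res2$q_value, res$q_value)
  # flag count is non-increasing in alpha
  a_lo <- sum(differential_prevalence(gm, samples, alpha = 0.01)$significant)
  a_hi <- sum(differential_prevalence(gm, samples, alpha = 0.10)$significant)
  expect_lte(a_lo, a_hi)
  expect_error(differential_prevalence(gm, samples[samples$group == "case", ]),
               "control|both")
})

test_that("per-subject collapse ORs presence over a subject's samples", {
  samples <- sample_table(data.frame(
    sample_id = paste0("S", 1:6),
    subject_id = c("U1", "U1", "U2", "U3", "U3", "U4"),
    group = c("case", "case", "case", "control", "control", "control")))
  m <- matrix(c(1, 0, 0, 0, 1, 0), nrow = 1,
              dimnames = list("G1", samples$sample_id))
  gm <- gene_matrix(m, "presence", "SPX")
  res <- differential_prevalence(gm, samples, per_subject = TRUE)
  # subject U1 present (S1), U2 absent, U3 present (S5), U4 absent
  expect_equal(unname(unlist(res[1, c("a", "b", "c", "d")])), c(1, 1, 1, 1))
  expect_equal(res$n_units, 4)
})
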