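# Gene-family copy-number cluster analysis: select annotated genes, cluster
# them with PAM on Pearson correlation distance, pick k by average silhouette
# width, summarise each retained cluster by its SVD eigengene, test
# eigengenes against case/control with the Wilcoxon rank-sum test (BH over
# retained clusters), and quantify per-gene enrichment by a bootstrap mean
# t-statistic.

#' Select genes by annotation keyword
#'
#' Keeps genes whose EggNOG free-text description contains `pattern` as a
#' case-insensitive substring (so `"flag"` matches "Flagellar hook-basal
#' body" — and also "conflagration"; the rule is deliberately blunt), plus
#' any explicitly listed extra genes.
#'
#' @param gm a copynum-kind [gene_matrix()].
#' @param annot an [annotation_map()].
#' @param pattern non-empty substring to look for.
#' @param extra_genes gene ids to add regardless of annotation.
#' @return The [gene_matrix()] restricted to the selected genes.
#' @export
select_annotated_genes <- function(gm, annot, pattern = "flag",
                                   extra_genes = character()) {
  stopifnot(inherits(gm, "gene_matrix"), inherits(annot, "annotation_map"))
  if (!nzchar(pattern)) stop("pattern must be non-empty")
  genes <- rownames(gm$values)
  desc <- annotate_genes(genes, annot)$description
  hit <- !is.na(desc) & grepl(pattern, desc, ignore.case = TRUE, fixed = FALSE)
  keep <- union(genes[hit], intersect(extra_genes, genes))
  keep <- genes[genes %in% keep]  # preserve matrix order
  if (length(keep) == 0) {
    stop("no gene description matches pattern '", pattern,
         "'; check the pattern and the annotation map")
  }
  gene_matrix(gm$values[keep, , drop = FALSE], kind = gm$kind,
              species_id = gm$species_id)
}

#' Pearson correlation distance between gene profiles
#'
#' d(i, j) = 1 - cor(x_i, x_j), in \[0, 2\], zero diagonal.
#'
#' @param X genes x subjects numeric matrix (>= 2 genes, >= 3 subjects, no
#'   constant rows).
#' @return Symmetric distance matrix.
#' @export
correlation_distance <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2 || ncol(X) < 3) stop("need >= 2 genes and >= 3 subjects")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene row(s): ",
         paste(rownames(X)[sds == 0], collapse = ", "))
  }
  D <- 1 - stats::cor(t(X))
  diag(D) <- 0
  D
}

#' Partitioning around medoids on a distance matrix
#'
#' BUILD initialisation followed by SWAP (via `cluster::pam`), plus a fixed
#' number of seeded random-initialisation restarts: SWAP is a local search,
#' and restarts let small instances reliably reach the optimal medoid set.
#' The restart stream is derived from the problem size and `k`, so the
#' result is deterministic for a given distance matrix; ties keep the
#' earliest solution found (BUILD first).
#'
#' @param D symmetric distance matrix.
#' @param k number of clusters, 2 <= k < n.
#' @param restarts extra random-start SWAP runs (default 20).
#' @return List: `assignments` (named integer vector), `medoids` (indices),
#'   `objective` (total distance of items to their medoids).
#' @export
pam_cluster <- function(D, k, restarts = 20) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k >= n) stop("k must be smaller than the number of items")
  if (k < 1) stop("k must be >= 1")
  d <- stats::as.dist(D)
  eval_fit <- function(fit) {
    ass <- fit$clustering
    med <- fit$id.med
    obj <- sum(vapply(seq_len(n), function(i) D[i, med[ass[i]]], numeric(1)))
    list(assignments = ass, medoids = med, objective = obj)
  }
  best <- eval_fit(cluster::pam(d, k = k, diss = TRUE))
  if (restarts > 0) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
            add = TRUE)
    set.seed(7919L * k + n)
    for (r in seq_len(restarts)) {
      fit <- tryCatch(
        cluster::pam(d, k = k, diss = TRUE, medoids = sample.int(n, k)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        cand <- eval_fit(fit)
        if (cand$objective < best$objective - 1e-12) best <- cand
      }
    }
  }
  best
}

#' Choose the number of clusters by average silhouette width
#'
#' Runs PAM for each k in `k_min:k_max` and picks the k maximising the
#' average silhouette width, s(i) = (b(i) - a(i)) / max(a(i), b(i)) with
#' singletons scored 0; ties break toward smaller k.
#'
#' @param D symmetric distance matrix.
#' @param k_min,k_max candidate range (capped at n - 1 with a warning).
#' @return List `k_selected`, `asw` (named vector over candidate k).
#' @export
choose_k_by_asw <- function(D, k_min = 2, k_max = 25) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (k_min < 2) stop("k_min must be >= 2")
  if (k_max >= n) {
    warning("k_max reduced from ", k_max, " to ", n - 1)
    k_max <- n - 1
  }
  if (k_min > k_max) stop("k_min exceeds the usable k_max")
  ks <- k_min:k_max
  asw <- vapply(ks, function(k) {
    fit <- pam_cluster(D, k)
    sil <- cluster::silhouette(fit$assignments, dmatrix = D)
    mean(sil[, "sil_width"])
  }, numeric(1))
  names(asw) <- ks
  list(k_selected = ks[which.max(asw)], asw = asw)
}

#' SVD eigengene of a gene cluster
#'
#' Rows (genes) are standardised to zero mean and unit variance across
#' subjects; the first right-singular vector of the standardised matrix is
#' returned, with its sign fixed so that its correlation with the mean
#' standardised profile is non-negative (SVD sign is otherwise arbitrary).
#'
#' @param X genes x subjects matrix, >= 3 genes (retained-cluster rule), no
#'   constant rows.
#' @return Unit-norm numeric vector over subjects.
#' @export
eigengene <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 3) stop("eigengene needs >= 3 genes")
  sds <- apply(X, 1, stats::sd)
  if (any(sds == 0)) {
    stop("constant gene row(s): ", paste(rownames(X)[sds == 0], collapse = ", "))
  }
  Z <- t(scale(t(X)))
  v <- svd(Z, nu = 0, nv = 1)$v[, 1]
  if (stats::cor(v, colMeans(Z)) < 0) v <- -v
  stats::setNames(v, colnames(X))
}

#' Two-sided Wilcoxon rank-sum test between groups
#'
#' Exact null distribution when the combined sample size is at most 25 and
#' there are no ties; tie-corrected normal approximation otherwise.
#'
#' @param values numeric vector over subjects.
#' @param groups matching `"case"`/`"control"` labels.
#' @return Two-sided p-value.
#' @export
wilcoxon_group_test <- function(values, groups) {
  groups <- as.character(groups)
  x <- values[groups == "case"]
  y <- values[groups == "control"]
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y) <= 25) && !ties
  stats::wilcox.test(x, y, exact = use_exact, correct = !use_exact)$p.value
}

#' Bootstrap mean t-statistic for group enrichment
#'
#' Resamples subjects with replacement within each group (original group
#' sizes preserved), computes the two-sample t-statistic (case minus
#' control) per resample, and returns the mean over `B` resamples. Resamples
#' with zero pooled variance are redrawn.
#'
#' @param values numeric vector over subjects.
#' @param groups matching `"case"`/`"control"` labels (>= 2 per group).
#' @param B number of bootstrap resamples.
#' @param seed integer seed.
#' @param var_equal pooled-variance (Student) t if `TRUE` (default), Welch
#'   otherwise.
#' @return Mean bootstrap t-statistic.
#' @export
bootstrap_t <- function(values, groups, B = 500, seed = 1, var_equal = TRUE) {
  if (B <= 0) stop("B must be positive")
  groups <- as.character(groups)
  x <- values[groups == "case"]
  y <- values[groups == "control"]
  if (length(x) < 2 || length(y) < 2) stop("need >= 2 subjects per group")
  t_stat <- function(a, b) {
    if (var_equal) {
      sp2 <- ((length(a) - 1) * stats::var(a) + (length(b) - 1) * stats::var(b)) /
        (length(a) + length(b) - 2)
      if (sp2 == 0) return(NA_real_)
      (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
    } else {
      se2 <- stats::var(a) / length(a) + stats::var(b) / length(b)
      if (se2 == 0) return(NA_real_)
      (mean(a) - mean(b)) / sqrt(se2)
    }
  }
  set.seed(seed)
  ts <- numeric(B)
  for (i in seq_len(B)) {
    ti <- NA_real_
    while (is.na(ti)) {
      ti <- t_stat(sample(x, replace = TRUE), sample(y, replace = TRUE))
    }
    ts[i] <- ti
  }
  mean(ts)
}

#' Copy-number cluster association analysis
#'
#' End-to-end procedure: select annotated genes, compute Pearson correlation
#' distance, cluster with PAM choosing k by average silhouette width over
#' `k_min:k_max`, discard clusters with fewer than `min_cluster_size` genes,
#' summarise each retained cluster by its SVD eigengene, test each eigengene
#' for a case/control difference with the Wilcoxon rank-sum test, adjust
#' with Benjamini-Hochberg over the retained clusters, and compute a
#' bootstrap mean t-statistic per selected gene.
#'
#' Copy numbers are analysed per subject: when a subject has several
#' samples, its columns are averaged first.
#'
#' @param copynum a copynum-kind [gene_matrix()].
#' @param annot an [annotation_map()].
#' @param samples a [sample_table()].
#' @param pattern,extra_genes passed to [select_annotated_genes()].
#' @param k_min,k_max silhouette search range.
#' @param min_cluster_size smallest cluster retained (default 3).
#' @param alpha FDR cutoff on adjusted p-values.
#' @param B,seed bootstrap settings for [bootstrap_t()].
#' @param var_equal t-statistic form for the bootstrap.
#' @return A `cluster_association` object.
#' @export
run_cluster_association <- function(copynum, annot, samples, pattern = "flag",
                                    extra_genes = character(), k_min = 2,
                                    k_max = 25, min_cluster_size = 3,
                                    alpha = 0.05, B = 500, seed = 1,
                                    var_equal = TRUE) {
  stopifnot(inherits(copynum, "gene_matrix"))
  if (copynum$kind != "copynum") stop("run_cluster_association needs a copynum matrix")
  samples <- sample_table(samples)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }
  sel <- stage("select_genes", select_annotated_genes(copynum, annot, pattern, extra_genes))
  shared <- shared_samples(sel, samples$sample_id)
  if (length(shared) < 3) stop("[align] fewer than 3 samples shared with metadata")
  meta <- samples[match(shared, samples$sample_id), ]
  X <- sel$values[, shared, drop = FALSE]
  subjects <- unique(meta$subject_id)
  X <- vapply(subjects, function(s) {
    rowMeans(X[, meta$subject_id == s, drop = FALSE])
  }, numeric(nrow(X)))
  colnames(X) <- subjects
  groups <- meta$group[match(subjects, meta$subject_id)]
  if (length(unique(groups)) < 2) stop("[align] both groups required")

  D <- stage("correlation_distance", correlation_distance(X))
  sel_k <- stage("choose_k", choose_k_by_asw(D, k_min, k_max))
  fit <- stage("pam", pam_cluster(D, sel_k$k_selected))
  sizes <- table(fit$assignments)
  retained <- as.integer(names(sizes)[sizes >= min_cluster_size])
  if (length(retained) == 0) stop("[retain] no cluster has >= ", min_cluster_size, " genes")

  eg <- stage("eigengene", {
    m <- t(vapply(retained, function(cl) {
      eigengene(X[names(fit$assignments)[fit$assignments == cl], , drop = FALSE])
    }, numeric(ncol(X))))
    rownames(m) <- paste0("cluster_", retained)
    m
  })
  p <- stage("wilcoxon", vapply(seq_along(retained), function(i) {
    wilcoxon_group_test(eg[i, ], groups)
  }, numeric(1)))
  q <- bh_adjust(p)
  tests <- data.frame(cluster = retained, n_genes = as.integer(sizes[as.character(retained)]),
                      p_value = p, q_value = q, significant = q <= alpha,
                      row.names = NULL)
  boot <- stage("bootstrap_t", {
    genes <- rownames(X)
    stats::setNames(vapply(seq_along(genes), function(i) {
      bootstrap_t(X[i, ], groups, B = B, seed = seed + i, var_equal = var_equal)
    }, numeric(1)), genes)
  })
  structure(list(k_selected = sel_k$k_selected, asw = sel_k$asw,
                 assignments = fit$assignments, medoids = fit$medoids,
                 cluster_sizes = as.integer(sizes),
                 retained_clusters = retained, eigengenes = eg,
                 groups = stats::setNames(groups, subjects),
                 tests = tests, significant_clusters = retained[q <= alpha],
                 bootstrap_t = boot, genes = rownames(X),
                 n_subjects = ncol(X), alpha = alpha, seed = seed),
            class = "cluster_association")
}

#' @export
print.cluster_association <- function(x, ...) {
  cat(sprintf("<cluster_association> %d genes, %d subjects; k = %d (%d retained, %d significant at q <= %g)\n",
              length(x$genes), x$n_subjects, x$k_selected,
              length(x$retained_clusters), length(x$significant_clusters),
              x$alpha))
  print(x$tests)
  invisible(x)
}

#' @export
summary.cluster_association <- function(object, ...) {
  print(object)
  cat("\nPer-gene bootstrap mean t (case minus control), strongest first:\n")
  bt <- sort(object$bootstrap_t, decreasing = TRUE)
  print(round(utils::head(bt, 10), 3))
  invisible(object)
}
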