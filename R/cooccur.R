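# Gene co-occurrence across samples: Jaccard similarity of presence/absence
# profiles and two-dimensional ordination of the complementary distance.
# Genes sitting on the same contaminant contig co-occur almost perfectly and
# show up as tight blocks/clusters.

#' Jaccard similarity of two presence/absence profiles
#'
#' |intersection| / |union|. Two all-absent profiles are scored 1 by
#' convention (and reported via a message) so that degenerate genes collapse
#' onto one point instead of poisoning the matrix.
#'
#' @param u,v 0/1 vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(u, v) {
  if (length(u) != length(v)) stop("profiles differ in length")
  if (!all(u %in% c(0, 1)) || !all(v %in% c(0, 1))) stop("profiles must be 0/1")
  uni <- sum(u == 1 | v == 1)
  if (uni == 0) {
    message("both profiles empty; Jaccard similarity 1 by convention")
    return(1)
  }
  sum(u == 1 & v == 1) / uni
}

#' Pairwise Jaccard similarity matrix for a gene subset
#'
#' @param gm a presence-kind [gene_matrix()].
#' @param gene_ids genes to include (>= 3, matching the rule that species
#'   with fewer than 3 significant genes are skipped).
#' @return Symmetric similarity matrix with unit diagonal.
#' @export
jaccard_matrix <- function(gm, gene_ids = rownames(gm$values)) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$kind != "presence") stop("jaccard_matrix needs a presence matrix")
  missing <- setdiff(gene_ids, rownames(gm$values))
  if (length(missing) > 0) stop("genes not in matrix: ", paste(missing, collapse = ", "))
  if (length(gene_ids) < 3) {
    stop(structure(class = c("panscreen_too_few_genes", "error", "condition"),
                   list(message = sprintf(
                     "species '%s' has %d gene(s) (< 3); co-occurrence skipped",
                     gm$species_id, length(gene_ids)), call = NULL)))
  }
  m <- gm$values[gene_ids, , drop = FALSE]
  inter <- tcrossprod(m)
  rs <- rowSums(m)
  uni <- outer(rs, rs, "+") - inter
  sim <- ifelse(uni == 0, 1, inter / uni)
  n_empty <- sum(rs == 0)
  if (n_empty > 0) {
    message(n_empty, " all-absent gene(s); their mutual similarities set to 1 by convention")
  }
  dimnames(sim) <- list(gene_ids, gene_ids)
  sim
}

#' Two-dimensional ordination of a dissimilarity matrix
#'
#' * `NMDS`: non-metric MDS (`vegan::metaMDS`, monoMDS engine) in 2
#'   dimensions with up to `trymax` seeded random restarts; the lowest-stress
#'   solution and its stress are returned.
#' * `PCoA`: classical scaling (`stats::cmdscale`); tiny negative eigenvalues
#'   from numerical noise are clamped to zero with a warning.
#' * `UMAP`: delegated to the `umap-learn` library through the `python`
#'   interpreter on the PATH (precomputed metric, fixed `random_state`).
#'
#' All methods are deterministic for a fixed `seed`.
#'
#' @param dissimilarity square symmetric matrix with zero diagonal.
#' @param method `"NMDS"`, `"UMAP"` or `"PCoA"`.
#' @param params method parameters. For UMAP: `n_neighbors` (2 to
#'   `ceiling(n/3)`) and `min_dist` (0.1 to 0.9 in steps of 0.1). For NMDS:
#'   `trymax` (default 50 restarts).
#' @param seed integer seed.
#' @return List with `coords` (n x 2, rownames preserved), `stress` (NMDS
#'   only, else `NA`), `method`, `params`.
#' @export
ordinate <- function(dissimilarity, method = c("NMDS", "UMAP", "PCoA"),
                     params = list(), seed = 1) {
  method <- match.arg(method)
  D <- as.matrix(dissimilarity)
  if (nrow(D) != ncol(D) || any(abs(D - t(D)) > 1e-8) || any(diag(D) != 0)) {
    stop("dissimilarity must be square, symmetric, with zero diagonal")
  }
  n <- nrow(D)
  coords <- switch(method,
    PCoA = {
      fit <- stats::cmdscale(stats::as.dist(D), k = min(2, n - 1), eig = TRUE)
      if (any(fit$eig < -1e-8)) {
        warning(sprintf("PCoA: %d negative eigenvalue(s) clamped to zero (min %.3g)",
                        sum(fit$eig < -1e-8), min(fit$eig)))
      }
      pts <- fit$points
      if (ncol(pts) < 2) pts <- cbind(pts, 0)
      stress <- NA_real_
      list(pts = pts, stress = stress)
    },
    NMDS = {
      trymax <- params$trymax %||% 50
      set.seed(seed)
      fit <- tryCatch(
        vegan::metaMDS(stats::as.dist(D), k = 2, trymax = trymax, trace = 0,
                       autotransform = FALSE, wascores = FALSE),
        error = function(e) stop("NMDS failed: ", conditionMessage(e)))
      if (isTRUE(fit$converged == FALSE)) {
        warning("NMDS did not converge within ", trymax,
                " restarts; reporting lowest-stress solution (stress = ",
                signif(fit$stress, 4), ")")
      }
      list(pts = fit$points, stress = fit$stress)
    },
    UMAP = {
      nn_max <- max(2, ceiling(n / 3))
      nn <- params$n_neighbors %||% min(15, nn_max)
      md <- params$min_dist %||% 0.1
      if (nn < 2 || nn > nn_max) {
        stop(sprintf("UMAP n_neighbors must lie in [2, %d] for %d genes", nn_max, n))
      }
      if (md < 0.1 - 1e-9 || md > 0.9 + 1e-9) {
        stop("UMAP min_dist must lie in [0.1, 0.9]")
      }
      list(pts = umap_embed(D, nn, md, seed), stress = NA_real_)
    })
  pts <- coords$pts[, 1:2, drop = FALSE]
  dimnames(pts) <- list(rownames(D), c("dim1", "dim2"))
  list(coords = pts, stress = coords$stress, method = method,
       params = switch(method,
                       NMDS = list(trymax = params$trymax %||% 50),
                       UMAP = list(n_neighbors = params$n_neighbors %||% min(15, max(2, ceiling(n / 3))),
                                   min_dist = params$min_dist %||% 0.1),
                       PCoA = list()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

umap_embed <- function(D, n_neighbors, min_dist, seed) {
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("UMAP needs a 'python' interpreter with umap-learn on the PATH")
  script <- system.file("python", "umap_embed.py", package = "panscreen")
  if (!nzchar(script)) stop("bundled umap_embed.py not found")
  din <- tempfile(fileext = ".tsv"); on.exit(unlink(din), add = TRUE)
  dout <- tempfile(fileext = ".tsv"); on.exit(unlink(dout), add = TRUE)
  utils::write.table(D, din, sep = "\t", row.names = FALSE, col.names = FALSE)
  # pin hash randomisation and threading: umap's disconnected-component
  # handling is otherwise not reproducible across interpreter invocations
  res <- suppressWarnings(system2(py, c(script, din, dout, n_neighbors, min_dist, seed),
                                  stdout = TRUE, stderr = TRUE,
                                  env = c("PYTHONHASHSEED=0",
                                          "OMP_NUM_THREADS=1",
                                          "NUMBA_NUM_THREADS=1")))
  status <- attr(res, "status") %||% 0
  if (status != 0 || !file.exists(dout)) {
    stop("UMAP embedding failed:\n", paste(res, collapse = "\n"))
  }
  as.matrix(utils::read.table(dout, sep = "\t"))
}

#' Gene co-occurrence summary for one species
#'
#' Jaccard similarity over the given genes plus the requested ordinations of
#' the complementary distance. Also records an average-linkage leaf order of
#' the genes (a display aid only).
#'
#' @param gm presence-kind [gene_matrix()].
#' @param gene_ids genes to include (>= 3).
#' @param methods ordination methods to run.
#' @param params named list of per-method parameter lists.
#' @param seed integer seed shared by all ordinations.
#' @return A `cooccurrence` object: `species_id`, `gene_ids`, `jaccard`,
#'   `embeddings` (per method: coords, stress), `leaf_order`, `params`.
#' @export
cooccurrence <- function(gm, gene_ids = rownames(gm$values),
                         methods = c("NMDS", "PCoA"), params = list(),
                         seed = 1) {
  sim <- jaccard_matrix(gm, gene_ids)
  D <- 1 - sim
  emb <- lapply(methods, function(m) ordinate(D, m, params[[m]] %||% list(), seed))
  names(emb) <- methods
  leaf <- stats::hclust(stats::as.dist(D), method = "average")$order
  structure(list(species_id = gm$species_id, gene_ids = gene_ids,
                 jaccard = sim, embeddings = emb,
                 leaf_order = gene_ids[leaf], seed = seed),
            class = "cooccurrence")
}

#' @export
print.cooccurrence <- function(x, ...) {
  st <- vapply(x$embeddings, function(e) e$stress, numeric(1))
  cat(sprintf("<cooccurrence> %s: %d genes; ordinations: %s\n", x$species_id,
              length(x$gene_ids),
              paste(sprintf("%s%s", names(x$embeddings),
                            ifelse(is.na(st), "", sprintf(" (stress %.3f)", st))),
                    collapse = ", ")))
  invisible(x)
}
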