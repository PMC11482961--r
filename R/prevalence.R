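# Differential gene prevalence between cases and controls: per-gene 2x2
# contingency tables, Fisher's exact test, Benjamini-Hochberg correction.

#' Build a 2x2 presence/group contingency table
#'
#' @param presence 0/1 vector over units (samples or subjects).
#' @param groups matching vector of `"case"`/`"control"` labels.
#' @return Integer vector `c(a, b, c, d)`: cases with / without the gene,
#'   controls with / without.
#' @export
contingency_table <- function(presence, groups) {
  if (length(presence) != length(groups)) stop("presence and groups differ in length")
  if (!all(presence %in% c(0, 1))) stop("presence must be 0/1")
  groups <- as.character(groups)
  n_case <- sum(groups == "case")
  n_ctrl <- sum(groups == "control")
  if (n_case < 1 || n_ctrl < 1) stop("need at least one unit in each group")
  a <- sum(presence == 1 & groups == "case")
  cc <- sum(presence == 1 & groups == "control")
  c(a = a, b = n_case - a, c = cc, d = n_ctrl - cc)
}

#' Two-sided Fisher's exact p-value for a 2x2 table
#'
#' Sums hypergeometric probabilities no larger than that of the observed
#' table. A table with an all-zero margin carries no information and returns
#' p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts (cases with/without,
#'   controls with/without).
#' @return p-value in (0, 1].
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != floor(cells))) {
    stop("cell counts must be non-negative integers")
  }
  if ((a + b == 0) || (c + d == 0) || (a + c == 0) || (b + d == 0)) return(1)
  stats::fisher.test(matrix(cells, nrow = 2, byrow = TRUE))$p.value
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH with cumulative-minimum monotonicity; output order matches the
#' input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Group prevalence percentages from a 2x2 table
#'
#' @param a,b,c,d cell counts as in [contingency_table()].
#' @return List with exact fractions (`case_frac`, `control_frac`) and
#'   integer-rounded percentages (`case_pct`, `control_pct`); `NA` for a
#'   zero denominator.
#' @export
group_prevalence <- function(a, b, c, d) {
  cf <- if (a + b > 0) a / (a + b) else NA_real_
  kf <- if (c + d > 0) c / (c + d) else NA_real_
  list(case_frac = cf, control_frac = kf,
       case_pct = if (is.na(cf)) NA_real_ else round(100 * cf),
       control_pct = if (is.na(kf)) NA_real_ else round(100 * kf))
}

#' Differential prevalence screen
#'
#' Tests every gene of a presence/absence matrix for a difference in carriage
#' rate between cases and controls with Fisher's exact test, then adjusts for
#' multiple testing. The test unit is the sample; with `per_subject = TRUE`
#' each subject counts once, a gene being scored present in a subject if it is
#' present in any of the subject's samples. Genes with zero variance among the
#' tested units get p = 1 and stay in the multiple-testing denominator.
#'
#' @param gm a presence-kind [gene_matrix()].
#' @param samples a [sample_table()] covering (at least) the matrix samples.
#' @param alpha significance cutoff applied to the adjusted p-values.
#' @param per_subject collapse replicate samples to one unit per subject.
#' @param adjust p-value adjustment function; defaults to [bh_adjust()].
#' @return A `prevalence_table` data frame, one row per gene in gene-id order:
#'   counts `a`..`d`, prevalences, `p_value`, `q_value`, `significant`, and
#'   `n_units` actually tested.
#' @export
differential_prevalence <- function(gm, samples, alpha = 0.05,
                                    per_subject = FALSE, adjust = bh_adjust) {
  stopifnot(inherits(gm, "gene_matrix"))
  if (gm$kind != "presence") stop("differential_prevalence needs a presence matrix")
  samples <- sample_table(samples)
  shared <- shared_samples(gm, samples$sample_id)
  if (length(shared) == 0) stop("no samples shared between matrix and metadata")
  meta <- samples[match(shared, samples$sample_id), ]
  pres <- gm$values[, shared, drop = FALSE]
  if (per_subject) {
    subj <- unique(meta$subject_id)
    pres <- vapply(subj, function(s) {
      as.numeric(rowSums(pres[, meta$subject_id == s, drop = FALSE]) > 0)
    }, numeric(nrow(pres)))
    if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1,
                                           dimnames = list(rownames(gm$values), subj))
    groups <- meta$group[match(subj, meta$subject_id)]
  } else {
    groups <- meta$group
  }
  if (length(unique(groups)) < 2) {
    stop("both case and control units are required (only '",
         unique(groups), "' present)")
  }
  genes <- sort(rownames(pres))
  tab <- t(vapply(genes, function(g) contingency_table(pres[g, ], groups),
                  numeric(4)))
  p <- vapply(seq_len(nrow(tab)), function(i) {
    fisher_exact_two_sided(tab[i, 1], tab[i, 2], tab[i, 3], tab[i, 4])
  }, numeric(1))
  q <- adjust(p)
  out <- data.frame(gene_id = genes, a = tab[, 1], b = tab[, 2],
                    c = tab[, 3], d = tab[, 4],
                    case_prevalence = tab[, 1] / (tab[, 1] + tab[, 2]),
                    control_prevalence = tab[, 3] / (tab[, 3] + tab[, 4]),
                    case_pct = round(100 * tab[, 1] / (tab[, 1] + tab[, 2])),
                    control_pct = round(100 * tab[, 3] / (tab[, 3] + tab[, 4])),
                    p_value = p, q_value = q, significant = q <= alpha,
                    n_units = length(groups),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("prevalence_table", "data.frame")
  attr(out, "alpha") <- alpha
  attr(out, "unit") <- if (per_subject) "subject" else "sample"
  out
}

#' @export
print.prevalence_table <- function(x, ...) {
  cat(sprintf("<prevalence_table> %d genes tested on %d %ss; %d significant at q <= %g\n",
              nrow(x), x$n_units[1], attr(x, "unit"), sum(x$significant),
              attr(x, "alpha")))
  NextMethod()
}
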