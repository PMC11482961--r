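---
title: "Screening pangenome-based metagenomic associations for contamination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening pangenome-based metagenomic associations for contamination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(panscreen)
```

## The model

Pangenome-based gene-content analysis aligns metagenomic reads to a
per-species gene catalogue and reports, per gene and sample, presence calls,
read counts and copy-number estimates. Because the catalogues include
metagenome-assembled genomes, a small number of genes may originate from
contaminating contigs of unrelated taxa. A contaminant gene behaves like a
perfectly measured gene of the *wrong* species: its read counts follow the
abundance of the true source taxon. If that taxon differs between cases and
controls, the gene appears (correctly, numerically; incorrectly,
biologically) as a significant association of the host species.

`panscreen` treats contamination detection as a ranking problem. For a gene
$g$ with read counts $x_g$ over samples and species relative abundances
$a_s$, compute Spearman's $\rho(x_g, a_s)$ for every species $s$, sort
species by descending $\rho$, and report

$$ r_g^{\text{family}} = \min\{\, \text{rank}(s) : \text{family}(s) =
\text{family}(\text{home}(g)) \,\}, $$

and analogously $r_g^{\text{species}}$. A genuine gene's counts track its
own species (or a close relative), so $r_g \approx 1$; a contaminant tracks
its source taxon and the first same-family species appears far down the
list. The statistic needs no external database, only the quantities the
quantifier already produced.

Assumptions worth stating: correlations are computed on the samples shared
between the gene matrix and the abundance profile (the quantifier emits gene
matrices only for samples where the species passed coverage, so this
intersection is the natural analysis set, and each result records the n
used); the home species is included in the correlation set, which is what
makes rank-1 self-matches possible; rank-based correlation makes the
statistic invariant to monotone transforms of counts, so no normalisation is
applied; relative abundances are compositional, which we deliberately do not
correct — the contaminant signal of interest *is* a co-abundance pattern.

## Differential prevalence

Prevalence is compared with Fisher's exact test on per-gene 2×2 tables and
adjusted with Benjamini–Hochberg; adjusted p ≤ 0.05 counts as significant.
Two choices are configurable because the field does not agree on them:

* **Test unit.** The default unit is the sample; `per_subject = TRUE`
  collapses replicates so each subject counts once, a gene being present in
  a subject if present in any of its samples. Published per-subject
  denominators motivate offering the collapse, but no collapse rule is
  standard, so the simple logical-OR is used and documented.
* **Adjustment.** BH is the default; the `adjust` argument accepts any
  p-to-q function, so a discrete-FDR method can be substituted. Source
  analyses in this area have used both, and on sparse 2×2 tables discrete
  methods are less conservative; with BH the packaged defaults are the more
  cautious choice.

Zero-variance genes (present or absent everywhere) get p = 1 and stay in the
multiple-testing denominator, keeping the adjustment stable under gene-set
changes.

## Co-occurrence and ordination

Jaccard similarity of presence profiles is computed for species with at
least 3 significant genes (fewer genes cannot form a meaningful block
structure; such species are skipped with a log record). Numerical
conventions: two all-absent profiles score similarity 1 (degenerate genes
collapse onto one point rather than poisoning the matrix; among significant
genes such profiles cannot occur), and the complementary distance is metric,
which the test suite spot-checks on random triples.

Ordination methods and their numerical choices:

* **NMDS** — 2 dimensions via monotone regression with up to 50 seeded
  random restarts; the lowest-stress solution and its stress are reported,
  and non-convergence is a warning with diagnostics, never silent.
* **PCoA** — classical scaling; tiny negative eigenvalues (numerical noise
  on a metric distance) are clamped to zero with a warning.
* **UMAP** — delegated to the `umap-learn` library through the `python`
  interpreter, with `n_neighbors` restricted to $[2, \lceil n/3 \rceil]$ and
  `min_dist` to $\{0.1, \dots, 0.9\}$. The embedding uses seeded *random*
  initialisation: spectral initialisation of a neighbour graph with several
  connected components — exactly the situation contaminant blocks create —
  is not reproducible across interpreter sessions, while the seeded random
  path is bit-stable. The wrapper also pins hash randomisation and thread
  counts in the subprocess.

All ordinations are deterministic given the seed.

## Annotation scoring

A gene's protein-cluster annotation carries a predicted taxonomic range.
The score maps ranges to $\{0, 0.5, 1\}$ via two configurable taxon lists;
the packaged default is the *Lachnospiraceae* study configuration:
ranges that cannot include Lachnospiraceae (Paenibacillaceae,
Pasteurellales, Negativicutes, Desulfovibrionales, Erysipelotrichia,
Oscillospiraceae) score 1; ranges historically compatible with
Lachnospiraceae members in NCBI taxonomy (Clostridia, Clostridiales,
Clostridiaceae, Ruminococcaceae, Eubacteriaceae, Lachnospiraceae and its
genera, "unclassified Lachnospiraceae", "unclassified Clostridiales") score
0; missing annotations and "Bacteria" score 0.5. Annotation vocabularies
are open, so an unlisted group scores 0.5 with a warning rather than
failing: a neutral default is safer than guessing a direction.

## Evaluation conventions

AUROC is the Mann–Whitney statistic with ties counted half. Directions:

* family rank, EggNOG score: directed, "higher score = more
  contaminant-like".
* FDR q: the q-value itself as the score, directed — the resulting AUROC
  below 0.5 *is* the finding (significance anti-predicts contamination).
* species-level rank: reported with median-based automatic direction choice,
  the default behaviour of the ROC software used in the original analyses.
  The directed value is its complement; both are available through
  `auroc(direction =)`. For a predictor whose discriminability is the
  question, the direction-agnostic convention answers "is there any signal"
  — and the answer (≈ 0.5, none) is the same either way.

A gene with no lineage match anywhere is scored as (largest observed
rank + 1): this preserves "worse than every observed match" ordering without
inventing a magnitude. The packaged 86-gene reference screen ships as a
plain TSV; its transcription repairs (a species name split by a line break,
a protein name split by a space, filled-in row-spanned cells) are documented
in the companion notes file next to it under `inst/extdata/`.

## Copy-number cluster association

For an annotated gene family (selection by case-insensitive substring match
on the free-text description — deliberately blunt; `"flag"` matches
"Flagellar…" and also "conflagration", and the matched set should be
reviewed), the pipeline is:

1. Pearson correlation distance $d_{ij} = 1 - \text{cor}(x_i, x_j)$ between
   gene copy-number profiles over subjects (replicate samples averaged per
   subject first).
2. PAM clustering. SWAP is a local search, so BUILD is supplemented with 20
   seeded random restarts and the lowest-objective solution kept; on small
   instances this reliably attains the exhaustive-search optimum (verified
   against brute force in the tests) and the result stays deterministic for
   a given distance matrix.
3. k selected by average silhouette width over k = 2…25 (capped at n − 1),
   singletons scored 0, ties toward smaller k.
4. Clusters with fewer than 3 genes are discarded: an "eigengene" of 1–2
   genes is not a summary.
5. Per retained cluster, genes are z-scored across subjects and the first
   right-singular vector of the standardised matrix is the eigengene. The
   z-scoring makes the summary scale-free (the established eigengene
   convention; the alternative, unstandardised SVD, would let one
   high-variance gene dominate). SVD sign is arbitrary, so the sign is fixed
   by non-negative correlation with the mean standardised profile — this
   makes results reproducible across linear-algebra backends.
6. Wilcoxon rank-sum test of each eigengene against case/control — exact
   null for combined n ≤ 25 without ties, tie-corrected normal approximation
   otherwise — with BH over the *retained* clusters only, q ≤ 0.05
   significant.
7. Per-gene enrichment as the mean two-sample t statistic (case minus
   control; pooled-variance Student form by default, Welch via
   `var_equal = FALSE`) over 500 bootstrap resamples, drawn with replacement
   within each group. Stratified resampling preserves the group sizes, which
   is what keeps the t statistic comparable across resamples; resamples with
   zero pooled variance are redrawn.

## The synthetic generator

`simulate_community()` emulates the structures of a merged quantifier run
for one home species: log-normal species abundances per sample (renormalised
to relative abundances), Poisson read counts with rate
depth × home-species abundance × copy number, presence calls by thresholding
copy number, and an annotation map. Contaminant genes use the foreign source
species' abundance instead of the home species', so their apparent copy
number is the foreign-to-home abundance ratio — the generative mechanism of
pangenome contamination, not a label pasted on noise.

Defaults encode the emulated study design and are fixed, not tuned: 123
cases and 114 controls (one sample per subject); 40 species with the home
species and two relatives in the family of interest and one foreign source
in another family; a +1.5 natural-log shift of the foreign species in cases
(an oral-taxon-like enrichment, comfortably inside reported effect sizes for
dysbiosis); 30 ordinary home genes of which 5 are truly differentially
carried at 0.80 vs 0.45 (the magnitude of the flagellar-gene prevalence
differences that motivated the copy-number analysis); 8 contaminant genes,
each attributed to its own synthetic MAG; depth scale 2000 (≈ 50 reads per
typical gene, a realistic coverage for a moderately abundant species);
presence threshold 0.35 on copy number; and two planted copy-number modules
of sizes 10 and 5 with within-module correlation 0.8 and group effects of
+1.5 and −1.5 latent SD — mirroring a case-enriched and a control-enriched
gene cluster — plus 10 flag-annotated background genes so the clustering
stage sees unstructured competitors. The returned copy-number matrix carries
the model-level copy numbers; read-level sampling noise lives in the reads
matrix. This separation keeps the planted module correlation at its nominal
value and matches what a quantifier's copy-number estimates converge to at
high coverage.

What the generator does **not** emulate — and what passing tests therefore
do not show about real data: overdispersed counts (Poisson only),
phylogenetic correlation among species abundances, compositional coupling
beyond the closure operation, cross-mapping between homologous genes,
per-species sample subsetting by coverage, multiple samples per subject
(supported by the readers and tests, but not generated by default), and any
read- or assembly-level process.

## Problem sizes and runtime

The test suite works at desk scale by design: the reference screen is 86
genes; synthetic bundles are 53 genes × 237 samples × 40 species; calibration
and recovery properties use 20 seeded replicates (type-I error of the
prevalence screen under a null generator; recovery of the planted modules as
exactly the significant-cluster set at n = 40 + 40); PAM is checked against
exhaustive medoid search at n ≤ 8; Fisher p-values against full
hypergeometric enumeration at n ≤ 200; AUROC against O(n²) pair counting.
The full suite runs in about a minute on one CPU.

## Known limitations

* The correlation–lineage test needs the source taxon in the abundance
  table; contamination from a species absent from the profile can only be
  caught by the annotation score or co-occurrence structure.
* Family-level matching uses exact, case-sensitive string equality of
  lineage names; it is only as good as the taxonomy's consistency.
* The EggNOG score depends on study-specific taxon lists; the packaged
  default applies to Lachnospiraceae-focused analyses and must be
  reconfigured for any other family of interest.
* UMAP reproducibility is guaranteed only through the bundled wrapper (seeded
  random init, pinned environment); embeddings from other UMAP front-ends
  will differ.
* The screen flags candidates; it does not prove contamination. Confirmation
  still requires sequence-level evidence.
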