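Package: panscreen
Title: Flagging Pangenome Contamination in Metagenomic Gene Association Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting pangenome contamination in gene-level
    metagenomic case-control analyses. Identifies differentially prevalent
    genes with Fisher's exact test and Benjamini-Hochberg correction, flags
    likely contaminants with a Spearman correlation-lineage rank test against
    species relative abundances, summarises gene co-occurrence with Jaccard
    similarity and 2-D ordination (NMDS, PCoA, UMAP), scores EggNOG predicted
    taxonomic ranges, and evaluates predictors by AUROC against BLAST-derived
    contamination labels. Also implements a gene-family copy-number analysis:
    PAM clustering on Pearson correlation distance with silhouette-based
    selection of the cluster number, SVD eigengene summaries, Wilcoxon
    rank-sum association tests, and bootstrap t-statistic enrichment. A
    seeded synthetic-community generator provides ground-truth bundles for
    end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    stats,
    tools,
    utils,
    vegan
Suggests:
    arrow,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
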