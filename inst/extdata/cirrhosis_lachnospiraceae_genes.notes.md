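# Transcription notes — cirrhosis_lachnospiraceae_genes.tsv

Transcribed from the published per-gene screen of a cirrhosis case–control
gut-metagenome study: 86 differentially prevalent Lachnospiraceae genes with
UHGP-90/EggNOG annotations, FDR q-values, correlation–lineage ranks and
BLAST-derived contamination calls.

Repairs applied during transcription (audited against the published row
counts: 33/86 contaminants, 26 single-assembly contaminants, 19
Negativicutes/Pasteurellales rows, confusion counts 1/39, 2/50, 27/28,
23/32 at q < 0.01):

- The rendered table row-spans the "Pangenome Species" column over each
  species block (Anaerostipes hadrus ×1, Lachnospira rogosae ×9, Roseburia
  inulinivorans ×22, Lachnospira eligens_B ×46, Acetatifactor sp900066565
  ×3, Faecalicatena gnavus ×5) and occasionally the "Species with Max
  Correlation Value" column; carried-over cells are filled in explicitly.
- "Staphylococcu s xylosus_B" (line-break artifact) -> "Staphylococcus
  xylosus_B".
- "CP_00 66" (space artifact) -> "CP_0066".
- Empty annotation cells are encoded as empty fields and read as missing.
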