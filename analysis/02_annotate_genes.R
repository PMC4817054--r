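#!/usr/bin/env Rscript
# Step 2: build gene models from the genome and its GFF3.
#
# Parses scaffolds + gene models, derives CDS/protein per gene and flags
# pseudogenes (internal stop) and partial models (missing start Met or
# terminal stop). Writes results/tables/gene_models.tsv.

suppressMessages(library(grannot))

scaffolds <- read_fasta("results/data/genome.fasta", "dna")
models <- suppressWarnings(read_gff3("results/data/genes.gff3", scaffolds))
tab <- gene_model_table(models)
tab$pseudogene <- vapply(models, detect_pseudogene, logical(1))
tab$partial <- vapply(models, function(m)
  detect_partial(m$protein, m$has_terminal_stop), character(1))

dir.create("results/tables", recursive = TRUE, showWarnings = FALSE)
write_tsv(tab, "results/tables/gene_models.tsv")
write_fasta(gene_model_proteins(models), "results/tables/proteins.fasta")

cat("Annotated", nrow(tab), "gene models on",
    length(unique(tab$scaffold)), "scaffolds\n")
cat("  intronless:", sum(tab$intronless),
    "| multi-exon:", sum(!tab$intronless), "\n")
cat("  internal stops (pseudogene candidates):", sum(tab$pseudogene), "\n")
cat("  partial models:", sum(tab$partial != "none"), "\n")
cat("  protein lengths:", min(tab$length_aa), "-", max(tab$length_aa),
    "aa\n")
cat("Wrote results/tables/gene_models.tsv\n")
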